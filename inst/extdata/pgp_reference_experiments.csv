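"drug","experiment","er_no_inhibitor","er_inhibitor","invitro_abundance_pmol_mg","invivo_abundance_pmol_mg","invivo_abundance_sd"
"DEX",1,5.42,0.85,1.16,0.16,0.07
"DEX",2,5.37,1.04,1.34,0.16,0.07
"DEX",3,8.33,1.35,1.92,0.16,0.07
"DEX",4,5.65,0.9,1.2,0.16,0.07
"BET",1,6.56,0.95,1.16,0.16,0.07
"BET",2,5.64,1.07,1.34,0.16,0.07
"BET",3,8.64,1.03,1.92,0.16,0.07
"BET",4,7.66,0.92,1.2,0.16,0.07
"DRV",1,40.43,0.82,1.16,0.16,0.07
"DRV",2,41.83,1.48,1.34,0.16,0.07
"DRV",3,37.86,1.12,1.92,0.16,0.07
"DRV",4,41.73,1.06,1.2,0.16,0.07
"LPV",1,95.37,1.02,1.3,0.16,0.07
"LPV",2,90.07,1.29,1.2,0.16,0.07
"LPV",3,75.63,1.64,1.2,0.16,0.07
"LPV",4,76.57,1.3,0.99,0.16,0.07
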