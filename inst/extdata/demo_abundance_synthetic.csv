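"drug","experiment_id","invitro_abundance_pmol_mg"
"SYNDEX",1,1.2
"SYNDEX",2,1.5
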