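"drug","experiment_id","direction","inhibitor","compartment","time_min","conc_uM","sampled_volume_ml","well"
"SYNDEX","1","A2B","none","receiver",15,0.000199473590641669,0.1,"w1"
"SYNDEX","1","A2B","none","receiver",30,0.000388976419379556,0.1,"w1"
"SYNDEX","1","A2B","none","receiver",45,0.000534557611726282,0.1,"w1"
"SYNDEX","1","A2B","none","receiver",60,0.000696446214477537,0.1,"w1"
"SYNDEX","1","A2B","none","donor",0,2.0178212955611,0.01,"w1"
"SYNDEX","1","A2B","none","donor",60,2.0690434168098,0.01,"w1"
"SYNDEX","1","B2A","none","receiver",15,0.00221623637148976,0.1,"w1"
"SYNDEX","1","B2A","none","receiver",30,0.00390111074911683,0.1,"w1"
"SYNDEX","1","B2A","none","receiver",45,0.00545182819587904,0.1,"w1"
"SYNDEX","1","B2A","none","receiver",60,0.00637137292670963,0.1,"w1"
"SYNDEX","1","B2A","none","donor",0,2.03091671347088,0.01,"w1"
"SYNDEX","1","B2A","none","donor",60,1.94771877026911,0.01,"w1"
"SYNDEX","1","A2B","pgp_inhibitor","receiver",15,0.000201167252629557,0.1,"w1"
"SYNDEX","1","A2B","pgp_inhibitor","receiver",30,0.000391641672225361,0.1,"w1"
"SYNDEX","1","A2B","pgp_inhibitor","receiver",45,0.000543438249560194,0.1,"w1"
"SYNDEX","1","A2B","pgp_inhibitor","receiver",60,0.000690209323623397,0.1,"w1"
"SYNDEX","1","A2B","pgp_inhibitor","donor",0,1.97552603450115,0.01,"w1"
"SYNDEX","1","A2B","pgp_inhibitor","donor",60,2.04487706477742,0.01,"w1"
"SYNDEX","1","B2A","pgp_inhibitor","receiver",15,0.00038641669148245,0.1,"w1"
"SYNDEX","1","B2A","pgp_inhibitor","receiver",30,0.000703391368562692,0.1,"w1"
"SYNDEX","1","B2A","pgp_inhibitor","receiver",45,0.000989721227333676,0.1,"w1"
"SYNDEX","1","B2A","pgp_inhibitor","receiver",60,0.00121323685175755,0.1,"w1"
"SYNDEX","1","B2A","pgp_inhibitor","donor",0,1.97025721218195,0.01,"w1"
"SYNDEX","1","B2A","pgp_inhibitor","donor",60,2.03217108947276,0.01,"w1"
"SYNDEX","2","A2B","none","receiver",15,0.000202527405661872,0.1,"w1"
"SYNDEX","2","A2B","none","receiver",30,0.00039169572305686,0.1,"w1"
"SYNDEX","2","A2B","none","receiver",45,0.000523793469643824,0.1,"w1"
"SYNDEX","2","A2B","none","receiver",60,0.000734394827092311,0.1,"w1"
"SYNDEX","2","A2B","none","donor",0,2.07475521585702,0.01,"w1"
"SYNDEX","2","A2B","none","donor",60,2.07069797500345,0.01,"w1"
"SYNDEX","2","B2A","none","receiver",15,0.00223474998577604,0.1,"w1"
"SYNDEX","2","B2A","none","receiver",30,0.00394422139574603,0.1,"w1"
"SYNDEX","2","B2A","none","receiver",45,0.00539207693398566,0.1,"w1"
"SYNDEX","2","B2A","none","receiver",60,0.00679100906621208,0.1,"w1"
"SYNDEX","2","B2A","none","donor",0,2.08761787979806,0.01,"w1"
"SYNDEX","2","B2A","none","donor",60,2.00162007810232,0.01,"w1"
"SYNDEX","2","A2B","pgp_inhibitor","receiver",15,0.00021600779695015,0.1,"w1"
"SYNDEX","2","A2B","pgp_inhibitor","receiver",30,0.000375243588130382,0.1,"w1"
"SYNDEX","2","A2B","pgp_inhibitor","receiver",45,0.000550852782843521,0.1,"w1"
"SYNDEX","2","A2B","pgp_inhibitor","receiver",60,0.000668740665767715,0.1,"w1"
"SYNDEX","2","A2B","pgp_inhibitor","donor",0,1.92395222405281,0.01,"w1"
"SYNDEX","2","A2B","pgp_inhibitor","donor",60,1.95414046604454,0.01,"w1"
"SYNDEX","2","B2A","pgp_inhibitor","receiver",15,0.000408878882166347,0.1,"w1"
"SYNDEX","2","B2A","pgp_inhibitor","receiver",30,0.00070823123123684,0.1,"w1"
"SYNDEX","2","B2A","pgp_inhibitor","receiver",45,0.000962907998922644,0.1,"w1"
"SYNDEX","2","B2A","pgp_inhibitor","receiver",60,0.00119905417466835,0.1,"w1"
"SYNDEX","2","B2A","pgp_inhibitor","donor",0,1.96076810533456,0.01,"w1"
"SYNDEX","2","B2A","pgp_inhibitor","donor",60,2.02139754341641,0.01,"w1"
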