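"gw","sa_ratio","abundance_ratio","q_mp_lph","q_uv_lph","v_placenta_l","v_fetal_l"
20,0.39,0.6,27.5,27.5,0.17,1
38,1,1,45,45,0.64,5
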