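well_id,assay_id,n_double_pos,n_ch1_only,n_ch2_only,n_negative,droplet_volume_nl
W01,MUT-CYSLTR2,1522,4730,3533,10215,0.85
W02,CN-CYSLTR2,6085,3590,6557,3768,0.85
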