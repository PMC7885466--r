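sample_id	locus_id	statistic	value	ci_low	ci_high	alteration
PUM-1A	CYSLTR2	mcf	0.74	0.72	0.76	NA
PUM-1A	CYSLTR2	aberrant_fraction	0.67	0.65	0.69	loss
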