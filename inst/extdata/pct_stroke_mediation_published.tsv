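mediator	outcome	total_or	total_ci_low	total_ci_high	direct_effect	proportion_pct	proportion_ci_low_pct	proportion_ci_high_pct
SBP	stroke	1.113	1.047	1.183	0.082	23.71	10.85	33.31
DBP	stroke	1.113	1.047	1.183	0.077	28.09	12.92	39.63
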