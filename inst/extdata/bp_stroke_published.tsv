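exposure	outcome	n_snps	beta	or	ci_low	ci_high
SBP	stroke	95	0.035	1.036	1.029	1.042
SBP	LAS	95	0.062	1.064	1.048	1.081
SBP	AIS	95	0.038	1.039	1.032	1.046
SBP	SVS	95	0.041	1.042	1.027	1.057
SBP	CES	95	0.027	1.028	1.015	1.041
DBP	stroke	93	0.05	1.051	1.038	1.065
DBP	LAS	93	0.064	1.066	1.038	1.095
DBP	AIS	93	0.055	1.057	1.043	1.071
DBP	SVS	93	0.071	1.074	1.046	1.102
DBP	CES	93	0.044	1.045	1.022	1.069
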