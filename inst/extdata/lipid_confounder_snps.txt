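rs1260326
rs964184
rs10761731
rs780093
rs5130
rs631106
rs7896518
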