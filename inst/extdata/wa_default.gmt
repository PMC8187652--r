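WA_DEFAULT	AXIN2-anchored Wnt-activation module	MACC1	KRT23	FGFR4	RPS6KA6	PROX1	ASCL2	AXIN2	RASSF10
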