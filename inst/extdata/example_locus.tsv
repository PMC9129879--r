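allele_primary	A
allele_secondary	C
flank_left	TTGGT
flank_right	GTCTT
label	synthetic example SNP
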