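patient	timepoint	chrom	start	end	log2_ratio
7	1	12	0	400000	-0.798
7	1	11	0	135000000	0.511
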