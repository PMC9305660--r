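patient	timepoint	chrom	start	end	log2_ratio
1	0	5	80000000	150000000	-0.862
1	0	17	0	81000000	-0.845
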