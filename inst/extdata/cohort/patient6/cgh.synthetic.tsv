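patient	timepoint	chrom	start	end	log2_ratio
6	1	7	0	159000000	-0.678
6	1	13	19000000	115000000	-0.678
6	1	14	30000000	90000000	-0.678
6	2	7	0	159000000	-0.678
6	2	13	19000000	115000000	-0.678
6	2	14	30000000	90000000	-0.678
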