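patient	timepoint	gene	hgvs_c	hgvs_p	vaf_percent	depth	alt_reads
3	0	NF1	c.2033del	p.(Pro678Arg*10)	49.52		
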