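patient	timepoint	gene	hgvs_c	hgvs_p	vaf_percent	depth	alt_reads
1	0	ASXL1	c.2317G>T	p.(Glu773*)	10.83		
1	0	DNMT3A	c.2645G>A	p.(Arg882His)	18.69		
1	0	IDH1	c.394C>T	p.(Arg132Cys)	13.85		
1	0	TP53	c.427G>A	p.(Val143Met)	20.49		
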