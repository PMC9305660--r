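patient	timepoint	gene	hgvs_c	hgvs_p	vaf_percent	depth	alt_reads
5	0	ASXL1	c.2077C>T	p.(Arg693*)	0.68		
5	0	KRAS	c.38G>A	p.(Gly13Asp)	0.35		
5	0	NRAS	c.182A>G	p.(Gln61Arg)	0.50		
5	1	ASXL1	c.2077C>T	p.(Arg693*)	7.84		
5	1	KRAS	c.38G>A	p.(Gly13Asp)	7.59		
5	1	NRAS	c.182A>G	p.(Gln61Arg)	5.34		
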