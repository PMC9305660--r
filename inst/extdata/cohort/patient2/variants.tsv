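patient	timepoint	gene	hgvs_c	hgvs_p	vaf_percent	depth	alt_reads
2	0	BCOR	c.4639+1G>A		66.76		
2	0	DNMT3A	c.2645G>A	p.(Arg882His)	39.43		
2	0	KRAS	c.34G>C	p.(Gly12Arg)	4.03		
2	0	SF3B1	c.2098A>G	p.(Lys700Glu)	1.31		
2	0	STAG2	c.3362_3365dup	p.(Ser1123Hisfs*14)	52.12		
2	0	U2AF1	c.101C>T	p.(Ser34Phe)	31.50		
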