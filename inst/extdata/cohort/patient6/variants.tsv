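patient	timepoint	gene	hgvs_c	hgvs_p	vaf_percent	depth	alt_reads
6	0	JAK2	c.1849G>T	p.(Val617Phe)	73.76		
6	1	JAK2	c.1849G>T	p.(Val617Phe)	97.53		
6	1	TP53	c.814G>A	p.(Val272Met)	19.56		
6	2	JAK2	c.1849G>T	p.(Val617Phe)	98.12		
6	2	TP53	c.814G>A	p.(Val272Met)	23.36		
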