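patient	timepoint	gene	hgvs_c	hgvs_p	vaf_percent	depth	alt_reads
4	0	IDH2	c.419G>A	p.(Arg140Gln)	46.79		
4	0	RUNX1	c.420T>G	p.(Ser140Arg)	43.00		
4	0	SRSF2	c.284C>T	p.(Pro95Leu)	39.78		
4	0	TET2	c.1455del	p.(Asn486Thr*11)	47.20		
4	0	TET2	c.3473del	p.(Ala1158Glu*68)	41.43		
4	0	TP53	c.844C>T	p.(Arg282Trp)	90.92		
4	1	IDH2	c.419G>A	p.(Arg140Gln)	33.28		
4	1	KRAS	c.35G>C	p.(Gly12Ala)	1.96		
4	1	NRAS	c.35G>C	p.(Gly12Ala)	1.70		
4	1	PTPN11	c.1508G>C	p.(Gly503Ala)	2.80		
4	1	RUNX1	c.420T>G	p.(Ser140Arg)	38.29		
4	1	SRSF2	c.284C>T	p.(Pro95Leu)	40.88		
4	1	TET2	c.1398_1402dup	p.(His468Leu*20)	5.11		
4	1	TET2	c.1455del	p.(Asn486Thr*11)	44.10		
4	1	TET2	c.3473del	p.(Ala1158Glu*68)	36.71		
4	1	TP53	c.844C>T	p.(Arg282Trp)	74.41		
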