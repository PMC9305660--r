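patient	timepoint	gene	hgvs_c	hgvs_p	vaf_percent	depth	alt_reads
8	0	NRAS	c.37G>C	p.(Gly13Arg)	12.69		
8	0	WT1	c.1136_1142dup	p.(Ala382Thr*5)	23.26		
8	2	NRAS	c.37G>C	p.(Gly13Arg)	12.78		
8	2	NRAS	c.37G>T	p.(Gly13Cys)	5.03		
8	2	WT1	c.1141_1144dup	p.(Ala382Val*4)	4.51		
8	2	WT1	c.1136_1142dup	p.(Ala382Thr*5)	11.35		
8	2	WT1	c.1128dup	p.(Thr377Asp*8)	1.48		
8	2	WT1	c.1110dup	p.(Val371Cys*14)	3.69		
8	3	NRAS	c.37G>C	p.(Gly13Arg)	17.38		
8	3	NRAS	c.37G>T	p.(Gly13Cys)	4.93		
8	3	WT1	c.1141_1144dup	p.(Ala382Val*4)	4.03		
8	3	WT1	c.1136_1142dup	p.(Ala382Thr*5)	17.18		
8	3	WT1	c.1128dup	p.(Thr377Asp*8)	4.76		
8	3	WT1	c.1110dup	p.(Val371Cys*14)	4.96		
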