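patient	timepoint	clone_iscn	metaphases_with	metaphases_total
5	0	t(4;14;11)(q22;q32;q23),add(10)(p14)	18	20
5	0	46,XX	2	20
5	1	t(4;14;11)(q22;q32;q23),add(10)(p14)	16	20
5	1	t(4;14;11)(q22;q32;q23),+der(4)t(4;14;11),+8,+9,add(10)(p14),+19,+21	3	20
5	1	46,XX	1	20
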