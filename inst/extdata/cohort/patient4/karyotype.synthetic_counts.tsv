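patient	timepoint	clone_iscn	metaphases_with	metaphases_total
4	0	del(5)(q14q34)	7	20
4	0	del(5)(q14q34),+8,i(8)(q10)x2	12	20
4	0	46,XX	1	20
4	1	del(5)(q14q34)	4	20
4	1	del(5)(q14q34),+8,i(8)(q10)x2	6	20
4	1	t(2;3)(p23;q27),del(5)(q14q34),del(7)(q21),+8,i(8)(q10)x2	8	20
4	1	46,XX	2	20
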