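patient	timepoint	clone_iscn	metaphases_with	metaphases_total
8	0	del(9)(q21q31)	16	20
8	0	46,XX	4	20
8	1	46,XX	20	20
8	2	del(9)(q21q31)	5	20
8	2	t(1;16)(p12;q21),del(9)(q21q31)	9	20
8	2	46,XX	6	20
8	3	del(9)(q21q31)	6	20
8	3	t(1;16)(p12;q21),del(9)(q21q31)	6	20
8	3	t(1;16)(p12;q21),?add(9)(p12),del(9)(q21q31),add(10)(p12),add(17)(q22)	4	20
8	3	46,XX	4	20
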