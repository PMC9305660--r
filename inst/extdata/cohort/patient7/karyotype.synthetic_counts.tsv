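patient	timepoint	clone_iscn	metaphases_with	metaphases_total
7	0	ins(9;12)(q34;p12p13),+12	18	20
7	0	46,XX	2	20
7	1	ins(9;12)(q34;p12p13),+12	1	20
7	1	+X,ins(9;12)(q34;p12p13),+11,+12,del(12)(p13),+19	17	20
7	1	46,XX	2	20
7	2	46,XX	20	20
7	3	ins(9;12)(q34;p12p13),+12	3	20
7	3	der(7)t(7;9)(q35;q21),ins(9;12)(q34;p12p13),+12	9	20
7	3	46,XX	8	20
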