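patient	timepoint	probe	nuclei_with	nuclei_total	target
7	0	12p13	2	200	del(12)(p13)
7	1	12p13	170	200	del(12)(p13)
7	2	12p13	0	200	del(12)(p13)
7	3	12p13	1	200	del(12)(p13)
7	0	9q34	178	200	ins(9;12)(q34;p12p13)
7	1	9q34	176	200	ins(9;12)(q34;p12p13)
7	2	9q34	0	200	ins(9;12)(q34;p12p13)
7	3	9q34	118	200	ins(9;12)(q34;p12p13)
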