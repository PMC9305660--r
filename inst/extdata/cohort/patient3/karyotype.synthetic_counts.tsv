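patient	timepoint	clone_iscn	metaphases_with	metaphases_total
3	0	t(9;20)(q11;q11),t(12;22)(p13;q11)	10	20
3	0	t(12;22)(p13;q11)	9	20
3	0	46,XX	1	20
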