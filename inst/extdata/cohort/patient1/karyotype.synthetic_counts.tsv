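patient	timepoint	clone_iscn	metaphases_with	metaphases_total
1	0	del(5)(q14q33),-17,add(18)(q22),+mar1,+mar2,+mar3	18	20
1	0	46,XX	2	20
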