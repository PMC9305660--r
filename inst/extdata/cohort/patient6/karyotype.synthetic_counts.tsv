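patient	timepoint	clone_iscn	metaphases_with	metaphases_total
6	1	add(5)(q12),-7,-13,del(14)(q12q31),der(17)t(13;17)(q21;p12)	15	20
6	1	46,XX	5	20
6	2	add(5)(q12),-7,-13,del(14)(q12q31),der(17)t(13;17)(q21;p12)	7	20
6	2	add(2)(q37),add(5)(q12),-7,-13,del(14)(q12q31),der(17)t(13;17)(q21;p12),del(20)(q12q13)	8	20
6	2	46,XX	5	20
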