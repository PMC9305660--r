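patient	timepoint	clone_iscn	metaphases_with	metaphases_total
2	0	+8,+10	15	20
2	0	46,XY	5	20
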