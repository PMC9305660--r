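patient	timepoint	gene	hgvs_c	hgvs_p	vaf_percent	depth	alt_reads
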