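patient: "6"
sex: female
timepoints:
  - {index: 0, label: initial, status: initial}
  - {index: 1, label: progression, status: progression}
  - {index: 2, label: progression, status: progression}
files:
  variants: variants.tsv
  karyotype: karyotype.synthetic_counts.tsv
  cgh: cgh.synthetic.tsv
cnv_effects:
  - {id: "der(17)t(13;17)(q21;p12)", direction: loss, chrom: "17", region: "p12ter"}
notes: >
  The derivative chromosome 17 deletes the short-arm region containing
  TP53; the cnv_effects entry encodes that biological interpretation so the
  TP53 variant is routed through the CNV/SNV overlap model. Counts and CGH
  segments synthetic; see ../README.md.
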