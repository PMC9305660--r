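patient: "4"
sex: female
timepoints:
  - {index: 0, label: initial, status: initial}
  - {index: 1, label: progression, status: progression}
files:
  variants: variants.tsv
  karyotype: karyotype.synthetic_counts.tsv
notes: Counts synthetic; see ../README.md.
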