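patient: "1"
sex: female
timepoints:
  - {index: 0, label: initial, status: initial}
files:
  variants: variants.tsv
  karyotype: karyotype.synthetic_counts.tsv
  cgh: cgh.synthetic.tsv
notes: >
  Metaphase counts and CGH segments are synthetic stand-ins consistent with
  the published clone description; see ../README.md.
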