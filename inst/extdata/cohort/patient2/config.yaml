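patient: "2"
sex: male
timepoints:
  - {index: 0, label: initial, status: initial}
files:
  variants: variants.tsv
  karyotype: karyotype.synthetic_counts.tsv
notes: >
  sex male inferred from the X-linked BCOR/STAG2 VAFs (impossible under the
  autosomal heterozygous rule). Counts synthetic; see ../README.md.
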