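patient: "8"
sex: female
timepoints:
  - {index: 0, label: initial, status: initial}
  - {index: 1, label: remission, status: remission, sct_before: true}
  - {index: 2, label: relapse, status: relapse}
  - {index: 3, label: progression, status: progression}
  - {index: 4, label: remission, status: remission}
files:
  variants: variants.tsv
  karyotype: karyotype.synthetic_counts.tsv
exclusive_genes: [WT1, NRAS]
notes: >
  Distinct hotspot variants of WT1 and NRAS are interpreted as marking
  independent subclones (multi-hit pattern), so they are never clustered
  into one clone. Counts synthetic; see ../README.md.
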