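patient: "7"
sex: female
timepoints:
  - {index: 0, label: initial, status: initial}
  - {index: 1, label: progression, status: progression}
  - {index: 2, label: remission, status: remission}
  - {index: 3, label: relapse, status: relapse, sct_before: true}
files:
  variants: variants.tsv
  karyotype: karyotype.synthetic_counts.tsv
  fish: fish.synthetic_counts.tsv
  cgh: cgh.synthetic.tsv
notes: >
  No somatic variants were detected at any time point; all evidence is
  cytogenetic. Counts, FISH and CGH values synthetic; see ../README.md.
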