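# Cohort fixtures

Eight patient directories encoding the published diagnostic findings of a
myeloid-neoplasia cohort: somatic variants with VAFs (percent), ISCN
karyotype clone descriptions, and clinical status per time point.

Metaphase counts (karyotyping) and nuclei counts (FISH) were not published
at per-clone granularity. Files named `*.synthetic_counts.tsv` and
`*.synthetic.tsv` therefore carry SYNTHETIC counts/segments, constructed to
be consistent with the VAF-derived CCFs of co-clonal variants and with the
published clone descriptions. They are stand-ins, not measured data.

Patient 1's table enumerates 10 events (6 cytogenetic + 4 variants) while
the running text reports 11 aberrations; the fixture encodes the table
verbatim, so `countAberrations()` returns 10 for patient 1.
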