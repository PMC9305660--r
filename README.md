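# clonalCCF

Clonal evolution reconstruction from the mixed evidence of routine
leukemia diagnostics.

Myeloid neoplasias (AML, MDS, MPN) evolve as hierarchies of subclones, and
routine work-up sees that hierarchy through four different instruments:
targeted sequencing (variant allele frequencies for SNVs/indels),
karyotyping (metaphase counts per cytogenetic clone), interphase FISH
(nuclei counts per probe) and array-CGH (log2 intensity ratios for
copy-number segments). `clonalCCF` is for diagnosticians and
computational biologists who need to put all of that on one scale — the
cancer cell fraction (CCF) — and turn it into clone trees, evolution
patterns and fishplots, without discarding the ambiguity that bulk data
genuinely leaves.

## The model

Per modality: CCF = 2·VAF for autosomal heterozygous variants (CCF = VAF
on hemizygous loci), carrier proportions with Wilson 95% intervals for
counted cells, and inversion of the one-copy mixture ratio
(2 ∓ f)/2 for CGH-only events.

When a CNV covers a variant's locus, VAF and CCF decouple. The package
models four cell classes — w (CNV+variant), x (CNV only), y (variant
only), z (neither) — with w+x+y+z = 1 and CCF_CNV = w+x, and solves

    VAF = (cnv_value·w + y) / (1·w + 1·x + 2·y + 2·z)   if the CNV is a deletion
    VAF = (cnv_value·w + y) / (3·w + 3·x + 2·y + 2·z)   if it is a duplication

in closed form under all four event-order cases (CNV first; variant first
with either allele hit; parallel). Cases whose solved fractions leave
[0, 1] are excluded; all survivors propagate as labelled alternative
reconstructions. Clone trees are then enumerated exhaustively under the
nesting constraints (children's CCFs sum to at most the parent's at every
time point; roots to at most 1; no clone before its parent) and each tree
is classified as linear, branched or neutral evolution.

## Worked example

A TP53 variant is observed at VAF 19.56% while a derivative chromosome 17
deleting the TP53 locus sits at CCF 0.75. Which came first?

```r
library(clonalCCF)
cases <- enumerateOverlapCases(vaf = 0.1956, ccf_cnv = 0.75, cnv_type = "deletion")
round(cases[, c("scenario","cnv_value","w","x","y","z","ccf_snv","violation")], 4)
#>   scenario cnv_value      w      x       y      z ccf_snv violation
#> 1        1         1 0.2445 0.5055  0.0000 0.2500  0.2445    0.0000
#> 2        2         0 0.7500 0.0000  0.2445 0.0055  0.9945    0.0000
#> 3        2         1 0.7500 0.0000 -0.5055 0.7555  0.2445    0.5055
#> 4        3         1 0.0000 0.7500  0.2445 0.0055  0.2445    0.0000
```

Three cases are consistent with w+x+y+z = 1 (the third is excluded, its
fractions overshoot by 0.51): either the deletion came first and the
variant arose on the remaining allele in a 24% subclone (scenario 1), or
the variant came first and the deletion then removed the wild-type allele
— biallelic TP53 inactivation in a ~99% clone (scenario 2, cnv_value 0) —
or the two events arose in parallel (scenario 3). The data alone cannot
decide, so reconstruction branches:

```r
trees <- reconstructPatient(cohortPatient(6))
sapply(trees, evolutionPattern)
#> [1] "branched" "linear"   "branched"
trees[[2]]
#> CloneTree (linear, rank 2, case TP53 c.814G>A:scenario2/cnv_value0)
#>   clone 1 <- root [JAK2 c.1849G>T]: 1.000 1.000 1.000
#>   clone 2 <- clone 1 [TP53 c.814G>A]: 0.000 0.994 1.000
#>   clone 3 <- clone 2 [-13, -7, add(5)(q12), del(14)(q12q31), der(17)t(13;17)(q21;p12)]: 0.000 0.750 0.750
#>   clone 4 <- clone 3 [add(2)(q37), del(20)(q12q13)]: 0.000 0.000 0.400
```

The linear alternative is exactly the biallelic-inactivation reading: the
TP53 point mutation sweeps inside the JAK2 stemline, then the deletion
removes the second allele. Render any tree as a fishplot with
`renderFishplot(exportFishplot(trees[[2]]), "patient6.svg")`.

A simulator closes the loop: `simulateObservations()` realizes a truth
tree as explicit cell populations and emits noisy variants/karyotype/
FISH/CGH files that `loadPatient()` + `reconstructPatient()` must recover
— the package's own end-to-end validation.

## Command line

```sh
exec/clonalccf overlap --vaf 0.25 --ccf-cnv 0.5 --type deletion
exec/clonalccf fixtures --patient 3 --out p3/
exec/clonalccf reconstruct --patient p3/ --out out/     # trees.json + log
exec/clonalccf render --tree out/trees.json --index 1 --out plot.svg
```

Exit codes: 0 success, 2 invalid input, 3 infeasible reconstruction.

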