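---
title: "Reconstructing clonal evolution from integrated leukemia diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing clonal evolution from integrated leukemia diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalCCF)
```

## The problem

Routine diagnostics of myeloid neoplasia sees the tumor genome through four
instruments at once: targeted sequencing reports variant allele frequencies
(VAFs) for SNVs and indels; karyotyping counts metaphases per cytogenetic
clone; interphase FISH counts nuclei carrying a probe signal; array-CGH
reports log2 fluorescence ratios for copy-number segments. Each modality
measures a different quantity on a different scale. To reason about clonal
evolution — which clone begat which, and how the composition shifted under
therapy — all of them must be converted to one common currency: the cancer
cell fraction (CCF), the fraction of analyzed cells carrying an event.

`clonalCCF` performs that conversion, resolves the one genuinely entangled
case (a variant whose locus sits inside a copy-number event), enumerates
every clone tree consistent with the CCFs across time points, classifies
the evolution pattern, and draws fishplots.

## CCF estimation per modality

* **VAF**: an autosomal heterozygous variant occupies one of two alleles,
  so CCF = 2·VAF. On hemizygous loci (X or Y in males) CCF = VAF. A
  doubled VAF above 1 is capped at 1 and flagged `capped_at_1` rather than
  being silently reinterpreted as loss of heterozygosity — LOH is a model
  change that deserves explicit input (see the overlap model below), not a
  side effect.
* **Counts** (metaphases, FISH nuclei): CCF is the carrier proportion,
  with a Wilson 95% score interval. When both karyotype and FISH cover the
  same event the estimates are combined by inverse-variance weighting.
* **log2 ratio**: under a one-copy change in a diploid background, a
  carrier fraction f gives a tumor/reference ratio (2−f)/2 for a loss and
  (2+f)/2 for a gain; the package inverts this. The model deliberately
  ignores tumor purity, multi-copy amplification and subclonal
  copy-number mixtures; CGH-only estimates are therefore used only when no
  count data exist for the event.

Estimates without read counts carry a fixed ±0.05 uncertainty band on the
VAF scale (±0.10 on CCF). That width is what the clustering tolerance
below assumes; the two defaults are one decision, not two.

## The CNV/SNV overlap model

When a deletion or duplication covers a variant's locus, VAF and CCF
decouple. The package models four cell classes: `w` (CNV and variant),
`x` (CNV only), `y` (variant only), `z` (neither), with
`w + x + y + z = 1` and `CCF_CNV = w + x`. Counting alleles gives

    VAF = (cnv_value·w + y) / (1·w + 1·x + 2·y + 2·z)   (deletion)
    VAF = (cnv_value·w + y) / (3·w + 3·x + 2·y + 2·z)   (duplication)

where `cnv_value` is the number of variant-carrying alleles in the `w`
cells. Three scenarios order the two events — CNV first (`y = 0`), variant
first (`x = 0`, where the CNV may hit the variant allele or the other
one), or parallel clones (`w = 0`) — yielding four cases in total, each
solvable in closed form. A case whose solved fractions leave `[0, 1]`
violates the sum assumption and is excluded; the tolerance `eps` (default
0.05 absolute) exists because counted CCFs and deep VAFs are noisy, and an
exact-zero exclusion rule would discard cases the data support. All
surviving cases propagate as labelled alternatives; the package never
auto-selects among them, because the order of two events in bulk data is
often knowable only through external biological argument.

Two corner cases worth noting:

* `CCF_CNV = 0` collapses every scenario to CCF = 2·VAF, recovering the
  heterozygous rule.
* For a deletion with `cnv_value = 0` and VAF = 0, the variant allele is
  itself deleted: the VAF is uninformative, and the scenario-2
  parametrization pins CCF_SNV to CCF_CNV. This is the algebraically
  consistent answer, not an artifact.

Every case also constrains ancestry downstream: the CNV-first case
requires the CNV clone on the variant clone's root path, the variant-first
case the converse, and the parallel case keeps the two clones in disjoint
lineages.

The simulator's `CellPopulation` realizes any case as explicit cell
classes with allele copy counts, and `exactVaf()` recovers the bulk VAF by
plain counting — an oracle with no shared algebra, tested to 1e-12 against
the closed form on a full simplex grid.

## Clustering and tree enumeration

Aberrations whose CCF trajectories agree at every shared time point —
within an absolute tolerance of 0.10, or with overlapping 95% bands,
whichever is more permissive — are merged into clones. Assignment is
greedy against the cluster's precision-weighted mean trajectory, followed
by whole-cluster merge passes to a fixed point; comparing against means
rather than single members keeps one noisy outlier from stranding itself
in a clone that then has no admissible place in any tree, while stopping
short of single-linkage chaining, which would fuse genuinely distinct
small subclones. A per-patient `exclusive_genes` configuration adds
cannot-link constraints: distinct hotspot variants of one gene (the
multi-hit pattern) are kept in separate clones.

Tree enumeration is exhaustive over parent assignments subject to three
constraints, checked at every time point: a clone's children's CCFs sum to
at most the clone's CCF plus slack `delta` (default 0.05, absorbing count
noise), root clones sum to at most 1 + `delta`, and no clone appears
before its parent. The search is a pruned depth-first scan whose
pruning is exactly implied by the constraints (verified against a
brute-force scan of all parent vectors on small instances), so the output
is the complete set of admissible trees, ordered fewest-roots-first and
then lexicographically — deterministic by construction. Reporting all
admissible trees is a feature: real cohorts contain patients whose data
genuinely underdetermine the parent of a small subclone.

Patterns: **linear** if every node (including the implicit root) has at
most one child; **neutral** if at some time point at least `k` sibling
subclones (default 4) coexist with none reaching a dominance CCF of 0.5;
**branched** otherwise. The defaults reproduce the qualitative
classifications of the packaged cohort where its counts permit.

Remission time points carry their own evidence: a normal karyotype counts
0/N metaphases for every cytogenetic event and undetected variants
contribute CCF 0, so clone trajectories drop to zero there without any
special-casing.

## The synthetic-data generator

`simulateObservations()` realizes a truth clone tree as one explicit cell
population per time point (a clone's own fraction is its CCF minus its
children's; the remainder is normal cells) and draws: VAFs ~
Binomial(depth, exact VAF)/depth; metaphase counts ~ Multinomial over cell
classes, serialized as cumulative ISCN clone strings; FISH nuclei ~
Binomial(n, carrier fraction); log2 ratios from the forward one-copy
model plus Gaussian noise. Per-modality RNG streams are split from one
master seed, so adding a modality never shifts another's draws. Defaults —
depth 5000, 20 metaphases, 200 nuclei — mirror routine practice (15–25
metaphases are examined; at least 200 nuclei are scored per probe).

What the generator does *not* emulate: sequencing error beyond binomial
sampling, CNVs overlapping simulated variant loci (overlap configurations
are realized directly via `populationFromOverlapCase()` instead), tumor
purity below 1, and karyotype culture bias. Passing recovery tests
therefore demonstrate correctness of the estimation and enumeration
machinery under the stated sampling model, not robustness to artifacts
real assays add on top.

The recovery test simulates a 4-clone branched tree at those defaults and
requires the truth tree among the emitted alternatives with clone-CCF RMSE
within three binomial standard errors of the sampling design. Problem
sizes throughout the test suite (grids of ~1800 simplex points, 10,000
random draws, trees of up to 7 clones) were chosen so the full suite
completes in about a minute on one core.

## The packaged cohort

The `inst/extdata/cohort` fixtures encode the published findings of an
eight-patient myeloid cohort: every variant with its VAF, every ISCN
karyotype clone, clinical status per time point. Per-clone metaphase and
nuclei counts were published only in a supplement that is not available,
so the packaged counts are synthetic (files are named
`*.synthetic_counts.tsv`), constructed once to be consistent with the
VAF-derived CCFs of co-clonal variants and with the described clonal
structure. Consequences worth knowing:

* Patient 1's table enumerates 10 events though the cohort description
  counts 11; the fixture encodes the table, so the package counts 10.
* Patient 6's TP53 variant under the derivative chromosome 17 exercises
  the overlap model; with the synthetic counts three of the four cases
  survive, producing one linear reconstruction (variant first, biallelic
  TP53 inactivation) and branched alternatives — the qualitative duality
  the cohort is known for.
* Patient 2's config declares `sex: male`, inferred from X-linked VAFs
  near 67% and 52% that are impossible under the autosomal rule.
* Patient 8 does not classify as neutral under the default `k = 4`:
  CCF-level clustering fuses two of its small same-sized subclones, and
  synthetic counts cannot restore information the table does not contain.
  The neutral rule itself is tested directly on constructed trees.

## Numerical choices

* Fractions internally, percent at every file boundary.
* Wilson (score) intervals for all count proportions; standard errors for
  weighting derived from CI half-widths, floored at 0.01 — a CCF is never
  treated as known to better than one percentage point.
* Band arithmetic is symbolic: ISCN band designations order naturally
  within an arm (q14 < q21 < q33 via digit sequence), so band-interval
  overlap needs no genome coordinate table. The trade-off: CGH segments,
  which live in coordinates, merge with band-level karyotype events at
  (chromosome, direction) resolution only.
* Tie-breaks are everywhere lexicographic after the documented sort keys;
  two runs on identical inputs produce byte-identical trees, exports and
  SVGs (the renderer formats numbers itself for that reason).
* `i(8)(q10)x2`-style multipliers are kept as one aberration with a
  multiplicity annotation; the CCF machinery treats the event as one
  clone marker regardless of copy multiplicity.

## Known limitations

* No purity/ploidy correction and no allele-specific copy number; the
  overlap model supports exactly one CNV over a locus, with duplication
  meaning one gained copy.
* Clustering is by CCF trajectory; clones that happen to share a
  trajectory are indistinguishable without external constraints.
* Tree counts grow combinatorially with clones of similar size;
  enumeration is capped (default 1000 trees) with a deterministic
  truncation warning.
* The evolution-pattern classifier depends on the emitted tree; for
  patients with many admissible trees the pattern is reported per tree,
  not per patient.
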