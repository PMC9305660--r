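Package: clonalCCF
Title: Clonal Evolution Reconstruction from Integrated Leukemia Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates somatic variant allele frequencies, karyotype
    metaphase counts, interphase FISH nuclei counts and array-CGH log2
    ratios from routine leukemia diagnostics into cancer cell fraction
    (CCF) estimates; solves the cell-fraction model for single nucleotide
    variants or indels whose locus is covered by a copy number variant;
    clusters aberrations into clones, enumerates all clone trees
    consistent with nesting constraints across time points, classifies
    the evolution pattern (linear, branched, neutral) and renders
    fishplot visualizations. Includes a restricted ISCN karyotype parser,
    a synthetic-data simulator with an explicit cell-population oracle,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'bands.R'
    'iscn.R'
    'io.R'
    'ccf.R'
    'overlap.R'
    'reconstruct.R'
    'trees-io.R'
    'viz.R'
    'simulate.R'
    'cli.R'
    'clonalCCF-package.R'
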