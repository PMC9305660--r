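singleCloneTree <- function() {
    methods::new("CloneTree", members = list("A"),
                 ccf = matrix(1, 1, 1, dimnames = list(NULL, "0")),
                 parent = 0L, pattern = "linear", rank = 1L, timepoints = 0L)
}

test_that("a single clone at CCF 1 exports as [[100]] with root parent", {
    ex <- exportFishplot(singleCloneTree())
    expect_equal(unname(ex@fractions), matrix(100, 1, 1))
    expect_equal(parentVector(ex), 0L)
})

test_that("export enforces nesting and flags floored interior zeros", {
    tr <- methods::new("CloneTree", members = list("A", "B"),
                       ccf = matrix(c(0.9, 0.8, 0.9,
                                      0.4, 0.0, 0.3), 2, 3, byrow = TRUE),
                       parent = c(0L, 1L), pattern = "linear", rank = 1L,
                       timepoints = 0:2)
    ex <- exportFishplot(tr, floor_pct = 0.1)
    expect_equal(ex@fractions[2, 2], 0.1)
    expect_equal(ex@floors$clone, 2L)
    # columns stay nested after flooring
    for (j in 1:3)
        expect_lte(ex@fractions[2, j], ex@fractions[1, j] + 1e-9)

    bad <- methods::new("CloneTree", members = list("A", "B"),
                        ccf = matrix(c(0.3, 0.9), 2, 1),
                        parent = c(0L, 1L), pattern = "linear", rank = 1L,
                        timepoints = 0L)
    expect_error(exportFishplot(bad), "inadmissible")
})

test_that("reconstruction exports never violate column nesting", {
    for (n in c(3, 6, 7)) {
        for (tr in reconstructPatient(cohortPatient(n))) {
            ex <- exportFishplot(tr)
            fr <- ex@fractions
            for (j in seq_len(ncol(fr))) {
                expect_lte(sum(fr[ex@parent == 0L, j]), 100 + 1e-6)
                for (i in seq_len(nrow(fr))) {
                    ch <- which(ex@parent == i)
                    if (length(ch))
                        expect_lte(sum(fr[ch, j]), fr[i, j] + 1e-6)
                }
            }
            expect_true(all(fr >= 0 & fr <= 100))
        }
    }
})

test_that("rendering is pure: identical inputs give identical bytes", {
    tr <- reconstructPatient(cohortPatient(3))[[1]]
    ex <- addTransplantMarker(exportFishplot(tr), 0.5)
    f1 <- tempfile(fileext = ".svg"); f2 <- tempfile(fileext = ".svg")
    renderFishplot(ex, f1)
    renderFishplot(ex, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    svg <- readLines(f1)
    expect_match(svg[1], "^<svg ")
    expect_true(any(grepl("polygon", svg)))
})

test_that("a zero-clone export renders axes and annotations only", {
    ex <- methods::new("FishplotExport", fractions = matrix(0, 0, 1),
                       parent = integer(), positions = 0,
                       annotations = data.frame(position = 0,
                                                marker = "analysis"),
                       floors = data.frame(), cloneLabels = character())
    f <- tempfile(fileext = ".svg")
    renderFishplot(ex, f)
    svg <- paste(readLines(f), collapse = "")
    expect_match(svg, "polygon")                 # the triangle marker
    expect_match(svg, "line")
})

test_that("nested multi-clone layouts have valid geometry everywhere", {
    # 7 nested clones over 3 time points: bodies must keep lo <= hi and
    # children inside their parent's span at every interpolation sample
    ccf <- matrix(c(0.95, 0.95, 0.95,
                    0.70, 0.60, 0.80,
                    0.30, 0.20, 0.50,
                    0.10, 0.05, 0.20,
                    0.00, 0.10, 0.15,
                    0.20, 0.30, 0.10,
                    0.05, 0.02, 0.08), 7, 3, byrow = TRUE)
    parent <- c(0L, 1L, 2L, 3L, 3L, 2L, 6L)
    tr <- methods::new("CloneTree", members = as.list(LETTERS[1:7]),
                       ccf = ccf, parent = parent, pattern = "branched",
                       rank = 1L, timepoints = 0:2)
    ex <- exportFishplot(tr)
    dh <- clonalCCF:::.denseHeights(ex@fractions, ex@positions, 24L)
    for (j in seq_along(dh$x)) {
        st <- clonalCCF:::.stackColumn(dh$H[, j], parent)
        expect_true(all(st$hi - st$lo >= -1e-9))
        for (i in seq_len(7)) {
            p <- parent[i]
            if (p != 0L) {
                expect_gte(st$lo[i], st$lo[p] - 1e-9)
                expect_lte(st$hi[i], st$hi[p] + 1e-9)
            }
        }
    }
    f <- tempfile(fileext = ".svg")
    renderFishplot(ex, f)
    expect_true(file.size(f) > 0)
})

test_that("the CSV pair mirrors the export", {
    ex <- exportFishplot(reconstructPatient(cohortPatient(7))[[1]])
    d <- tempfile()
    writeFishplotCsv(ex, d)
    fr <- read.csv(file.path(d, "fractions.csv"))
    pa <- read.csv(file.path(d, "parents.csv"))
    expect_equal(nrow(fr), nrow(ex@fractions))
    expect_equal(pa$parent, ex@parent)
    expect_equal(as.matrix(fr[, -1]), ex@fractions, ignore_attr = TRUE)
})
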