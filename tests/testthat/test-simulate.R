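test_that("exactVaf equals the model equations on a simplex grid (spot set)", {
    grid <- simplexGrid(0.25)   # coarse grid here; full 0.05 grid in the
                                # acceptance suite
    for (type in c("deletion", "duplication")) {
        cvs <- if (type == "deletion") c(0L, 1L) else c(1L, 2L)
        for (cv in cvs) for (r in seq_len(nrow(grid))) {
            fr <- grid[r, ]
            pop <- populationFromOverlapCase(fr[1], fr[2], fr[3], fr[4],
                                             cv, type)
            expect_equal(exactVaf(pop, "L"),
                         predictVaf(fr[1], fr[2], fr[3], fr[4], cv, type),
                         tolerance = 1e-12)
        }
    }
})

test_that("population validity rejects malformed fractions and genotypes", {
    expect_error(CellPopulation(c(a = 0.6, b = 0.6),
        data.frame(clone_id = c("a", "b"), locus = "L",
                   mutant_copies = 0, total_copies = 2)), "sum to 1")
    expect_error(CellPopulation(c(a = 1),
        data.frame(clone_id = "a", locus = "L",
                   mutant_copies = 3, total_copies = 2)), "exceed")
    expect_error(populationFromOverlapCase(0.5, 0, 0, 0.5, 2, "deletion"),
                 "cnv_value")
})

test_that("high depth drives the simulated VAF to the exact value", {
    tree <- makeTruthTree()
    d <- file.path(tempdir(), "sim_lln")
    simulateObservations(tree, d, depth = 1e6, seed = 123)
    v <- read.delim(file.path(d, "variants.tsv"))
    truth <- cloneCCF(tree)
    # DNMT3A marks clone 2: exact VAF = CCF/2
    got <- v$vaf_percent[v$gene == "DNMT3A"] / 100
    expect_equal(got, truth[2, ] / 2, tolerance = 2e-3,
                 ignore_attr = TRUE)
})

test_that("the noiseless shortcut reproduces the truth tree exactly", {
    tree <- makeTruthTree()
    d <- file.path(tempdir(), "sim_exact")
    simulateObservations(tree, d, noiseless = TRUE, seed = 1)
    rec <- reconstructPatient(loadPatient(d))
    parents <- lapply(rec, parentVector)
    members <- lapply(rec, cloneMembers)
    hit <- FALSE
    for (i in seq_along(rec)) {
        if (identical(parents[[i]], parentVector(tree)) &&
            identical(lapply(members[[i]], sort), lapply(cloneMembers(tree), sort))) {
            hit <- TRUE
            expect_equal(cloneCCF(rec[[i]]), cloneCCF(tree),
                         tolerance = 1e-6, ignore_attr = TRUE)
        }
    }
    expect_true(hit)
})

test_that("simulation is reproducible from the seed and modality streams are split", {
    tree <- makeTruthTree()
    d1 <- file.path(tempdir(), "sim_a")
    d2 <- file.path(tempdir(), "sim_b")
    simulateObservations(tree, d1, seed = 99)
    simulateObservations(tree, d2, seed = 99)
    for (f in c("variants.tsv", "karyotype.tsv", "fish.tsv", "cgh.tsv"))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), label = f)
    d3 <- file.path(tempdir(), "sim_c")
    simulateObservations(tree, d3, seed = 100)
    expect_false(identical(readLines(file.path(d1, "variants.tsv")),
                           readLines(file.path(d3, "variants.tsv"))))
})

test_that("invalid sampling sizes are rejected", {
    tree <- makeTruthTree()
    expect_error(simulateObservations(tree, tempfile(), depth = 0), "positive")
    expect_error(simulateObservations(tree, tempfile(), n_metaphases = -1),
                 "positive")
})

test_that("truth files use the trees.json schema and diff against output", {
    tree <- makeTruthTree()
    d <- file.path(tempdir(), "sim_schema")
    simulateObservations(tree, d, noiseless = TRUE, seed = 5)
    truth <- readTrees(file.path(d, "truth.json"))
    expect_equal(length(truth), 1L)
    expect_identical(parentVector(truth[[1]]), parentVector(tree))
    expect_equal(cloneCCF(truth[[1]]), cloneCCF(tree), tolerance = 1e-12,
                 ignore_attr = TRUE)
})
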