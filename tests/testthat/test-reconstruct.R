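mkEst <- function(id, tp, ccf, half = 0.05) {
    data.frame(aberration_id = id, timepoint_index = as.integer(tp),
               ccf = ccf, ci_low = pmax(0, ccf - half),
               ci_high = pmin(1, ccf + half), source = "vaf", flags = "",
               stringsAsFactors = FALSE)
}

mkCloneSet <- function(ccf, delta_names = NULL) {
    n <- nrow(ccf)
    methods::new("CloneSet",
                 members = as.list(delta_names %||% LETTERS[seq_len(n)]),
                 ccf = ccf, se = ccf * 0 + 0.02)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("aberrations with close trajectories merge; distant ones do not", {
    est <- rbind(mkEst("a", 0, 0.99), mkEst("b", 0, 0.97))
    cs <- clusterAberrations(est, tol = 0.10)
    expect_equal(length(cloneMembers(cs)), 1L)

    est2 <- rbind(mkEst("a", 0, 0.99), mkEst("b", 0, 0.40))
    cs2 <- clusterAberrations(est2, tol = 0.10)
    expect_equal(length(cloneMembers(cs2)), 2L)
})

test_that("cannot-link pairs never share a clone", {
    est <- rbind(mkEst("WT1 a", 0, 0.10), mkEst("WT1 b", 0, 0.11),
                 mkEst("NRAS a", 0, 0.09))
    cs <- clusterAberrations(est, tol = 0.10,
                             cannotLink = list(c("WT1 a", "WT1 b")))
    mem <- cloneMembers(cs)
    together <- vapply(mem, function(m) all(c("WT1 a", "WT1 b") %in% m),
                       logical(1))
    expect_false(any(together))
})

test_that("patient 3 clusters into two clones (translocation + NF1 stemline)", {
    cs <- clusterAberrations(estimateCCFs(cohortPatient(3)), tol = 0.10)
    expect_equal(length(cloneMembers(cs)), 2L)
    stem <- cloneMembers(cs)[[1]]
    expect_true(all(c("NF1 c.2033del", "t(12;22)(p13;q11)") %in% stem))
})

test_that("tree enumeration matches the worked three-clone examples", {
    # A(1.0), B(0.6), C(0.3): chain or siblings, C can never be a root
    ccf <- matrix(c(1.0, 0.6, 0.3), 3, 1)
    trees <- buildCloneTrees(mkCloneSet(ccf), delta = 0)
    parents <- lapply(trees, parentVector)
    expect_equal(length(trees), 2L)
    expect_true(list(c(0L, 1L, 1L)) %in% parents)   # A -> {B, C}
    expect_true(list(c(0L, 1L, 2L)) %in% parents)   # A -> B -> C

    # A(1.0), B(0.6), C(0.5): siblings would sum to 1.1 > 1, so only the
    # chain survives at delta 0 and delta 0.05; at delta 0.10 the sibling
    # arrangement and the inverted chain A->C->B (0.6 <= 0.5 + 0.1) join
    # it — frozen from the brute-force parent-vector scan
    ccf2 <- matrix(c(1.0, 0.6, 0.5), 3, 1)
    expect_equal(lapply(buildCloneTrees(mkCloneSet(ccf2), delta = 0),
                        parentVector),
                 list(c(0L, 1L, 2L)))
    expect_equal(lapply(buildCloneTrees(mkCloneSet(ccf2), delta = 0.05),
                        parentVector),
                 list(c(0L, 1L, 2L)))
    t10 <- buildCloneTrees(mkCloneSet(ccf2), delta = 0.10)
    expect_equal(length(t10), 3L)
    expect_setequal(vapply(t10, function(t) paste(parentVector(t),
                                                  collapse = ","), ""),
                    c("0,1,1", "0,1,2", "0,3,1"))
})

test_that("single clone yields one linear tree", {
    trees <- buildCloneTrees(mkCloneSet(matrix(0.8, 1, 1)))
    expect_equal(length(trees), 1L)
    expect_equal(parentVector(trees[[1]]), 0L)
    expect_equal(evolutionPattern(trees[[1]]), "linear")
})

test_that("enumeration agrees with the brute-force parent-vector scan", {
    set.seed(7)
    for (rep in 1:12) {
        n <- sample(2:4, 1)
        nT <- sample(1:3, 1)
        ccf <- matrix(round(runif(n * nT), 2), n, nT)
        delta <- sample(c(0, 0.05, 0.1), 1)
        oracle <- bruteForceTrees(ccf, delta)
        got <- tryCatch(
            lapply(buildCloneTrees(mkCloneSet(ccf), delta = delta),
                   parentVector),
            error = function(e) list())
        expect_equal(length(got), length(oracle),
                     info = paste(c(delta, round(ccf, 2)), collapse = ","))
        expect_setequal(vapply(got, paste, "", collapse = ","),
                        vapply(oracle, paste, "", collapse = ","))
    }
})

test_that("appearance order forbids parents that arise later", {
    # B appears only at the second time point but is larger than A there;
    # it can neither nest under A nor coexist as a root
    ccf <- matrix(c(0.2, 0.2,
                    0.0, 0.9), 2, 2, byrow = TRUE)
    err <- tryCatch(buildCloneTrees(mkCloneSet(ccf), delta = 0.05),
                    error = function(e) e)
    expect_s3_class(err, "reconstruction_infeasible")
})

test_that("evolution patterns classify by child counts and sibling structure", {
    path <- methods::new("CloneTree", members = as.list(LETTERS[1:3]),
                         ccf = matrix(c(1, 0.6, 0.3), 3, 1),
                         parent = c(0L, 1L, 2L), rank = 1L,
                         timepoints = 0L)
    expect_equal(classifyEvolution(path), "linear")

    fork <- methods::new("CloneTree", members = as.list(LETTERS[1:3]),
                         ccf = matrix(c(1, 0.5, 0.3), 3, 1),
                         parent = c(0L, 1L, 1L), rank = 1L, timepoints = 0L)
    expect_equal(classifyEvolution(fork), "branched")

    # five coexisting small sibling subclones, none dominant
    star <- methods::new("CloneTree", members = as.list(LETTERS[1:6]),
                         ccf = matrix(c(0.9, rep(0.12, 5)), 6, 1),
                         parent = c(0L, rep(1L, 5)), rank = 1L,
                         timepoints = 0L)
    expect_equal(classifyEvolution(star), "neutral")
    # a dominant sibling defeats the neutral call
    dom <- star
    dom@ccf[2, 1] <- 0.6
    expect_equal(classifyEvolution(dom), "branched")
    # fewer siblings than k likewise
    expect_equal(classifyEvolution(star, k = 6L), "branched")
})

test_that("every emitted tree satisfies the nesting invariants", {
    for (n in c(2, 4, 6, 7)) {
        trees <- reconstructPatient(cohortPatient(n))
        for (tr in trees) {
            ccf <- cloneCCF(tr); parent <- parentVector(tr)
            for (j in seq_len(ncol(ccf))) {
                expect_lte(sum(ccf[parent == 0L, j]), 1 + 0.05 + 1e-9)
                for (i in seq_len(nrow(ccf))) {
                    ch <- which(parent == i)
                    if (length(ch))
                        expect_lte(sum(ccf[ch, j]), ccf[i, j] + 0.05 + 1e-9)
                }
            }
        }
    }
})

test_that("patient 6 yields alternative reconstructions, linear and branched", {
    trees <- reconstructPatient(cohortPatient(6))
    expect_gte(length(trees), 2L)
    patterns <- vapply(trees, evolutionPattern, "")
    expect_true("linear" %in% patterns)
    expect_true("branched" %in% patterns)
    # the alternatives come from different surviving overlap cases
    expect_gte(length(unique(vapply(trees, function(t) t@caseLabel, ""))), 2L)
    # the TP53-first (biallelic) case is the linear one
    lin <- trees[[which(patterns == "linear")[1]]]
    expect_match(lin@caseLabel, "scenario2")
})

test_that("remission time points force all clone CCFs to zero", {
    trees <- reconstructPatient(cohortPatient(7))
    for (tr in trees) {
        ccf <- cloneCCF(tr)
        expect_true(all(ccf[, 3] == 0))          # remission column
        stem <- which(vapply(cloneMembers(tr), function(m)
            "ins(9;12)(q34;p12p13)" %in% m, logical(1)))
        expect_gt(ccf[stem, 4], 0)               # stemline reappears at relapse
    }
})

test_that("a single-variant single-time-point bundle gives one linear tree", {
    d <- writePatientDir(
        file.path(tempdir(), "tiny"),
        config = list(patient = "t",
                      timepoints = list(list(index = 0, label = "initial",
                                             status = "initial")),
                      files = list(variants = "variants.tsv")),
        variants = data.frame(patient = "t", timepoint = 0, gene = "TP53",
                              hgvs_c = "c.427G>A", hgvs_p = "",
                              vaf_percent = 30, depth = NA, alt_reads = NA))
    trees <- reconstructPatient(loadPatient(d))
    expect_equal(length(trees), 1L)
    expect_equal(length(cloneMembers(trees[[1]])), 1L)
    expect_equal(evolutionPattern(trees[[1]]), "linear")
})

test_that("reconstruction is deterministic", {
    t1 <- reconstructPatient(cohortPatient(6))
    t2 <- reconstructPatient(cohortPatient(6))
    expect_identical(lapply(t1, parentVector), lapply(t2, parentVector))
    expect_identical(lapply(t1, cloneCCF), lapply(t2, cloneCCF))
    expect_identical(vapply(t1, function(x) x@caseLabel, ""),
                     vapply(t2, function(x) x@caseLabel, ""))
})
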