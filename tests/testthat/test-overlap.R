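test_that("predictVaf evaluates the allele-counting model", {
    expect_equal(predictVaf(0.375, 0.125, 0, 0.5, 1, "deletion"), 0.25)
    expect_equal(predictVaf(0.5, 0, 0, 0.5, 2, "duplication"), 0.4)
    # no mutated allele anywhere
    expect_equal(predictVaf(0, 0.3, 0, 0.7, 1, "deletion"), 0)
    expect_equal(predictVaf(0, 0.3, 0, 0.7, 1, "duplication"), 0)
    expect_error(predictVaf(0.3, 0.3, 0.3, 0.3, 1, "deletion"), "sum to 1")
})

test_that("the four cases solve in closed form with correct feasibility", {
    del <- enumerateOverlapCases(0.25, 0.5, "deletion")
    expect_equal(nrow(del), 4L)
    expect_equal(del$scenario, c(1L, 2L, 2L, 3L))
    expect_equal(del$cnv_value, c(1L, 0L, 1L, 1L))
    expect_equal(del$feasible, c(TRUE, TRUE, FALSE, TRUE))
    expect_equal(del$ccf_snv[del$scenario == 1], 0.375)
    expect_equal(del$ccf_snv[del$scenario == 2 & del$cnv_value == 0], 0.875)
    expect_equal(del$ccf_snv[del$scenario == 3], 0.375)
    expect_lt(del$y[del$scenario == 2 & del$cnv_value == 1], 0)   # negative y

    dup <- enumerateOverlapCases(0.4, 0.5, "duplication")
    expect_equal(dup$cnv_value, c(1L, 2L, 1L, 1L))
    expect_equal(dup$feasible, c(FALSE, TRUE, TRUE, FALSE))
    expect_equal(dup$ccf_snv[dup$scenario == 2 & dup$cnv_value == 2], 0.5)
    expect_equal(dup$y[dup$scenario == 2 & dup$cnv_value == 2], 0)
    expect_equal(dup$ccf_snv[dup$scenario == 2 & dup$cnv_value == 1], 1.0)
})

test_that("vaf = 0 means no variant except where the deletion erased it", {
    # with no variant reads, every case with a surviving variant allele
    # solves to CCF 0; the deletion/cnv_value=0 case is the one exception:
    # there the variant allele itself is deleted, VAF 0 is uninformative,
    # and the scenario-2 parametrization pins CCF_SNV to CCF_CNV
    del <- enumerateOverlapCases(0, 0.6, "deletion")
    expect_equal(del$ccf_snv[!(del$scenario == 2 & del$cnv_value == 0)],
                 rep(0, 3))
    expect_equal(del$ccf_snv[del$scenario == 2 & del$cnv_value == 0], 0.6)
    dup <- enumerateOverlapCases(0, 0.6, "duplication")
    expect_equal(dup$ccf_snv[dup$feasible], rep(0, 2))
})

test_that("ccf_cnv = 0 collapses every scenario to the heterozygous rule", {
    for (v in c(0.1, 0.25, 0.4)) for (type in c("deletion", "duplication")) {
        cases <- enumerateOverlapCases(v, 0, type)
        feas <- cases[cases$feasible, ]
        expect_true(all(abs(feas$ccf_snv_raw - 2 * v) < 1e-12))
    }
})

test_that("solved fractions always sum to one and round-trip the VAF", {
    set.seed(11)
    for (r in 1:200) {
        v <- runif(1); c0 <- runif(1)
        type <- sample(c("deletion", "duplication"), 1)
        cases <- enumerateOverlapCases(v, c0, type)
        expect_true(all(abs(cases$w + cases$x + cases$y + cases$z - 1) < 1e-9))
        for (i in which(cases$feasible)) {
            back <- predictVaf(cases$w[i], cases$x[i], cases$y[i], cases$z[i],
                               cases$cnv_value[i], type)
            expect_lt(abs(back - v), 1e-9)
        }
    }
})

test_that("infeasible cases have no brute-force realization either", {
    # grid-search oracle: when the closed form leaves [0,1], no lattice
    # point of the simplex reproduces the observed VAF for that case
    grid <- simplexGrid(0.05)
    checkNone <- function(v, c0, type, scenario, cv, eps) {
        zero_idx <- switch(scenario, `1` = 3L, `2` = 2L, `3` = 1L)
        for (r in seq_len(nrow(grid))) {
            fr <- grid[r, ]
            if (fr[zero_idx] != 0) next
            if (abs(fr[1] + fr[2] - c0) > eps) next    # must match CCF_CNV
            pv <- predictVaf(fr[1], fr[2], fr[3], fr[4], cv, type)
            if (abs(pv - v) <= eps) return(FALSE)
        }
        TRUE
    }
    cases <- enumerateOverlapCases(0.25, 0.5, "deletion", eps = 0.05)
    bad <- cases[!cases$feasible, ]
    for (i in seq_len(nrow(bad)))
        expect_true(checkNone(0.25, 0.5, "deletion", bad$scenario[i],
                              bad$cnv_value[i], 0.04))
    cases <- enumerateOverlapCases(0.4, 0.5, "duplication", eps = 0.05)
    bad <- cases[!cases$feasible, ]
    for (i in seq_len(nrow(bad)))
        expect_true(checkNone(0.4, 0.5, "duplication", bad$scenario[i],
                              bad$cnv_value[i], 0.04))
})

test_that("enumeration is continuous in vaf and ccf_cnv away from boundaries", {
    base <- enumerateOverlapCases(0.25, 0.5, "deletion")
    eps <- 1e-6
    pert <- enumerateOverlapCases(0.25 + eps, 0.5 - eps, "deletion")
    expect_equal(pert$ccf_snv, base$ccf_snv, tolerance = 1e-4)
    expect_equal(pert$feasible, base$feasible)
})

test_that("resolveOverlap returns survivors, flags ambiguity, errors on none", {
    amb <- resolveOverlap(0.4, 0.5, "duplication")
    expect_equal(nrow(amb), 2L)
    expect_true(all(grepl("ambiguous", amb$flags)))

    amb3 <- resolveOverlap(0.25, 0.5, "deletion")
    expect_equal(nrow(amb3), 3L)

    # degenerate no-CNV limit resolves to a single heterozygous estimate
    single <- resolveOverlap(0.25, 0, "deletion")
    expect_true(all(abs(single$ccf - 0.5) < 1e-12))

    expect_error(resolveOverlap(0.9, 0.05, "deletion", eps = 0.01),
                 "tolerance")
})

test_that("exactVaf on an explicit population equals the model equations", {
    pop <- populationFromOverlapCase(0.375, 0.125, 0, 0.5, 1, "deletion")
    expect_equal(exactVaf(pop, "L"), 0.25, tolerance = 1e-15)
    expect_equal(exactVaf(pop, "L"),
                 predictVaf(0.375, 0.125, 0, 0.5, 1, "deletion"),
                 tolerance = 1e-15)
    # all wild type
    wt <- CellPopulation(c(a = 1), data.frame(clone_id = "a", locus = "L",
                                              mutant_copies = 0,
                                              total_copies = 2))
    expect_equal(exactVaf(wt, "L"), 0)
    het <- CellPopulation(c(a = 1), data.frame(clone_id = "a", locus = "L",
                                               mutant_copies = 1,
                                               total_copies = 2))
    expect_equal(exactVaf(het, "L"), 0.5)
})
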