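test_that("the heterozygous rule doubles the VAF, with capping and hemizygous context", {
    expect_equal(ccfFromVaf(0.0050)$ccf, 0.0100)     # ~1% CCF at VAF 0.5%
    expect_equal(ccfFromVaf(0)$ccf, 0)
    capped <- ccfFromVaf(0.7376)                     # 2*VAF exceeds 1
    expect_equal(capped$ccf, 1)
    expect_match(capped$flags, "capped_at_1")
    hemi <- ccfFromVaf(0.6676, "hemizygous")
    expect_equal(hemi$ccf, 0.6676)
    expect_match(hemi$flags, "hemizygous_assumed")
    expect_error(ccfFromVaf(1.2), "\\[0, 1\\]")
})

test_that("ccfFromVaf is monotone non-decreasing in vaf", {
    vaf <- seq(0, 1, by = 0.01)
    ccf <- vapply(vaf, function(v) ccfFromVaf(v)$ccf, numeric(1))
    expect_true(all(diff(ccf) >= 0))
    hemi <- vapply(vaf, function(v) ccfFromVaf(v, "hemizygous")$ccf, numeric(1))
    expect_true(all(diff(hemi) >= 0))
})

test_that("count-based CCFs are proportions with Wilson 95% intervals", {
    expect_equal(ccfFromCounts(10, 20)$ccf, 0.5)
    z <- ccfFromCounts(0, 200)
    expect_equal(z$ccf, 0)
    expect_equal(z$ci_low, 0)
    est <- ccfFromCounts(120, 200)
    expect_equal(est$ccf, 0.6)
    # independent oracle: Wilson score interval from prop.test
    ref <- prop.test(120, 200, correct = FALSE)$conf.int
    expect_equal(est$ci_low, ref[1], tolerance = 1e-10)
    expect_equal(est$ci_high, ref[2], tolerance = 1e-10)
    expect_equal(round(c(est$ci_low, est$ci_high), 3), c(0.531, 0.665))
    expect_error(ccfFromCounts(1, 0), "positive")
    expect_error(ccfFromCounts(30, 20), "with <= total")
})

test_that("count CCF matches the mean of a Bernoulli resample", {
    set.seed(42)
    k <- 120; n <- 200
    est <- ccfFromCounts(k, n)$ccf
    draws <- rbinom(20000, n, k / n) / n
    se <- sd(draws) / sqrt(length(draws))
    expect_lt(abs(mean(draws) - est), 3 * se)
})

test_that("log2-ratio inversion recovers the mixed fraction", {
    expect_equal(ccfFromLog2Ratio(0, "loss")$ccf, 0)
    expect_equal(ccfFromLog2Ratio(0, "gain")$ccf, 0)
    expect_equal(ccfFromLog2Ratio(log2(0.75), "loss")$ccf, 0.5)
    expect_equal(ccfFromLog2Ratio(log2(1.25), "gain")$ccf, 0.5)
    expect_error(ccfFromLog2Ratio(0.3, "loss"), "loss")
    expect_error(ccfFromLog2Ratio(-0.3, "gain"), "gain")
})

test_that("log2 inversion is the exact inverse of the forward ratio model", {
    f <- seq(0, 1, by = 0.01)
    for (dir in c("loss", "gain")) {
        r <- vapply(f, clonalCCF:::.log2RatioFromCcf, numeric(1),
                    direction = dir)
        back <- vapply(seq_along(f), function(i)
            ccfFromLog2Ratio(r[i], dir)$ccf, numeric(1))
        expect_equal(back, f, tolerance = 1e-12)
    }
})

test_that("estimate combination is precision-weighted and keeps flags", {
    a <- ccfFromCounts(18, 20, "metaphase", "ab", 0L)
    b <- ccfFromCounts(180, 200, "fish", "ab", 0L)
    comb <- clonalCCF:::.combineEstimates(rbind(a, b))
    expect_equal(nrow(comb), 1L)
    expect_equal(comb$ccf, 0.9, tolerance = 0.01)
    # the 10x larger FISH sample dominates
    expect_lt(abs(comb$ccf - b$ccf), abs(comb$ccf - a$ccf) + 1e-12)
    expect_equal(comb$source, "fish+metaphase")
})
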