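## Cancer cell fraction estimation from single evidence modalities.
##
## A CCF estimate is a one-row data.frame so that estimates from many
## aberrations/time points rbind into a tidy table. Columns:
##   aberration_id, timepoint_index, ccf, ci_low, ci_high, source, flags
## `flags` is a comma-separated subset of
##   {capped_at_1, hemizygous_assumed, ambiguous, clipped}.

.newCcfEstimate <- function(ccf, ci_low, ci_high, source,
                            flags = character(),
                            aberration_id = NA_character_,
                            timepoint_index = NA_integer_) {
    stopifnot(ci_low - 1e-12 <= ccf, ccf <= ci_high + 1e-12,
              ci_low >= -1e-12, ci_high <= 1 + 1e-12)
    data.frame(aberration_id = aberration_id,
               timepoint_index = as.integer(timepoint_index),
               ccf = min(max(ccf, 0), 1),
               ci_low = min(max(ci_low, 0), 1),
               ci_high = min(max(ci_high, 0), 1),
               source = source,
               flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
}

.hasFlag <- function(est, flag) {
    vapply(strsplit(est$flags, ","), function(f) flag %in% f, logical(1))
}

## Wilson 95% score interval for a binomial proportion.
.wilsonCI <- function(k, n, conf = 0.95) {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    p <- k / n
    denom <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / denom
    half <- z / denom * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
    c(max(0, center - half), min(1, center + half))
}

## Default half-width of the uncertainty band when no count data back an
## estimate; also the CI fallback for log2-ratio estimates.
.DEFAULT_CI_HALFWIDTH <- 0.05

#' CCF from a variant allele frequency
#'
#' Applies the heterozygous rule CCF = 2*VAF for autosomal variants; for
#' hemizygous loci (X/Y in males) each cell carries a single allele, so
#' CCF = VAF. Values exceeding 1 are capped and flagged rather than being
#' interpreted as loss of heterozygosity.
#'
#' @param vaf variant allele frequency in `[0, 1]`.
#' @param copy_context "autosomal_het" (default) or "hemizygous".
#' @param depth,alt_reads optional read counts; when given, the confidence
#'   interval is the Wilson 95% binomial interval on the VAF, transformed;
#'   otherwise a fixed ±0.05 band is used.
#' @param aberration_id,timepoint_index optional identifiers carried into
#'   the estimate row.
#' @return One-row CCF estimate data.frame (source "vaf").
#' @examples
#' ccfFromVaf(0.0050)           # 1% CCF
#' ccfFromVaf(0.7376)$flags     # capped_at_1
#' @export
ccfFromVaf <- function(vaf, copy_context = c("autosomal_het", "hemizygous"),
                       depth = NULL, alt_reads = NULL,
                       aberration_id = NA_character_,
                       timepoint_index = NA_integer_) {
    copy_context <- match.arg(copy_context)
    if (is.na(vaf) || vaf < 0 || vaf > 1)
        stop("vaf must lie in [0, 1]")
    mult <- if (copy_context == "autosomal_het") 2 else 1
    flags <- character()
    if (copy_context == "hemizygous") flags <- c(flags, "hemizygous_assumed")
    raw <- mult * vaf
    ccf <- min(1, raw)
    if (raw > 1) flags <- c(flags, "capped_at_1")
    if (!is.null(depth) && !is.null(alt_reads) &&
        !is.na(depth) && !is.na(alt_reads) && depth > 0) {
        ci <- .wilsonCI(alt_reads, depth) * mult
    } else {
        ci <- c(raw - .DEFAULT_CI_HALFWIDTH * mult,
                raw + .DEFAULT_CI_HALFWIDTH * mult)
    }
    .newCcfEstimate(ccf, max(0, min(ci[1], ccf)), min(1, max(ci[2], ccf)),
                    "vaf", flags, aberration_id, timepoint_index)
}

#' CCF from cell counts
#'
#' Proportion of carrier cells among counted cells (metaphases in
#' karyotyping, interphase nuclei in FISH), with a Wilson 95% binomial
#' confidence interval.
#'
#' @param with number of cells carrying the aberration.
#' @param total number of cells examined (> 0).
#' @param source "metaphase" or "fish".
#' @param aberration_id,timepoint_index optional identifiers.
#' @return One-row CCF estimate data.frame.
#' @examples
#' ccfFromCounts(10, 20)
#' ccfFromCounts(120, 200)   # Wilson CI about [0.531, 0.665]
#' @export
ccfFromCounts <- function(with, total, source = c("metaphase", "fish"),
                          aberration_id = NA_character_,
                          timepoint_index = NA_integer_) {
    source <- match.arg(source)
    if (is.na(total) || total <= 0)
        stop("total cell count must be positive")
    if (is.na(with) || with < 0 || with > total)
        stop("carrier count must satisfy 0 <= with <= total")
    ci <- .wilsonCI(with, total)
    .newCcfEstimate(with / total, ci[1], ci[2], source,
                    character(), aberration_id, timepoint_index)
}

#' CCF from an array-CGH log2 ratio
#'
#' Inverts the one-copy-change mixture model in a diploid background: a
#' fraction f of cells losing one copy gives a tumor/reference intensity
#' ratio (2 - f)/2, a fraction gaining one copy gives (2 + f)/2. Hence
#' f = 2 - 2^(log2_ratio + 1) for losses and f = 2^(log2_ratio + 1) - 2 for
#' gains. The result is clipped to `[0, 1]` and flagged when clipping
#' occurs. The model is a deliberate simplification: it ignores tumor
#' purity, multi-copy amplifications and subclonal copy-number mixtures.
#'
#' @param log2_ratio observed log2 fluorescence ratio; its sign must match
#'   `direction`.
#' @param direction "loss" or "gain".
#' @param aberration_id,timepoint_index optional identifiers.
#' @return One-row CCF estimate data.frame (source "cgh").
#' @examples
#' ccfFromLog2Ratio(log2(0.75), "loss")   # CCF 0.5
#' ccfFromLog2Ratio(log2(1.25), "gain")   # CCF 0.5
#' @export
ccfFromLog2Ratio <- function(log2_ratio, direction = c("loss", "gain"),
                             aberration_id = NA_character_,
                             timepoint_index = NA_integer_) {
    direction <- match.arg(direction)
    if (is.na(log2_ratio)) stop("log2_ratio must be numeric")
    if (direction == "loss" && log2_ratio > 0)
        stop("loss requires log2_ratio <= 0")
    if (direction == "gain" && log2_ratio < 0)
        stop("gain requires log2_ratio >= 0")
    raw <- if (direction == "loss") 2 - 2^(log2_ratio + 1)
           else 2^(log2_ratio + 1) - 2
    flags <- character()
    if (raw < 0 || raw > 1) flags <- "clipped"
    ccf <- min(1, max(0, raw))
    .newCcfEstimate(ccf, max(0, ccf - .DEFAULT_CI_HALFWIDTH),
                    min(1, ccf + .DEFAULT_CI_HALFWIDTH), "cgh",
                    flags, aberration_id, timepoint_index)
}

## Forward CGH ratio model, the inverse of ccfFromLog2Ratio (used by the
## simulator and the round-trip tests).
.log2RatioFromCcf <- function(f, direction) {
    if (direction == "loss") log2((2 - f) / 2) else log2((2 + f) / 2)
}

## Precision-weighted combination of estimate rows for the same aberration
## and time point. Weights are inverse squared standard errors derived from
## the CI half-widths.
.combineEstimates <- function(est) {
    if (nrow(est) == 1L) return(est)
    se <- pmax((est$ci_high - est$ci_low) / (2 * 1.96), 1e-3)
    w <- 1 / se^2
    ccf <- sum(w * est$ccf) / sum(w)
    se_c <- 1 / sqrt(sum(w))
    flags <- unique(unlist(strsplit(est$flags[nzchar(est$flags)], ",")))
    .newCcfEstimate(ccf, max(0, ccf - 1.96 * se_c), min(1, ccf + 1.96 * se_c),
                    paste(sort(unique(est$source)), collapse = "+"),
                    flags, est$aberration_id[1], est$timepoint_index[1])
}
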