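## Scenario engine for an SNV/indel whose locus is covered by a CNV.
##
## Cell classes: w = cells carrying both the CNV and the SNV/indel,
## x = CNV only, y = SNV/indel only, z = neither; w + x + y + z = 1 and
## CCF_CNV = w + x. The bulk VAF of the variant follows from allele
## counting over the classes:
##
##   VAF = (cnv_value*w + y) / (1*w + 1*x + 2*y + 2*z)   CNV is a deletion
##   VAF = (cnv_value*w + y) / (3*w + 3*x + 2*y + 2*z)   CNV is a duplication
##
## cnv_value is the number of variant-carrying alleles in the w cells.
## Three scenarios order the two events:
##   scenario 1 - CNV first, variant arises within the CNV clone: y = 0,
##                cnv_value = 1, CCF_SNV = w;
##   scenario 2 - variant first, CNV arises within the variant clone: x = 0,
##                w = CCF_CNV, CCF_SNV = w + y; cnv_value is 0 or 1 for a
##                deletion (variant allele deleted or spared) and 2 or 1 for
##                a duplication (variant allele duplicated or not);
##   scenario 3 - the two events in parallel clones: w = 0, cnv_value = 1,
##                CCF_SNV = y.
## Scenario 2 contributes two cases, so four cases in total. A case whose
## solved fractions leave [0, 1] breaks the w+x+y+z = 1 assumption and is
## excluded (up to the tolerance eps).

.CASE_GRID <- data.frame(
    scenario  = c(1L, 2L, 2L, 3L),
    del_value = c(1L, 0L, 1L, 1L),
    dup_value = c(1L, 2L, 1L, 1L))

#' Predicted bulk VAF of an overlap-case cell configuration
#'
#' Evaluates the allele-counting model for given cell fractions: the variant
#' allele count is `cnv_value*w + y`, the total allele count at the locus is
#' `w + x + 2y + 2z` under a deletion (CNV cells keep one copy) and
#' `3w + 3x + 2y + 2z` under a duplication (CNV cells carry three copies).
#'
#' @param w,x,y,z cell-class fractions, summing to 1 (tolerance 1e-9).
#' @param cnv_value number of variant alleles in the w cells (0, 1 or 2).
#' @param cnv_type "deletion" or "duplication".
#' @return The model VAF.
#' @examples
#' predictVaf(0.375, 0.125, 0, 0.5, cnv_value = 1, cnv_type = "deletion")
#' @export
predictVaf <- function(w, x, y, z, cnv_value,
                       cnv_type = c("deletion", "duplication")) {
    cnv_type <- match.arg(cnv_type)
    if (abs(w + x + y + z - 1) > 1e-9)
        stop("cell fractions must sum to 1")
    cn <- if (cnv_type == "deletion") 1 else 3
    denom <- cn * w + cn * x + 2 * y + 2 * z
    if (denom == 0)
        stop("no allele copies present: all cell fractions are zero")
    (cnv_value * w + y) / denom
}

## Closed-form solution of one case. The allele-total denominator is
## constant within a cnv_type: D = 2 - c for a deletion, 2 + c for a
## duplication, where c = CCF_CNV. Each scenario pins two fractions and the
## remaining two follow linearly from the observed VAF.
.solveCase <- function(vaf, ccf_cnv, cnv_type, scenario, cnv_value) {
    c0 <- ccf_cnv
    D <- if (cnv_type == "deletion") 2 - c0 else 2 + c0
    if (scenario == 1L) {
        w <- vaf * D
        x <- c0 - w; y <- 0; z <- 1 - c0
        ccf_snv <- w
    } else if (scenario == 2L) {
        w <- c0; x <- 0
        y <- vaf * D - cnv_value * c0
        z <- 1 - c0 - y
        ccf_snv <- c0 + y
    } else {
        w <- 0; x <- c0
        y <- vaf * D
        z <- 1 - c0 - y
        ccf_snv <- y
    }
    list(w = w, x = x, y = y, z = z, ccf_snv = ccf_snv)
}

#' Enumerate the four CNV/SNV overlap cases
#'
#' Solves the cell-fraction model in closed form for all four cases
#' (scenario 1; scenario 2 with each of its two cnv_values; scenario 3) and
#' marks each as feasible or excluded. The solved fractions always satisfy
#' w + x + y + z = 1 exactly; infeasibility shows up as fractions outside
#' `[0, 1]`, and the `violation` column records the total mass by which they
#' leave that range (0 when feasible at tolerance 0).
#'
#' @param vaf observed variant allele frequency in `[0, 1]`.
#' @param ccf_cnv known CCF of the copy-number event in `[0, 1]`.
#' @param cnv_type "deletion" or "duplication" (duplication means exactly
#'   one gained copy; higher amplifications are out of model scope).
#' @param eps feasibility tolerance on the fractions (absolute), default
#'   0.05: counted CCFs and deep VAFs are noisy, and an exact-zero rule
#'   would discard cases that the data support.
#' @return A data.frame with one row per case: `scenario`, `cnv_value`,
#'   `cnv_type`, `w`, `x`, `y`, `z`, `vaf`, `ccf_cnv`, `ccf_snv` (clipped to
#'   `[0, 1]`), `ccf_snv_raw`, `feasible`, `violation`.
#' @examples
#' enumerateOverlapCases(0.25, 0.5, "deletion")
#' @export
enumerateOverlapCases <- function(vaf, ccf_cnv,
                                  cnv_type = c("deletion", "duplication"),
                                  eps = 0.05) {
    cnv_type <- match.arg(cnv_type)
    if (is.na(vaf) || vaf < 0 || vaf > 1)
        stop("vaf must lie in [0, 1]")
    if (is.na(ccf_cnv) || ccf_cnv < 0 || ccf_cnv > 1)
        stop("ccf_cnv must lie in [0, 1]")
    cases <- .CASE_GRID
    cases$cnv_value <- if (cnv_type == "deletion") cases$del_value else
        cases$dup_value
    out <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
        s <- .solveCase(vaf, ccf_cnv, cnv_type,
                        cases$scenario[i], cases$cnv_value[i])
        fr <- c(s$w, s$x, s$y, s$z)
        violation <- sum(pmax(0, -fr)) + sum(pmax(0, fr - 1))
        data.frame(scenario = cases$scenario[i],
                   cnv_value = cases$cnv_value[i],
                   cnv_type = cnv_type,
                   w = s$w, x = s$x, y = s$y, z = s$z,
                   vaf = vaf, ccf_cnv = ccf_cnv,
                   ccf_snv = min(1, max(0, s$ccf_snv)),
                   ccf_snv_raw = s$ccf_snv,
                   feasible = violation <= eps,
                   violation = violation,
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Resolve an overlap to CCF estimates
#'
#' Filters the four cases to the feasible ones and converts each surviving
#' case into a CCF estimate for the variant. A unique survivor yields a
#' single unambiguous estimate; several survivors are all returned, flagged
#' `ambiguous`, so that downstream reconstruction can branch over them (no
#' tie-breaking is attempted here: ordering the two events is a biological
#' question the data alone may not answer).
#'
#' @inheritParams enumerateOverlapCases
#' @param aberration_id,timepoint_index optional identifiers.
#' @return CCF estimate data.frame (source "overlap_model"), one row per
#'   surviving case, with columns `scenario` and `cnv_value` appended.
#' @examples
#' resolveOverlap(0.4, 0.5, "duplication")   # two cases, ambiguous
#' @export
resolveOverlap <- function(vaf, ccf_cnv,
                           cnv_type = c("deletion", "duplication"),
                           eps = 0.05, aberration_id = NA_character_,
                           timepoint_index = NA_integer_) {
    cases <- enumerateOverlapCases(vaf, ccf_cnv, cnv_type, eps)
    surv <- cases[cases$feasible, , drop = FALSE]
    if (!nrow(surv))
        stop(sprintf(paste0(
            "no overlap case satisfies w+x+y+z=1 at eps=%g ",
            "(smallest violation %.4f); review the tolerance or the ",
            "input CCF/VAF for consistency"), eps, min(cases$violation)))
    ambiguous <- nrow(surv) > 1L
    out <- do.call(rbind, lapply(seq_len(nrow(surv)), function(i) {
        flags <- character()
        if (ambiguous) flags <- c(flags, "ambiguous")
        if (surv$ccf_snv_raw[i] > 1) flags <- c(flags, "capped_at_1")
        est <- .newCcfEstimate(surv$ccf_snv[i],
                               max(0, surv$ccf_snv[i] - .DEFAULT_CI_HALFWIDTH),
                               min(1, surv$ccf_snv[i] + .DEFAULT_CI_HALFWIDTH),
                               "overlap_model", flags,
                               aberration_id, timepoint_index)
        est$scenario <- surv$scenario[i]
        est$cnv_value <- surv$cnv_value[i]
        est
    }))
    rownames(out) <- NULL
    out
}
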