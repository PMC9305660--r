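## Clonal reconstruction: CCF estimation across modalities, clustering of
## aberrations into clones, exhaustive enumeration of admissible clone
## trees, and classification of the evolution pattern.

.RECONSTRUCTION_INFEASIBLE <- function(message) {
    structure(class = c("reconstruction_infeasible", "error", "condition"),
              list(message = message, call = NULL))
}

## ---------------------------------------------------------------------------
## Per-aberration CCF estimates
## ---------------------------------------------------------------------------

## Effective copy-number view of an aberration: its own direction/region for
## kind=cnv, or a config-declared CNV effect for an SV (e.g. a derivative
## chromosome known to delete a tumor suppressor locus).
.effectiveCnv <- function(ab_row, config) {
    if (ab_row$kind == "cnv")
        return(list(direction = ab_row$cnv_direction, chrom = ab_row$chrom,
                    arm = ab_row$arm, lo = ab_row$band_start,
                    hi = ab_row$band_end))
    for (eff in config$cnv_effects %||% list()) {
        if (identical(eff$id, ab_row$id)) {
            iv <- if (!is.null(eff$region)) .parseBandInterval(eff$region)
                  else list(arm = "*", lo = 0, hi = Inf)
            return(list(direction = eff$direction,
                        chrom = eff$chrom %||% ab_row$chrom,
                        arm = iv$arm, lo = iv$lo, hi = iv$hi))
        }
    }
    NULL
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Estimate CCFs for every aberration and time point of a bundle
#'
#' Variants use the heterozygous 2*VAF rule (hemizygous for X/Y loci when
#' the patient config declares `sex: male`); cytogenetic aberrations use
#' carrier-cell proportions from karyotyping and FISH, combined by inverse-
#' variance weighting when both are available; aberrations seen only in
#' array-CGH fall back to the log2-ratio inversion. CNV/SNV overlap
#' resolution is not applied here — see [reconstructPatient()].
#'
#' @param bundle a [PatientBundle-class].
#' @return CCF estimate data.frame, one row per aberration and time point
#'   with evidence.
#' @export
estimateCCFs <- function(bundle) {
    stopifnot(is(bundle, "PatientBundle"))
    ab <- bundle@aberrations
    sex <- bundle@config$sex %||% "unknown"
    rows <- list()
    v <- bundle@variantObs
    for (i in seq_len(nrow(v))) {
        gene <- ab$gene[match(v$aberration_id[i], ab$id)]
        gb <- if (!is.na(gene)) geneBand(gene) else NULL
        ctx <- if (!is.null(gb) && gb$chrom %in% c("X", "Y") &&
                   identical(sex, "male")) "hemizygous" else "autosomal_het"
        rows[[length(rows) + 1L]] <- ccfFromVaf(
            v$vaf[i], ctx, v$depth[i], v$alt_reads[i],
            v$aberration_id[i], v$timepoint_index[i])
    }
    k <- bundle@karyotypeObs
    f <- bundle@fishObs
    g <- bundle@cghObs
    cyto <- ab$id[!ab$kind %in% c("snv", "indel")]
    for (id in cyto) for (tp in bundle@timepoints$index) {
        parts <- list()
        kt <- k[k$timepoint_index == tp, , drop = FALSE]
        if (nrow(kt)) {
            ## a performed karyotype is evidence even when the aberration is
            ## absent from every counted metaphase (0/total)
            hit <- vapply(strsplit(kt$aberration_ids, ","),
                          function(ids) id %in% ids, logical(1))
            with_n <- sum(kt$metaphases_with[hit])
            total <- max(kt$metaphases_total)
            parts[[length(parts) + 1L]] <- ccfFromCounts(
                with_n, total, "metaphase", id, tp)
        }
        ft <- f[f$timepoint_index == tp & f$aberration_id %in% id, , drop = FALSE]
        for (i in seq_len(nrow(ft)))
            parts[[length(parts) + 1L]] <- ccfFromCounts(
                ft$nuclei_with[i], ft$nuclei_total[i], "fish", id, tp)
        if (!length(parts)) {
            gt <- g[g$timepoint_index == tp & g$aberration_id %in% id, ,
                    drop = FALSE]
            for (i in seq_len(nrow(gt)))
                parts[[length(parts) + 1L]] <- ccfFromLog2Ratio(
                    gt$log2_ratio[i], gt$direction[i], id, tp)
        }
        if (length(parts))
            rows[[length(rows) + 1L]] <- .combineEstimates(do.call(rbind, parts))
    }
    out <- if (length(rows)) do.call(rbind, rows) else
        .newCcfEstimate(0, 0, 0, "vaf")[0, ]
    rownames(out) <- NULL
    out
}

## ---------------------------------------------------------------------------
## Clustering
## ---------------------------------------------------------------------------

#' Cluster aberrations into clones by CCF trajectory
#'
#' Aberrations whose CCF trajectories agree at every shared time point —
#' within an absolute tolerance or with overlapping 95% intervals, whichever
#' is more permissive — are merged into one clone. Time points without an
#' estimate count as CCF 0 (not detected). Assignment is greedy in order of
#' decreasing overall CCF and requires compatibility with every member of
#' the receiving clone, so the result is deterministic. The clone CCF per
#' time point is the precision-weighted mean of its members.
#'
#' @param estimates CCF estimate data.frame (see [estimateCCFs()]).
#' @param tol absolute CCF tolerance, default 0.10.
#' @param timepoints integer vector of time point indices to use (default:
#'   all that occur in `estimates`).
#' @param cannotLink list of character pairs of aberration ids that must not
#'   share a clone (e.g. distinct hotspot variants of one gene interpreted
#'   as independent subclones).
#' @return A [CloneSet-class], clones ordered by first appearance and then
#'   by decreasing CCF.
#' @export
clusterAberrations <- function(estimates, tol = 0.10, timepoints = NULL,
                               cannotLink = NULL) {
    if (!nrow(estimates)) stop("no estimates to cluster")
    tps <- sort(unique(c(timepoints, estimates$timepoint_index)))
    ids <- unique(estimates$aberration_id)
    nT <- length(tps)
    ccf <- matrix(0, length(ids), nT, dimnames = list(ids, tps))
    lo <- ccf; hi <- ccf
    hi[] <- .DEFAULT_CI_HALFWIDTH   # absence: 0 with a small upper bound
    for (r in seq_len(nrow(estimates))) {
        i <- match(estimates$aberration_id[r], ids)
        j <- match(estimates$timepoint_index[r], tps)
        ccf[i, j] <- estimates$ccf[r]
        lo[i, j] <- estimates$ci_low[r]
        hi[i, j] <- estimates$ci_high[r]
    }
    se <- pmax((hi - lo) / (2 * 1.96), 0.01)
    clMean <- function(mem) {
        w <- 1 / se[mem, , drop = FALSE]^2
        m <- colSums(ccf[mem, , drop = FALSE] * w) / colSums(w)
        list(m = m, se = 1 / sqrt(colSums(w)))
    }
    forbidden <- function(memA, memB) {
        idsA <- ids[memA]; idsB <- ids[memB]
        any(vapply(cannotLink %||% list(), function(p)
            (p[1] %in% idsA && p[2] %in% idsB) ||
            (p[2] %in% idsA && p[1] %in% idsB), logical(1)))
    }
    ## compatible when the trajectories agree within tol at every time
    ## point, or the 95% bands around the two (cluster-mean) trajectories
    ## overlap — whichever is more permissive
    compatMeans <- function(a, b) {
        all(abs(a$m - b$m) <= tol |
            (a$m - 1.96 * a$se <= b$m + 1.96 * b$se &
             b$m - 1.96 * b$se <= a$m + 1.96 * a$se))
    }
    ord <- order(-apply(ccf, 1, max), ids[seq_along(ids)])
    clusters <- list()
    for (i in ord) {
        ei <- clMean(i)
        placed <- FALSE
        for (ci in seq_along(clusters)) {
            mem <- clusters[[ci]]
            if (compatMeans(ei, clMean(mem)) && !forbidden(i, mem)) {
                clusters[[ci]] <- c(mem, i); placed <- TRUE; break
            }
        }
        if (!placed) clusters[[length(clusters) + 1L]] <- i
    }
    ## merge whole clusters until stable: an aberration stranded by the
    ## greedy pass (assignment order matters for borderline trajectories)
    ## still joins the clone whose mean it matches
    repeat {
        merged <- FALSE
        for (a in seq_along(clusters)) {
            for (b in seq_along(clusters)) {
                if (a >= b) next
                if (compatMeans(clMean(clusters[[a]]), clMean(clusters[[b]])) &&
                    !forbidden(clusters[[a]], clusters[[b]])) {
                    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
                    clusters[[b]] <- NULL
                    merged <- TRUE
                    break
                }
            }
            if (merged) break
        }
        if (!merged) break
    }
    n <- length(clusters)
    cl_ccf <- matrix(0, n, nT, dimnames = list(NULL, tps))
    cl_se <- cl_ccf
    members <- vector("list", n)
    for (ci in seq_len(n)) {
        mem <- clusters[[ci]]
        members[[ci]] <- ids[mem]
        est <- clMean(mem)
        cl_ccf[ci, ] <- est$m
        cl_se[ci, ] <- est$se
    }
    first_tp <- apply(cl_ccf, 1, function(x) {
        nz <- which(x > 1e-9); if (length(nz)) nz[1] else nT + 1L })
    ord2 <- order(first_tp, -apply(cl_ccf, 1, max))
    new("CloneSet", members = members[ord2],
        ccf = cl_ccf[ord2, , drop = FALSE],
        se = cl_se[ord2, , drop = FALSE])
}

## ---------------------------------------------------------------------------
## Tree enumeration
## ---------------------------------------------------------------------------

## is `anc` an ancestor of `node` (or the node itself when orEqual)?
.isAncestor <- function(parent, anc, node, orEqual = FALSE) {
    if (orEqual && anc == node) return(TRUE)
    j <- node
    while (parent[j] != 0L) {
        j <- parent[j]
        if (j == anc) return(TRUE)
    }
    FALSE
}

.checkTreeConstraints <- function(parent, constraints) {
    for (cs in constraints %||% list()) {
        if (cs$type == "ancestor_or_equal") {
            if (!.isAncestor(parent, cs$anc, cs$desc, orEqual = TRUE))
                return(FALSE)
        } else if (cs$type == "independent") {
            if (cs$a == cs$b) return(FALSE)
            if (.isAncestor(parent, cs$a, cs$b) ||
                .isAncestor(parent, cs$b, cs$a)) return(FALSE)
        }
    }
    TRUE
}

#' Enumerate all admissible clone trees
#'
#' Exhaustive search over parent assignments subject to the nesting
#' constraints: at every time point the CCFs of a clone's children sum to at
#' most the clone's CCF plus slack `delta`, root clones sum to at most
#' 1 + `delta`, and a clone cannot appear (first nonzero CCF) before its
#' parent. Trees are returned fewest-roots-first, then in lexicographic
#' order of the parent vector, each classified by [classifyEvolution()].
#'
#' @param clones a [CloneSet-class].
#' @param delta nesting slack on CCF sums, default 0.05 (counted CCFs are
#'   noisy).
#' @param constraints optional list of ancestry constraints, each
#'   `list(type = "ancestor_or_equal", anc =, desc =)` or
#'   `list(type = "independent", a =, b =)` with clone indices.
#' @param maxTrees cap on the number of trees returned (deterministic
#'   truncation of the search, with a warning).
#' @param neutralSiblings,dominance forwarded to [classifyEvolution()].
#' @return List of [CloneTree-class] objects, `rank` set by output order.
#' @export
buildCloneTrees <- function(clones, delta = 0.05, constraints = NULL,
                            maxTrees = 1000L, neutralSiblings = 4L,
                            dominance = 0.5) {
    stopifnot(is(clones, "CloneSet"))
    ccf <- clones@ccf
    n <- nrow(ccf)
    if (n == 0L) stop("no clones to arrange")
    nT <- ncol(ccf)
    first_tp <- apply(ccf, 1, function(x) {
        nz <- which(x > 1e-9); if (length(nz)) nz[1] else Inf })
    ## candidate parents: root (0) or clones that appear no later and are
    ## at least as large (within slack) at every time point
    cand <- lapply(seq_len(n), function(i) {
        js <- setdiff(seq_len(n), i)
        js <- js[first_tp[js] <= first_tp[i] &
                 vapply(js, function(j) all(ccf[i, ] <= ccf[j, ] + delta),
                        logical(1))]
        c(0L, js)
    })
    parent <- integer(n)
    childsum <- matrix(0, n + 1L, nT)   # row 1 = virtual root
    results <- list()
    firstViolation <- NULL
    recurse <- function(i) {
        if (length(results) >= maxTrees) return()
        if (i > n) {
            if (.checkTreeConstraints(parent, constraints))
                results[[length(results) + 1L]] <<- parent
            return()
        }
        for (p in cand[[i]]) {
            ## cycle check: walking up from p must not reach i
            ok <- TRUE; j <- p
            while (j != 0L) {
                if (j == i) { ok <- FALSE; break }
                j <- parent[j]
            }
            if (!ok) next
            limit <- if (p == 0L) 1 else ccf[p, ]
            newsum <- childsum[p + 1L, ] + ccf[i, ]
            if (any(newsum > limit + delta)) {
                if (is.null(firstViolation))
                    firstViolation <<- sprintf(
                        "children of %s exceed CCF %s at a time point",
                        if (p == 0L) "root" else paste("clone", p),
                        if (p == 0L) "1" else sprintf("%.3f", min(limit)))
                next
            }
            parent[i] <<- p
            childsum[p + 1L, ] <<- newsum
            recurse(i + 1L)
            childsum[p + 1L, ] <<- childsum[p + 1L, ] - ccf[i, ]
            parent[i] <<- 0L
        }
    }
    recurse(1L)
    if (!length(results))
        stop(.RECONSTRUCTION_INFEASIBLE(paste0(
            "no admissible clone tree: ",
            firstViolation %||% "ancestry constraints exclude all assignments")))
    nroots <- vapply(results, function(p) sum(p == 0L), integer(1))
    key <- vapply(results, function(p)
        paste(sprintf("%03d", p), collapse = ""), character(1))
    ord <- order(nroots, key)
    if (length(results) >= maxTrees)
        warning(sprintf("tree enumeration truncated at %d trees", maxTrees))
    tp_idx <- if (!is.null(colnames(ccf))) as.integer(colnames(ccf))
              else seq_len(nT) - 1L
    lapply(seq_along(ord), function(r) {
        tr <- new("CloneTree", members = clones@members, ccf = ccf,
                  parent = results[[ord[r]]], rank = as.integer(r),
                  timepoints = as.integer(tp_idx))
        tr@pattern <- classifyEvolution(tr, k = neutralSiblings,
                                        dominance = dominance)
        tr
    })
}

#' Classify the evolution pattern of a clone tree
#'
#' Linear evolution: every clone (including the implicit root of the tree)
#' has at most one child — a stepwise chain of sweeps. Branching evolution:
#' some clone has two or more coexisting child subclones. Neutral evolution,
#' the extreme of branching: at some time point at least `k` sibling
#' subclones coexist and none of them reaches the dominance threshold — many
#' independent subclones accumulating without a selective sweep.
#'
#' @param tree a [CloneTree-class].
#' @param k minimum number of coexisting sibling subclones for the neutral
#'   call, default 4.
#' @param dominance CCF a sibling must stay below for the neutral call,
#'   default 0.5.
#' @return "linear", "branched" or "neutral".
#' @export
classifyEvolution <- function(tree, k = 4L, dominance = 0.5) {
    stopifnot(is(tree, "CloneTree"))
    parent <- tree@parent
    ccf <- tree@ccf
    n <- length(parent)
    nchildren <- tabulate(parent + 1L, nbins = n + 1L)
    if (all(nchildren <= 1L)) return("linear")
    for (p in 0:n) {
        ch <- which(parent == p)
        if (length(ch) < k) next
        for (j in seq_len(ncol(ccf))) {
            live <- ch[ccf[ch, j] > 1e-9]
            if (length(live) >= k && all(ccf[live, j] < dominance))
                return("neutral")
        }
    }
    "branched"
}

## ---------------------------------------------------------------------------
## Full pipeline
## ---------------------------------------------------------------------------

## Surviving overlap cases for one (variant, cnv) pair, joint across all
## time points where both events are present. Returns a list of cases, each
## carrying per-time-point resolved CCFs, or NULL if the pair never
## co-occurs.
.overlapSurvivors <- function(vaf_by_tp, cnv_ccf_by_tp, cnv_type, eps) {
    tps <- intersect(names(vaf_by_tp), names(cnv_ccf_by_tp))
    tps <- tps[vapply(tps, function(t) cnv_ccf_by_tp[[t]] > 1e-9, logical(1))]
    if (!length(tps)) return(NULL)
    survivors <- list()
    excluded <- character()
    for (ci in seq_len(nrow(.CASE_GRID))) {
        scen <- .CASE_GRID$scenario[ci]
        cv <- if (cnv_type == "deletion") .CASE_GRID$del_value[ci] else
            .CASE_GRID$dup_value[ci]
        ccfs <- numeric(); ok <- TRUE; worst <- 0
        for (t in tps) {
            cases <- enumerateOverlapCases(vaf_by_tp[[t]], cnv_ccf_by_tp[[t]],
                                           cnv_type, eps)
            row <- cases[cases$scenario == scen & cases$cnv_value == cv, ]
            worst <- max(worst, row$violation)
            if (!row$feasible) { ok <- FALSE; break }
            ccfs[t] <- row$ccf_snv
        }
        label <- sprintf("scenario%d/cnv_value%d", scen, cv)
        if (ok) survivors[[length(survivors) + 1L]] <-
                list(scenario = scen, cnv_value = cv, label = label,
                     ccf_by_tp = ccfs)
        else excluded <- c(excluded, sprintf("%s (violation %.3f)",
                                             label, worst))
    }
    list(survivors = survivors, excluded = excluded, tps = tps)
}

#' Reconstruct clonal evolution for a patient
#'
#' End-to-end pipeline: per-aberration CCF estimation from all modalities;
#' resolution of variants covered by a copy-number event through the
#' four-case overlap model, branching the reconstruction over every
#' surviving case (the order of the two events is in general unknowable from
#' bulk data, so alternatives are reported, never auto-selected); clustering
#' into clones; exhaustive enumeration of admissible clone trees; and
#' classification of the evolution pattern. Overlap cases additionally
#' constrain ancestry: a CNV-first case requires the CNV clone on the
#' variant clone's root path, a variant-first case the converse, and a
#' parallel case keeps the two clones in disjoint lineages.
#'
#' @param bundle a [PatientBundle-class].
#' @param tol clustering tolerance, default 0.10.
#' @param delta nesting slack, default 0.05.
#' @param eps overlap feasibility tolerance, default 0.05.
#' @param maxAlternatives cap on overlap-case combinations explored.
#' @param maxTrees cap on trees per combination.
#' @param neutralSiblings,dominance neutral-evolution parameters, see
#'   [classifyEvolution()].
#' @return List of [CloneTree-class] objects across all surviving overlap
#'   cases, re-ranked in output order; attribute `"log"` carries an
#'   auditable trace of excluded scenarios. Errors with condition class
#'   `reconstruction_infeasible` when no admissible tree exists.
#' @export
reconstructPatient <- function(bundle, tol = 0.10, delta = 0.05, eps = 0.05,
                               maxAlternatives = 16L, maxTrees = 1000L,
                               neutralSiblings = 4L, dominance = 0.5) {
    stopifnot(is(bundle, "PatientBundle"))
    est <- estimateCCFs(bundle)
    if (!nrow(est))
        stop(.RECONSTRUCTION_INFEASIBLE("bundle contains no usable evidence"))
    ab <- bundle@aberrations
    tps <- bundle@timepoints$index
    logv <- character()

    ## overlap pairs -------------------------------------------------------
    variants <- ab[ab$kind %in% c("snv", "indel"), , drop = FALSE]
    pairs <- list()
    for (i in seq_len(nrow(variants))) {
        gb <- geneBand(variants$gene[i])
        if (is.null(gb)) next
        for (j in seq_len(nrow(ab))) {
            eff <- .effectiveCnv(ab[j, ], bundle@config)
            if (is.null(eff) || ab$id[j] == variants$id[i]) next
            if (.regionsOverlap(gb$chrom, gb$arm, gb$lo, gb$hi,
                                eff$chrom, eff$arm, eff$lo, eff$hi))
                pairs[[length(pairs) + 1L]] <-
                    list(var = variants$id[i], cnv = ab$id[j],
                         type = if (eff$direction == "loss") "deletion"
                                else "duplication")
        }
    }

    estOf <- function(id) est[est$aberration_id == id, , drop = FALSE]
    branches <- list(list(label = "", cases = list()))
    for (p in pairs) {
        vobs <- bundle@variantObs[bundle@variantObs$aberration_id == p$var, ]
        vaf_by_tp <- stats::setNames(as.list(vobs$vaf),
                                     vobs$timepoint_index)
        ce <- estOf(p$cnv)
        cnv_by_tp <- stats::setNames(as.list(ce$ccf), ce$timepoint_index)
        res <- .overlapSurvivors(vaf_by_tp, cnv_by_tp, p$type, eps)
        if (is.null(res)) next
        logv <- c(logv, sprintf("overlap %s within %s (%s): %d of 4 cases feasible",
                                p$var, p$cnv, p$type, length(res$survivors)))
        logv <- c(logv, sprintf("  excluded %s", res$excluded))
        if (!length(res$survivors))
            stop(.RECONSTRUCTION_INFEASIBLE(sprintf(
                "no overlap case for %s within %s satisfies w+x+y+z=1 at eps=%g",
                p$var, p$cnv, eps)))
        branches <- unlist(lapply(branches, function(b) {
            lapply(res$survivors, function(s) {
                list(label = paste(c(b$label[nzchar(b$label)],
                                     sprintf("%s:%s", p$var, s$label)),
                                   collapse = "; "),
                     cases = c(b$cases, list(c(p, s))))
            })
        }), recursive = FALSE)
        if (length(branches) > maxAlternatives) {
            warning(sprintf("overlap alternatives truncated at %d",
                            maxAlternatives))
            branches <- branches[seq_len(maxAlternatives)]
        }
    }

    cannot <- list()
    for (gexc in bundle@config$exclusive_genes %||% character()) {
        ids <- variants$id[variants$gene == gexc]
        if (length(ids) > 1L)
            cannot <- c(cannot, utils::combn(ids, 2, simplify = FALSE))
    }

    trees <- list()
    for (b in branches) {
        est_b <- est
        cannot_b <- cannot
        for (cs in b$cases) {
            keep <- !(est_b$aberration_id == cs$var &
                      est_b$timepoint_index %in% as.integer(names(cs$ccf_by_tp)))
            est_b <- est_b[keep, , drop = FALSE]
            for (t in names(cs$ccf_by_tp)) {
                row <- .newCcfEstimate(cs$ccf_by_tp[[t]],
                                       max(0, cs$ccf_by_tp[[t]] - .DEFAULT_CI_HALFWIDTH),
                                       min(1, cs$ccf_by_tp[[t]] + .DEFAULT_CI_HALFWIDTH),
                                       "overlap_model", character(),
                                       cs$var, as.integer(t))
                est_b <- rbind(est_b, row[, colnames(est_b), drop = FALSE])
            }
            if (cs$scenario == 3L)
                cannot_b <- c(cannot_b, list(c(cs$var, cs$cnv)))
        }
        clones <- clusterAberrations(est_b, tol, timepoints = tps,
                                     cannotLink = cannot_b)
        constraints <- list()
        for (cs in b$cases) {
            ci_var <- which(vapply(clones@members, function(m)
                cs$var %in% m, logical(1)))
            ci_cnv <- which(vapply(clones@members, function(m)
                cs$cnv %in% m, logical(1)))
            if (!length(ci_var) || !length(ci_cnv)) next
            constraints[[length(constraints) + 1L]] <-
                if (cs$scenario == 1L)
                    list(type = "ancestor_or_equal", anc = ci_cnv, desc = ci_var)
                else if (cs$scenario == 2L)
                    list(type = "ancestor_or_equal", anc = ci_var, desc = ci_cnv)
                else list(type = "independent", a = ci_var, b = ci_cnv)
        }
        tr <- withCallingHandlers(
            buildCloneTrees(clones, delta, constraints, maxTrees,
                            neutralSiblings, dominance),
            warning = function(w) {
                logv <<- c(logv, conditionMessage(w))
                invokeRestart("muffleWarning")
            })
        for (t in tr) {
            t@caseLabel <- b$label
            t@aberrations <- ab
            t@timepoints <- as.integer(tps)
            trees[[length(trees) + 1L]] <- t
        }
    }
    for (r in seq_along(trees)) trees[[r]]@rank <- as.integer(r)
    attr(trees, "log") <- logv
    trees
}
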