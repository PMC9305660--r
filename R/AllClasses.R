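#' @import methods
NULL

## ---------------------------------------------------------------------------
## Central S4 containers.
##
## Tabular records (aberrations, observations, CCF estimates, overlap cases)
## are plain data.frames with documented columns, the way Bioconductor
## packages return per-feature result tables. The containers below hold the
## objects with real structure: a patient's multi-modal evidence, a clustered
## clone set, a clone tree, an explicit simulated cell population and a
## fishplot export.
## ---------------------------------------------------------------------------

.ABERRATION_COLS <- c("id", "kind", "gene", "hgvs", "iscn_token", "chrom",
                      "arm", "band_start", "band_end", "start", "end",
                      "cnv_direction", "multiplicity")

.emptyAberrations <- function() {
    data.frame(id = character(), kind = character(), gene = character(),
               hgvs = character(), iscn_token = character(),
               chrom = character(), arm = character(),
               band_start = numeric(), band_end = numeric(),
               start = numeric(), end = numeric(),
               cnv_direction = character(), multiplicity = integer(),
               stringsAsFactors = FALSE)
}

.emptyVariantObs <- function() {
    data.frame(aberration_id = character(), timepoint_index = integer(),
               vaf = numeric(), depth = numeric(), alt_reads = numeric(),
               stringsAsFactors = FALSE)
}

.emptyKaryotypeObs <- function() {
    data.frame(timepoint_index = integer(), clone_iscn = character(),
               metaphases_with = integer(), metaphases_total = integer(),
               aberration_ids = character(), stringsAsFactors = FALSE)
}

.emptyFishObs <- function() {
    data.frame(timepoint_index = integer(), probe = character(),
               nuclei_with = integer(), nuclei_total = integer(),
               aberration_id = character(), stringsAsFactors = FALSE)
}

.emptyCghObs <- function() {
    data.frame(timepoint_index = integer(), chrom = character(),
               start = numeric(), end = numeric(), log2_ratio = numeric(),
               direction = character(), aberration_id = character(),
               stringsAsFactors = FALSE)
}

#' PatientBundle: all diagnostic evidence for one patient
#'
#' Cross-referenced container for one patient's aberrations and the raw
#' per-time-point evidence behind them: somatic variant allele frequencies
#' from panel sequencing, metaphase counts from karyotyping, nuclei counts
#' from interphase FISH and log2 ratios from array-CGH.
#'
#' @slot patient patient identifier.
#' @slot timepoints data.frame with columns `index` (0-based ordinal),
#'   `label`, `clinical_status` (one of initial, progression, remission,
#'   relapse, other) and `sct_before` (logical; stem cell transplantation
#'   between the previous time point and this one).
#' @slot aberrations data.frame of distinct merged aberrations (columns
#'   `id`, `kind` in snv/indel/sv/cnv, `gene`, `hgvs`, `iscn_token`,
#'   `chrom`, `arm`, `band_start`, `band_end`, `start`, `end`,
#'   `cnv_direction`, `multiplicity`).
#' @slot variantObs,karyotypeObs,fishObs,cghObs observation tables linked to
#'   aberrations by id; karyotype rows link to all aberrations of the clone
#'   (comma-separated `aberration_ids`).
#' @slot config named list of loader options (sex, cnv_effects,
#'   exclusive_genes, ...).
#' @exportClass PatientBundle
setClass("PatientBundle",
    representation(patient = "character", timepoints = "data.frame",
                   aberrations = "data.frame", variantObs = "data.frame",
                   karyotypeObs = "data.frame", fishObs = "data.frame",
                   cghObs = "data.frame", config = "list"),
    prototype(patient = NA_character_,
              timepoints = data.frame(index = integer(), label = character(),
                                      clinical_status = character(),
                                      sct_before = logical(),
                                      stringsAsFactors = FALSE),
              aberrations = .emptyAberrations(),
              variantObs = .emptyVariantObs(),
              karyotypeObs = .emptyKaryotypeObs(),
              fishObs = .emptyFishObs(),
              cghObs = .emptyCghObs(),
              config = list()))

setValidity("PatientBundle", function(object) {
    msg <- character()
    tp <- object@timepoints
    ab <- object@aberrations
    if (anyDuplicated(ab$id))
        msg <- c(msg, "aberration ids must be unique within a patient")
    if (nrow(tp) && any(diff(sort(tp$index)) == 0))
        msg <- c(msg, "time point indices must be strictly increasing")
    bad <- ab$kind == "cnv" & (is.na(ab$cnv_direction) |
                               !ab$cnv_direction %in% c("loss", "gain"))
    if (any(bad))
        msg <- c(msg, "kind=cnv requires cnv_direction loss or gain")
    bad <- ab$kind %in% c("snv", "indel") & (is.na(ab$gene) | is.na(ab$hgvs))
    if (any(bad))
        msg <- c(msg, "kind=snv/indel requires gene and hgvs")
    v <- object@variantObs
    if (nrow(v)) {
        if (any(v$vaf < 0 | v$vaf > 1))
            msg <- c(msg, "VAF must lie in [0, 1]")
        has <- !is.na(v$depth) & !is.na(v$alt_reads)
        if (any(has & abs(v$alt_reads[has] / v$depth[has] - v$vaf[has]) > 1e-6))
            msg <- c(msg, "alt_reads/depth must agree with vaf")
        if (!all(v$aberration_id %in% ab$id))
            msg <- c(msg, "variant observation references unknown aberration")
        if (!all(v$timepoint_index %in% tp$index))
            msg <- c(msg, "variant observation references unknown time point")
    }
    k <- object@karyotypeObs
    if (nrow(k)) {
        if (any(k$metaphases_total <= 0) ||
            any(k$metaphases_with < 0 | k$metaphases_with > k$metaphases_total))
            msg <- c(msg, "metaphase counts must satisfy 0 <= with <= total, total > 0")
        if (!all(k$timepoint_index %in% tp$index))
            msg <- c(msg, "karyotype observation references unknown time point")
    }
    f <- object@fishObs
    if (nrow(f)) {
        if (any(f$nuclei_total <= 0) ||
            any(f$nuclei_with < 0 | f$nuclei_with > f$nuclei_total))
            msg <- c(msg, "nuclei counts must satisfy 0 <= with <= total, total > 0")
        if (!all(f$timepoint_index %in% tp$index))
            msg <- c(msg, "FISH observation references unknown time point")
    }
    g <- object@cghObs
    if (nrow(g)) {
        if (any(g$start >= g$end))
            msg <- c(msg, "CGH segments need start < end")
        if (any(g$direction == "loss" & g$log2_ratio >= 0) ||
            any(g$direction == "gain" & g$log2_ratio <= 0))
            msg <- c(msg, "CGH direction must match the sign of log2_ratio")
        if (!all(g$timepoint_index %in% tp$index))
            msg <- c(msg, "CGH observation references unknown time point")
    }
    if (length(msg)) msg else TRUE
})

#' CloneSet: aberrations clustered into clones
#'
#' @slot members list of character vectors; aberration ids per clone.
#' @slot ccf numeric matrix, clones x time points, values in `[0, 1]`
#'   (0 where the clone is absent).
#' @slot se numeric matrix of standard errors matching `ccf`.
#' @exportClass CloneSet
setClass("CloneSet",
    representation(members = "list", ccf = "matrix", se = "matrix"))

setValidity("CloneSet", function(object) {
    msg <- character()
    if (length(object@members) != nrow(object@ccf))
        msg <- c(msg, "one ccf row per clone required")
    if (any(lengths(object@members) == 0))
        msg <- c(msg, "clones must have a non-empty aberration set")
    if (length(object@ccf) &&
        any(object@ccf < -1e-9 | object@ccf > 1 + 1e-9))
        msg <- c(msg, "clone CCFs must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' CloneTree: one admissible clonal phylogeny
#'
#' A parent assignment over a [CloneSet] obeying the pigeonhole nesting
#' constraints: at every time point the CCFs of a clone's children sum to at
#' most the clone's CCF (plus slack `delta`), root clones sum to at most 1,
#' and no clone appears before its parent.
#'
#' @slot members,ccf as in [CloneSet].
#' @slot parent integer vector; `parent[i]` is the row index of clone i's
#'   parent, 0 for a root.
#' @slot pattern evolution pattern: "linear", "branched" or "neutral".
#' @slot rank ordinal among alternative trees (1 = first).
#' @slot caseLabel label of the CNV/SNV overlap case this reconstruction
#'   assumed ("" when no overlap was involved).
#' @slot aberrations aberration metadata table (may be empty).
#' @slot timepoints integer time point indices labelling `ccf` columns.
#' @exportClass CloneTree
setClass("CloneTree",
    representation(members = "list", ccf = "matrix", parent = "integer",
                   pattern = "character", rank = "integer",
                   caseLabel = "character", aberrations = "data.frame",
                   timepoints = "integer"),
    prototype(pattern = NA_character_, rank = 1L, caseLabel = "",
              aberrations = .emptyAberrations()))

setValidity("CloneTree", function(object) {
    msg <- character()
    n <- length(object@members)
    if (length(object@parent) != n || nrow(object@ccf) != n)
        msg <- c(msg, "parent and ccf must have one entry per clone")
    if (n && (any(object@parent < 0L) || any(object@parent > n)))
        msg <- c(msg, "parent indices out of range")
    if (n && any(object@parent == seq_len(n)))
        msg <- c(msg, "a clone cannot be its own parent")
    ## cycle check
    if (n && !any(nzchar(msg))) {
        for (i in seq_len(n)) {
            seen <- logical(n); j <- i
            while (object@parent[j] != 0L) {
                j <- object@parent[j]
                if (seen[j]) { msg <- c(msg, "parent links contain a cycle"); break }
                seen[j] <- TRUE
            }
            if (any(grepl("cycle", msg))) break
        }
    }
    if (length(msg)) msg else TRUE
})

#' CellPopulation: explicit simulated cell population
#'
#' The brute-force substrate behind the CNV/SNV overlap model: every clone is
#' an explicit cell class with a population fraction and, per locus, the
#' number of mutant and total allele copies. The exact bulk VAF of a locus is
#' a weighted sum over the classes, with no model assumptions.
#'
#' @slot fractions named numeric vector of cell-class fractions; sums to 1.
#' @slot genotype data.frame with columns `clone_id`, `locus`,
#'   `mutant_copies`, `total_copies`.
#' @exportClass CellPopulation
setClass("CellPopulation",
    representation(fractions = "numeric", genotype = "data.frame"))

setValidity("CellPopulation", function(object) {
    msg <- character()
    if (abs(sum(object@fractions) - 1) > 1e-9)
        msg <- c(msg, "cell-class fractions must sum to 1")
    if (any(object@fractions < -1e-12))
        msg <- c(msg, "cell-class fractions must be non-negative")
    g <- object@genotype
    if (nrow(g)) {
        if (!all(g$clone_id %in% names(object@fractions)))
            msg <- c(msg, "genotype references unknown cell class")
        if (any(g$mutant_copies < 0) || any(g$total_copies < 0))
            msg <- c(msg, "copy numbers must be non-negative")
        if (any(g$mutant_copies > g$total_copies))
            msg <- c(msg, "mutant copies cannot exceed total copies")
    }
    if (length(msg)) msg else TRUE
})

#' CellPopulation constructor
#'
#' @param fractions named numeric vector of cell-class fractions (sum 1).
#' @param genotype data.frame with columns `clone_id`, `locus`,
#'   `mutant_copies`, `total_copies`.
#' @return A [CellPopulation-class] object.
#' @examples
#' pop <- CellPopulation(c(tumor = 0.4, normal = 0.6),
#'     data.frame(clone_id = c("tumor", "normal"), locus = "TP53",
#'                mutant_copies = c(1, 0), total_copies = c(2, 2)))
#' exactVaf(pop, "TP53")
#' @export
CellPopulation <- function(fractions, genotype) {
    new("CellPopulation", fractions = fractions,
        genotype = as.data.frame(genotype, stringsAsFactors = FALSE))
}

#' FishplotExport: fishplot-ready fraction matrix and parent vector
#'
#' @slot fractions numeric matrix, clones x time points, percent units.
#' @slot parent integer parent vector (0 = root).
#' @slot positions numeric axis positions of the time points.
#' @slot annotations data.frame with columns `position`, `marker`
#'   ("analysis" or "transplant").
#' @slot floors data.frame recording interior zero values floored to keep
#'   the render topology valid (columns `clone`, `timepoint`, `value`).
#' @slot cloneLabels character labels per clone.
#' @exportClass FishplotExport
setClass("FishplotExport",
    representation(fractions = "matrix", parent = "integer",
                   positions = "numeric", annotations = "data.frame",
                   floors = "data.frame", cloneLabels = "character"))

setValidity("FishplotExport", function(object) {
    msg <- character()
    fr <- object@fractions
    if (length(fr) && (any(fr < 0) || any(fr > 100 + 1e-6)))
        msg <- c(msg, "fractions must lie in [0, 100] percent")
    if (nrow(fr) != length(object@parent))
        msg <- c(msg, "one parent entry per clone required")
    if (ncol(fr) != length(object@positions))
        msg <- c(msg, "one axis position per time point required")
    tol <- 1e-6
    for (j in seq_len(ncol(fr))) {
        roots <- which(object@parent == 0L)
        if (sum(fr[roots, j]) > 100 + tol)
            msg <- c(msg, sprintf("root fractions exceed 100%% in column %d", j))
        for (i in seq_len(nrow(fr))) {
            ch <- which(object@parent == i)
            if (length(ch) && sum(fr[ch, j]) > fr[i, j] + tol)
                msg <- c(msg, sprintf(
                    "children of clone %d exceed parent in column %d", i, j))
        }
    }
    if (length(msg)) unique(msg) else TRUE
})

## ------------------------------- show methods ------------------------------

setMethod("show", "PatientBundle", function(object) {
    cat("PatientBundle:", object@patient, "\n")
    cat(" ", nrow(object@timepoints), "time point(s);",
        nrow(object@aberrations), "aberration(s)\n")
    if (nrow(object@aberrations))
        cat("  kinds:", paste(sprintf("%s=%d",
            names(table(object@aberrations$kind)),
            as.integer(table(object@aberrations$kind))), collapse = ", "), "\n")
    cat("  observations: variant", nrow(object@variantObs),
        "| karyotype", nrow(object@karyotypeObs),
        "| FISH", nrow(object@fishObs),
        "| CGH", nrow(object@cghObs), "\n")
    invisible(object)
})

setMethod("show", "CloneSet", function(object) {
    cat("CloneSet with", length(object@members), "clone(s) over",
        ncol(object@ccf), "time point(s)\n")
    for (i in seq_along(object@members))
        cat(sprintf("  clone %d [%s]: ccf %s\n", i,
                    paste(object@members[[i]], collapse = ", "),
                    paste(sprintf("%.3f", object@ccf[i, ]), collapse = " ")))
    invisible(object)
})

setMethod("show", "CloneTree", function(object) {
    cat("CloneTree (", object@pattern, ", rank ", object@rank,
        if (nzchar(object@caseLabel)) paste0(", case ", object@caseLabel),
        ")\n", sep = "")
    for (i in seq_along(object@members))
        cat(sprintf("  clone %d <- %s [%s]: %s\n", i,
                    if (object@parent[i] == 0L) "root"
                    else paste0("clone ", object@parent[i]),
                    paste(object@members[[i]], collapse = ", "),
                    paste(sprintf("%.3f", object@ccf[i, ]), collapse = " ")))
    invisible(object)
})

setMethod("show", "CellPopulation", function(object) {
    cat("CellPopulation with", length(object@fractions), "cell class(es)\n")
    print(round(object@fractions, 4))
    invisible(object)
})

setMethod("show", "FishplotExport", function(object) {
    cat("FishplotExport:", nrow(object@fractions), "clone(s) x",
        ncol(object@fractions), "time point(s) (percent)\n")
    invisible(object)
})

## ------------------------------- accessors ---------------------------------

#' @describeIn PatientBundle-class aberration table accessor
#' @param object,x a container object.
#' @export
setGeneric("aberrations", function(object) standardGeneric("aberrations"))

#' @rdname PatientBundle-class
#' @export
setMethod("aberrations", "PatientBundle", function(object) object@aberrations)

#' @rdname CloneTree-class
#' @export
setMethod("aberrations", "CloneTree", function(object) object@aberrations)

#' Clone CCF matrix accessor
#' @param object a [CloneSet-class] or [CloneTree-class].
#' @export
setGeneric("cloneCCF", function(object) standardGeneric("cloneCCF"))

#' @rdname cloneCCF
#' @export
setMethod("cloneCCF", "CloneSet", function(object) object@ccf)

#' @rdname cloneCCF
#' @export
setMethod("cloneCCF", "CloneTree", function(object) object@ccf)

#' Clone membership accessor
#' @param object a [CloneSet-class] or [CloneTree-class].
#' @export
setGeneric("cloneMembers", function(object) standardGeneric("cloneMembers"))

#' @rdname cloneMembers
#' @export
setMethod("cloneMembers", "CloneSet", function(object) object@members)

#' @rdname cloneMembers
#' @export
setMethod("cloneMembers", "CloneTree", function(object) object@members)

#' Parent vector accessor (0 = root)
#' @param object a [CloneTree-class] or [FishplotExport-class].
#' @export
setGeneric("parentVector", function(object) standardGeneric("parentVector"))

#' @rdname parentVector
#' @export
setMethod("parentVector", "CloneTree", function(object) object@parent)

#' @rdname parentVector
#' @export
setMethod("parentVector", "FishplotExport", function(object) object@parent)

#' Evolution pattern accessor
#' @param object a [CloneTree-class].
#' @export
setGeneric("evolutionPattern", function(object) standardGeneric("evolutionPattern"))

#' @rdname evolutionPattern
#' @export
setMethod("evolutionPattern", "CloneTree", function(object) object@pattern)

#' Time point table accessor
#' @param object a [PatientBundle-class].
#' @export
setGeneric("timePoints", function(object) standardGeneric("timePoints"))

#' @rdname timePoints
#' @export
setMethod("timePoints", "PatientBundle", function(object) object@timepoints)
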