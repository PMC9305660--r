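## Synthetic-data generator and brute-force oracle.
##
## A CellPopulation realizes a clone tree (or an overlap-case configuration)
## as explicit cell classes with per-locus allele copies; its exact bulk VAF
## is plain allele counting, independent of the closed-form scenario
## algebra, which makes it the oracle for the overlap engine. The generator
## then draws noisy observations of all four diagnostic modalities from the
## population and writes them in the loader's file formats.

#' Exact bulk VAF of a locus in an explicit cell population
#'
#' Allele counting with no model assumptions:
#' sum(fraction * mutant_copies) / sum(fraction * total_copies).
#'
#' @param pop a [CellPopulation-class].
#' @param locus locus name; must be genotyped in every cell class.
#' @return Exact variant allele fraction.
#' @examples
#' pop <- CellPopulation(c(a = 0.5, b = 0.5),
#'     data.frame(clone_id = c("a", "b"), locus = "L",
#'                mutant_copies = c(1, 0), total_copies = c(2, 2)))
#' exactVaf(pop, "L")   # 0.25
#' @export
exactVaf <- function(pop, locus) {
    stopifnot(is(pop, "CellPopulation"))
    g <- pop@genotype[pop@genotype$locus == locus, , drop = FALSE]
    if (!all(names(pop@fractions) %in% g$clone_id))
        stop(sprintf("locus '%s' is not genotyped in every cell class", locus))
    f <- pop@fractions[g$clone_id]
    tot <- sum(f * g$total_copies)
    if (tot == 0)
        stop(sprintf("no copies of locus '%s' present in the population", locus))
    sum(f * g$mutant_copies) / tot
}

#' Realize an overlap case as an explicit cell population
#'
#' Builds the four cell classes of the CNV/SNV overlap model: w (CNV and
#' variant), x (CNV only), y (variant only), z (neither). Deletion cells
#' carry 1 copy of the locus, duplication cells 3, all others 2; the w cells
#' carry `cnv_value` mutant copies and the y cells one mutant copy of two.
#'
#' @param w,x,y,z cell-class fractions (must sum to 1; small negative values
#'   are rejected — clip before calling if needed).
#' @param cnv_value mutant copies in the w cells.
#' @param cnv_type "deletion" or "duplication".
#' @param locus locus name for the genotype table.
#' @return A [CellPopulation-class] whose [exactVaf()] equals the scenario
#'   model prediction.
#' @examples
#' pop <- populationFromOverlapCase(0.375, 0.125, 0, 0.5, 1, "deletion")
#' exactVaf(pop, "L")   # 0.25
#' @export
populationFromOverlapCase <- function(w, x, y, z, cnv_value,
                                      cnv_type = c("deletion", "duplication"),
                                      locus = "L") {
    cnv_type <- match.arg(cnv_type)
    cn <- if (cnv_type == "deletion") 1L else 3L
    if (cnv_value > cn)
        stop("cnv_value cannot exceed the CNV-cell copy number")
    fr <- c(w = w, x = x, y = y, z = z)
    CellPopulation(fr, data.frame(
        clone_id = c("w", "x", "y", "z"),
        locus = locus,
        mutant_copies = c(as.integer(cnv_value), 0L, 1L, 0L),
        total_copies = c(cn, cn, 2L, 2L),
        stringsAsFactors = FALSE))
}

## Cell population of one time point of a clone tree: a clone's own
## fraction is its CCF minus its children's, plus a normal-cell rest class.
## Loci are treated as independent (each clone carries one mutant of two
## copies for every aberration on its root path).
.populationFromTree <- function(tree, tp_col) {
    ccf <- tree@ccf[, tp_col]
    n <- length(ccf)
    own <- ccf
    for (i in seq_len(n)) {
        ch <- which(tree@parent == i)
        own[i] <- ccf[i] - sum(ccf[ch])
    }
    roots <- which(tree@parent == 0L)
    normal <- 1 - sum(ccf[roots])
    if (any(own < -1e-9) || normal < -1e-9)
        stop("tree CCFs violate nesting; cannot realize a population")
    fr <- c(pmax(own, 0), max(normal, 0))
    names(fr) <- c(sprintf("clone%d", seq_len(n)), "normal")
    fr <- fr / sum(fr)
    carriers <- lapply(seq_len(n), function(i) {
        path <- i
        j <- i
        while (tree@parent[j] != 0L) { j <- tree@parent[j]; path <- c(path, j) }
        unique(unlist(tree@members[path]))
    })
    loci <- unique(unlist(tree@members))
    g <- do.call(rbind, lapply(loci, function(l) {
        has <- vapply(carriers, function(ids) l %in% ids, logical(1))
        data.frame(clone_id = names(fr),
                   locus = l,
                   mutant_copies = c(ifelse(has, 1L, 0L), 0L),
                   total_copies = 2L, stringsAsFactors = FALSE)
    }))
    CellPopulation(fr, g)
}

## Per-modality RNG streams split from one master seed, so adding or
## reordering a modality does not shift the draws of another.
.modalitySeed <- function(seed, offset) {
    (as.integer(seed) + 10007L * offset) %% 2147483629L
}

#' Simulate multi-modal diagnostic observations from a truth clone tree
#'
#' Draws noisy observations of every modality from the explicit cell
#' populations realizing `tree` at each time point, and writes a loadable
#' patient directory: variants.tsv (VAFs ~ Binomial(depth, exact VAF)),
#' karyotype.tsv (metaphases ~ Multinomial over cell classes; the clone
#' string is the cumulative ISCN karyotype of the clone's root path),
#' fish.tsv (nuclei ~ Binomial(n, carrier fraction) per cytogenetic
#' aberration), cgh.tsv (log2 ratio of the one-copy mixture model plus
#' Gaussian noise), config.yaml and truth.json (same schema as
#' reconstruction output, for direct diffing).
#'
#' The truth tree's aberration table supplies the identity of each locus:
#' snv/indel rows need `gene` and `hgvs`, cytogenetic rows a parseable
#' `iscn_token`. Loci are simulated as independent (no CNV covering a
#' variant locus); overlap configurations are realized explicitly with
#' [populationFromOverlapCase()] instead.
#'
#' @param tree a [CloneTree-class] with an aberration table.
#' @param out_dir output directory (created if needed).
#' @param depth sequencing depth per variant (default 5000).
#' @param n_metaphases metaphases examined per time point (default 20,
#'   routine practice examines 15 to 25).
#' @param n_nuclei FISH nuclei per probe (default 200, at least 200 are
#'   analyzed in routine diagnostics).
#' @param cgh_noise_sd Gaussian standard deviation on log2 ratios
#'   (default 0.05).
#' @param seed master seed; per-modality streams are derived from it.
#' @param noiseless if TRUE, write exact expectations instead of draws
#'   (an infinite-sampling shortcut; counts are scaled to `n * fraction`
#'   rounded).
#' @param patient patient identifier written to the files.
#' @return The output directory, invisibly.
#' @export
simulateObservations <- function(tree, out_dir, depth = 5000,
                                 n_metaphases = 20, n_nuclei = 200,
                                 cgh_noise_sd = 0.05, seed = 1,
                                 noiseless = FALSE, patient = "sim") {
    stopifnot(is(tree, "CloneTree"))
    if (depth <= 0 || n_metaphases <= 0 || n_nuclei <= 0)
        stop("sampling sizes must be positive")
    ab <- tree@aberrations
    if (!nrow(ab)) stop("truth tree carries no aberration table")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tps <- tree@timepoints
    pops <- lapply(seq_along(tps), function(j) .populationFromTree(tree, j))

    is_var <- ab$kind %in% c("snv", "indel")
    ## variants ------------------------------------------------------------
    set.seed(.modalitySeed(seed, 1L))
    vrows <- list()
    for (j in seq_along(tps)) for (i in which(is_var)) {
        v <- exactVaf(pops[[j]], ab$id[i])
        k <- if (noiseless) round(v * depth) else stats::rbinom(1, depth, v)
        vrows[[length(vrows) + 1L]] <- data.frame(
            patient = patient, timepoint = tps[j], gene = ab$gene[i],
            hgvs_c = ab$hgvs[i], hgvs_p = "",
            vaf_percent = 100 * k / depth, depth = depth, alt_reads = k,
            stringsAsFactors = FALSE)
    }
    utils::write.table(do.call(rbind, vrows), file.path(out_dir, "variants.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## karyotype -----------------------------------------------------------
    set.seed(.modalitySeed(seed, 2L))
    cyto <- which(!is_var)
    krows <- list()
    for (j in seq_along(tps)) {
        fr <- pops[[j]]@fractions
        counts <- if (noiseless) round(fr * n_metaphases)
                  else as.vector(stats::rmultinom(1, n_metaphases, fr))
        names(counts) <- names(fr)
        for (ci in seq_along(tree@members)) {
            cname <- sprintf("clone%d", ci)
            if (counts[cname] == 0) next
            path <- ci; jj <- ci
            while (tree@parent[jj] != 0L) { jj <- tree@parent[jj]; path <- c(path, jj) }
            ids <- unique(unlist(tree@members[rev(path)]))
            ids <- ids[ids %in% ab$id[cyto]]
            iscn <- if (length(ids))
                formatIscn(ab[match(ids, ab$id), , drop = FALSE]) else "46,XX"
            krows[[length(krows) + 1L]] <- data.frame(
                patient = patient, timepoint = tps[j], clone_iscn = iscn,
                metaphases_with = counts[cname],
                metaphases_total = n_metaphases, stringsAsFactors = FALSE)
        }
        normal <- n_metaphases - sum(counts[sprintf("clone%d", seq_along(tree@members))])
        if (normal > 0)
            krows[[length(krows) + 1L]] <- data.frame(
                patient = patient, timepoint = tps[j], clone_iscn = "46,XX",
                metaphases_with = normal, metaphases_total = n_metaphases,
                stringsAsFactors = FALSE)
    }
    utils::write.table(do.call(rbind, krows), file.path(out_dir, "karyotype.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    ## FISH ----------------------------------------------------------------
    set.seed(.modalitySeed(seed, 3L))
    frows <- list()
    for (j in seq_along(tps)) for (i in cyto) {
        carrier <- exactVaf(pops[[j]], ab$id[i]) * 2   # 1-of-2 copies coding
        carrier <- min(1, carrier)
        k <- if (noiseless) round(carrier * n_nuclei)
             else stats::rbinom(1, n_nuclei, carrier)
        probe <- if (!is.na(ab$chrom[i]))
            paste0(ab$chrom[i], ifelse(is.na(ab$arm[i]) || ab$arm[i] == "*",
                                       "", ab$arm[i])) else ab$id[i]
        frows[[length(frows) + 1L]] <- data.frame(
            patient = patient, timepoint = tps[j], probe = probe,
            target = ab$id[i], nuclei_with = k, nuclei_total = n_nuclei,
            stringsAsFactors = FALSE)
    }
    if (length(frows))
        utils::write.table(do.call(rbind, frows), file.path(out_dir, "fish.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)

    ## CGH -----------------------------------------------------------------
    set.seed(.modalitySeed(seed, 4L))
    grows <- list()
    cnvs <- which(ab$kind == "cnv")
    for (j in seq_along(tps)) for (i in cnvs) {
        f <- min(1, exactVaf(pops[[j]], ab$id[i]) * 2)
        r <- .log2RatioFromCcf(f, ab$cnv_direction[i])
        if (!noiseless) r <- r + stats::rnorm(1, 0, cgh_noise_sd)
        ## keep the sign consistent with the direction after noise
        if (ab$cnv_direction[i] == "loss") r <- min(r, -1e-6) else r <- max(r, 1e-6)
        grows[[length(grows) + 1L]] <- data.frame(
            patient = patient, timepoint = tps[j],
            chrom = ab$chrom[i], start = 0, end = 1e6,
            log2_ratio = r, stringsAsFactors = FALSE)
    }
    if (length(grows))
        utils::write.table(do.call(rbind, grows), file.path(out_dir, "cgh.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)

    ## config + truth -------------------------------------------------------
    cfg <- list(patient = patient,
                timepoints = lapply(seq_along(tps), function(j)
                    list(index = tps[j], label = sprintf("t%d", tps[j]),
                         status = "other")),
                files = list(variants = "variants.tsv",
                             karyotype = "karyotype.tsv",
                             fish = if (length(frows)) "fish.tsv" else NULL,
                             cgh = if (length(grows)) "cgh.tsv" else NULL))
    yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
    writeTrees(list(tree), file.path(out_dir, "truth.json"))
    invisible(out_dir)
}
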