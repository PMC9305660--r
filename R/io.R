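## Readers for the diagnostic input files and cross-modality merging.
##
## A patient directory holds a config.yaml naming the time points and data
## files:
##   variants.tsv  patient, timepoint, gene, hgvs_c, hgvs_p, vaf_percent,
##                 depth, alt_reads        (depth/alt_reads optional)
##   karyotype.tsv patient, timepoint, clone_iscn, metaphases_with,
##                 metaphases_total        (one row per karyotype clone)
##   fish.tsv      patient, timepoint, probe, nuclei_with, nuclei_total
##                 [, target]              (optional)
##   cgh.tsv       patient, timepoint, chrom, start, end, log2_ratio
##                 (optional; 0-based half-open coordinates)
## File values are percent where Table-style reporting uses percent; all
## internal math uses fractions.

## Read a TSV keeping label-like columns as character: automatic type
## conversion would turn an ISCN token like "+8" into the number 8.
.CHAR_COLS <- c("patient", "gene", "hgvs_c", "hgvs_p", "clone_iscn",
                "probe", "target", "chrom")

.readTsv <- function(path) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            check.names = TRUE, colClasses = "character",
                            na.strings = c("NA", ""))
    for (col in setdiff(names(df), .CHAR_COLS))
        df[[col]] <- utils::type.convert(df[[col]], as.is = TRUE)
    df
}

.variantKind <- function(hgvs_c) {
    ifelse(grepl("del|dup|ins", hgvs_c), "indel", "snv")
}

## merge an aberration row into the table; identity = id (the cleaned ISCN
## token or gene+variant string)
.mergeAberration <- function(tab, row) {
    i <- match(row$id, tab$id)
    if (is.na(i)) return(rbind(tab, row))
    tab
}

## find cnv aberrations overlapping a (chrom, arm, lo, hi) region
.matchCnv <- function(tab, chrom, arm, lo, hi, direction = NULL) {
    idx <- which(tab$kind == "cnv" &
                 vapply(seq_len(nrow(tab)), function(i)
                     .regionsOverlap(tab$chrom[i], tab$arm[i],
                                     tab$band_start[i], tab$band_end[i],
                                     chrom, arm, lo, hi), logical(1)))
    if (!is.null(direction))
        idx <- idx[tab$cnv_direction[idx] == direction]
    idx
}

#' Load a patient bundle from a directory
#'
#' Reads config.yaml plus the variant, karyotype and optional FISH/CGH
#' tables, parses the ISCN clone descriptions, and merges evidence for the
#' same event across modalities: FISH probes attach to the cytogenetic
#' aberration whose region covers the probe locus, CGH segments to a
#' copy-number aberration on the same chromosome with the same direction.
#' Loading is idempotent: the merged aberration set is a pure function of
#' the files.
#'
#' @param dir patient directory containing config.yaml.
#' @return A validated [PatientBundle-class].
#' @examples
#' bundle <- cohortPatient(3)
#' countAberrations(bundle)
#' @export
loadPatient <- function(dir) {
    cfg_path <- file.path(dir, "config.yaml")
    if (!file.exists(cfg_path)) stop("config.yaml not found in ", dir)
    cfg <- yaml::read_yaml(cfg_path)
    tp <- do.call(rbind, lapply(cfg$timepoints, function(t)
        data.frame(index = as.integer(t$index),
                   label = t$label %||% as.character(t$index),
                   clinical_status = t$status %||% "other",
                   sct_before = isTRUE(t$sct_before),
                   stringsAsFactors = FALSE)))
    tp <- tp[order(tp$index), , drop = FALSE]
    known_tp <- tp$index
    ab <- .emptyAberrations()
    vobs <- .emptyVariantObs()
    kobs <- .emptyKaryotypeObs()
    fobs <- .emptyFishObs()
    gobs <- .emptyCghObs()

    ## variants -------------------------------------------------------------
    vfile <- cfg$files$variants
    if (!is.null(vfile) && file.exists(file.path(dir, vfile))) {
        v <- .readTsv(file.path(dir, vfile))
        v <- v[!is.na(v$gene) & nzchar(v$gene), , drop = FALSE]
        for (i in seq_len(nrow(v))) {
            if (!v$timepoint[i] %in% known_tp)
                stop(sprintf("variant row references unknown time point %s",
                             v$timepoint[i]))
            id <- paste(v$gene[i], v$hgvs_c[i])
            gb <- geneBand(v$gene[i])
            row <- .abRow(id = id, kind = .variantKind(v$hgvs_c[i]),
                          gene = v$gene[i], hgvs = v$hgvs_c[i],
                          chrom = if (!is.null(gb)) gb$chrom else NA_character_,
                          arm = if (!is.null(gb)) gb$arm else NA_character_,
                          band_start = if (!is.null(gb)) gb$lo else NA_real_,
                          band_end = if (!is.null(gb)) gb$hi else NA_real_)
            ab <- .mergeAberration(ab, row)
            depth <- if ("depth" %in% names(v)) v$depth[i] else NA_real_
            alt <- if ("alt_reads" %in% names(v)) v$alt_reads[i] else NA_real_
            vobs <- rbind(vobs, data.frame(
                aberration_id = id, timepoint_index = as.integer(v$timepoint[i]),
                vaf = v$vaf_percent[i] / 100, depth = depth, alt_reads = alt,
                stringsAsFactors = FALSE))
        }
    }

    ## karyotype ------------------------------------------------------------
    kfile <- cfg$files$karyotype
    if (!is.null(kfile) && file.exists(file.path(dir, kfile))) {
        k <- .readTsv(file.path(dir, kfile))
        for (i in seq_len(nrow(k))) {
            if (!k$timepoint[i] %in% known_tp)
                stop(sprintf("karyotype row references unknown time point %s",
                             k$timepoint[i]))
            rows <- parseIscn(k$clone_iscn[i])
            for (r in seq_len(nrow(rows)))
                ab <- .mergeAberration(ab, rows[r, , drop = FALSE])
            kobs <- rbind(kobs, data.frame(
                timepoint_index = as.integer(k$timepoint[i]),
                clone_iscn = k$clone_iscn[i],
                metaphases_with = as.integer(k$metaphases_with[i]),
                metaphases_total = as.integer(k$metaphases_total[i]),
                aberration_ids = paste(rows$id, collapse = ","),
                stringsAsFactors = FALSE))
        }
    }

    ## FISH -----------------------------------------------------------------
    ffile <- cfg$files$fish
    if (!is.null(ffile) && file.exists(file.path(dir, ffile))) {
        f <- .readTsv(file.path(dir, ffile))
        for (i in seq_len(nrow(f))) {
            if (!f$timepoint[i] %in% known_tp)
                stop(sprintf("FISH row references unknown time point %s",
                             f$timepoint[i]))
            target <- if ("target" %in% names(f) && !is.na(f$target[i]))
                f$target[i] else NA_character_
            if (is.na(target)) {
                m <- regmatches(f$probe[i], regexec(
                    "^([0-9XY]+)([pq].*)?$", f$probe[i]))[[1]]
                if (length(m)) {
                    iv <- if (nzchar(m[3])) .parseBandInterval(m[3])
                          else list(arm = "*", lo = 0, hi = Inf)
                    hits <- which(!ab$kind %in% c("snv", "indel") &
                        vapply(seq_len(nrow(ab)), function(r)
                            .regionsOverlap(ab$chrom[r], ab$arm[r],
                                            ab$band_start[r], ab$band_end[r],
                                            m[2], iv$arm, iv$lo, iv$hi),
                            logical(1)))
                    if (length(hits)) target <- ab$id[hits[1]]
                }
            }
            if (is.na(target)) {
                warning(sprintf("FISH probe %s matches no aberration; skipped",
                                f$probe[i]))
                next
            }
            if (!target %in% ab$id)
                stop(sprintf("FISH row targets unknown aberration '%s'", target))
            fobs <- rbind(fobs, data.frame(
                timepoint_index = as.integer(f$timepoint[i]),
                probe = f$probe[i],
                nuclei_with = as.integer(f$nuclei_with[i]),
                nuclei_total = as.integer(f$nuclei_total[i]),
                aberration_id = target, stringsAsFactors = FALSE))
        }
    }

    ## CGH ------------------------------------------------------------------
    gfile <- cfg$files$cgh
    if (!is.null(gfile) && file.exists(file.path(dir, gfile))) {
        g <- .readTsv(file.path(dir, gfile))
        for (i in seq_len(nrow(g))) {
            if (!g$timepoint[i] %in% known_tp)
                stop(sprintf("CGH row references unknown time point %s",
                             g$timepoint[i]))
            direction <- if (g$log2_ratio[i] < 0) "loss" else "gain"
            chrom <- as.character(g$chrom[i])
            same <- .matchCnv(ab, chrom, NA_character_, NA_real_, NA_real_,
                              direction)
            opp <- .matchCnv(ab, chrom, NA_character_, NA_real_, NA_real_,
                             setdiff(c("loss", "gain"), direction))
            if (!length(same) && length(opp))
                stop(sprintf(paste0(
                    "conflicting cnv_direction: CGH %s on chr%s but ",
                    "karyotype shows %s (%s)"), direction, chrom,
                    ab$cnv_direction[opp[1]], ab$id[opp[1]]))
            if (length(same)) target <- ab$id[same[1]]
            else {
                target <- sprintf("cgh:%s:%d-%d", chrom,
                                  as.integer(g$start[i]), as.integer(g$end[i]))
                ab <- .mergeAberration(ab, .abRow(
                    id = target, kind = "cnv", chrom = chrom,
                    start = g$start[i], end = g$end[i],
                    cnv_direction = direction))
            }
            gobs <- rbind(gobs, data.frame(
                timepoint_index = as.integer(g$timepoint[i]), chrom = chrom,
                start = g$start[i], end = g$end[i],
                log2_ratio = g$log2_ratio[i], direction = direction,
                aberration_id = target, stringsAsFactors = FALSE))
        }
    }

    cfg_keep <- cfg[setdiff(names(cfg), c("timepoints", "files"))]
    ## normalize cnv_effects entries
    if (!is.null(cfg_keep$cnv_effects))
        cfg_keep$cnv_effects <- lapply(cfg_keep$cnv_effects, function(e) {
            e$id <- gsub(.ZW_CHARS, "", e$id); e
        })
    new("PatientBundle", patient = as.character(cfg$patient),
        timepoints = tp, aberrations = ab, variantObs = vobs,
        karyotypeObs = kobs, fishObs = fobs, cghObs = gobs,
        config = cfg_keep)
}

#' Count distinct aberrations in a bundle
#'
#' Number of distinct merged aberrations across all time points — events
#' seen by several modalities count once.
#'
#' @param bundle a [PatientBundle-class].
#' @return Integer count.
#' @export
countAberrations <- function(bundle) {
    stopifnot(is(bundle, "PatientBundle"))
    nrow(bundle@aberrations)
}

#' Load a packaged cohort patient fixture
#'
#' The package ships per-patient fixture directories encoding the published
#' diagnostic findings of an eight-patient myeloid-neoplasia cohort
#' (variants with VAFs, ISCN karyotypes, clinical status per time point).
#' Metaphase and nuclei counts were not published at this granularity; the
#' packaged counts are synthetic (files are named `*.synthetic_counts.tsv`),
#' chosen consistent with the VAF-derived CCFs of co-clonal variants.
#'
#' @param n patient number, 1 to 8.
#' @return A [PatientBundle-class].
#' @examples
#' countAberrations(cohortPatient(3))   # 3 aberrations
#' @export
cohortPatient <- function(n) {
    dir <- system.file("extdata", "cohort", sprintf("patient%d", n),
                       package = "clonalCCF")
    if (!nzchar(dir)) stop("no packaged fixture for patient ", n)
    loadPatient(dir)
}

#' Read variants from a minimal VCF
#'
#' Optional VCF ingestion for the variant table: the VAF is taken from the
#' INFO `AF` field or computed from the FORMAT `AD` allele depths of the
#' first sample; the gene symbol is read from the INFO `GENE` field and the
#' transcript change from `HGVSC`. Requires the VariantAnnotation package.
#'
#' @param file VCF path.
#' @param patient patient identifier for the returned rows.
#' @param timepoint time point index for the returned rows.
#' @return A data.frame in the variants.tsv column layout.
#' @export
readVariantsVcf <- function(file, patient, timepoint) {
    if (!requireNamespace("VariantAnnotation", quietly = TRUE))
        stop("readVariantsVcf requires the VariantAnnotation package")
    vcf <- VariantAnnotation::readVcf(file)
    info <- VariantAnnotation::info(vcf)
    n <- nrow(vcf)
    vaf <- rep(NA_real_, n)
    depth <- rep(NA_real_, n)
    alt <- rep(NA_real_, n)
    if ("AF" %in% colnames(info))
        vaf <- vapply(info$AF, function(x) as.numeric(x)[1], numeric(1))
    gt <- VariantAnnotation::geno(vcf)
    if ("AD" %in% names(gt)) {
        ad <- gt$AD
        for (i in seq_len(n)) {
            counts <- unlist(ad[i, 1])
            if (length(counts) >= 2 && sum(counts) > 0) {
                depth[i] <- sum(counts[1:2])
                alt[i] <- counts[2]
                if (is.na(vaf[i])) vaf[i] <- alt[i] / depth[i]
            }
        }
    }
    gene <- if ("GENE" %in% colnames(info))
        as.character(unlist(info$GENE)) else rep(NA_character_, n)
    hgvs <- if ("HGVSC" %in% colnames(info))
        as.character(unlist(info$HGVSC)) else rownames(vcf)
    data.frame(patient = patient, timepoint = timepoint, gene = gene,
               hgvs_c = hgvs, hgvs_p = "", vaf_percent = 100 * vaf,
               depth = depth, alt_reads = alt, stringsAsFactors = FALSE)
}
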