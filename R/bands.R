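## Symbolic cytoband arithmetic.
##
## ISCN band designations order naturally within a chromosome arm: the first
## digit is the region, subsequent digits are band and sub-band, so q14 lies
## between q13 and q21 and the numeric sequence 1-4 sorts before 2-1. We
## exploit that ordering to compare band intervals without a coordinate
## table: band "14.2" maps to position 1 + 4/10 + 2/100. "ter" maps to +Inf
## (arm telomere), "10"/"cen" to the centromeric edge.

.bandPos <- function(band) {
    band <- tolower(band)
    if (band %in% c("ter", "pter", "qter")) return(Inf)
    if (band == "cen") return(0)
    digits <- strsplit(sub("\\.", "", band), "")[[1]]
    if (!length(digits) || !all(digits %in% as.character(0:9)))
        return(NA_real_)
    sum(as.numeric(digits) / 10^(seq_along(digits) - 1))
}

## Parse a band designation like "q14.1" into arm + position.
.parseBand <- function(s) {
    m <- regmatches(s, regexec("^([pq])((?:[0-9]+(?:\\.[0-9]+)?)|ter|cen)$", s))[[1]]
    if (!length(m)) return(NULL)
    list(arm = m[2], pos = .bandPos(m[3]))
}

## Parse a band interval string like "q14q33", "q14", "p12pter", or "q10"
## into (arm, lo, hi). A single band is a degenerate interval. Returns NULL
## on failure.
.parseBandInterval <- function(s) {
    s <- gsub("\\s", "", s)
    m <- regmatches(s, regexec(
        "^([pq])((?:[0-9]+(?:\\.[0-9]+)?)|ter|cen)(?:([pq])?((?:[0-9]+(?:\\.[0-9]+)?)|ter|cen))?$",
        s))[[1]]
    if (!length(m)) return(NULL)
    arm <- m[2]
    lo <- .bandPos(m[3])
    if (nzchar(m[5])) {
        arm2 <- if (nzchar(m[4])) m[4] else arm
        hi <- .bandPos(m[5])
        if (arm2 != arm) {
            ## interval spanning both arms: treat as whole chromosome
            return(list(arm = "*", lo = 0, hi = Inf))
        }
    } else hi <- lo
    if (is.na(lo) || is.na(hi)) return(NULL)
    list(arm = arm, lo = min(lo, hi), hi = max(lo, hi))
}

## Overlap test between two symbolic regions. Arm "*" means the whole
## chromosome. NA band bounds (locus unknown, e.g. a coordinate-only CGH
## segment matched against a band-level karyotype event) are treated as
## overlapping conservatively: chromosome identity alone decides.
.regionsOverlap <- function(chrom1, arm1, lo1, hi1, chrom2, arm2, lo2, hi2) {
    if (is.na(chrom1) || is.na(chrom2)) return(FALSE)
    if (chrom1 != chrom2) return(FALSE)
    if (is.na(arm1) || is.na(arm2)) return(TRUE)
    if (arm1 == "*" || arm2 == "*") return(TRUE)
    if (arm1 != arm2) return(FALSE)
    if (is.na(lo1) || is.na(lo2) || is.na(hi1) || is.na(hi2)) return(TRUE)
    lo1 <= hi2 && lo2 <= hi1
}

## Cytoband assignments of the leukemia-panel genes handled by the loader
## (standard gene positions; used to place variants relative to CNV regions
## and to pick the hemizygous context for X/Y genes in males).
.GENE_BANDS <- data.frame(
    gene  = c("ASXL1", "BCOR", "DNMT3A", "IDH1", "IDH2", "JAK2", "KRAS",
              "NF1", "NRAS", "PTPN11", "RUNX1", "SF3B1", "SRSF2", "STAG2",
              "TET2", "TP53", "U2AF1", "WT1", "EZH2", "FLT3", "NPM1",
              "CEBPA", "GATA2", "ETV6", "MECOM"),
    chrom = c("20", "X", "2", "2", "15", "9", "12",
              "17", "1", "12", "21", "2", "17", "X",
              "4", "17", "21", "11", "7", "13", "5",
              "19", "3", "12", "3"),
    band  = c("q11.21", "p11.4", "p23.3", "q34", "q26.1", "p24.1", "p12.1",
              "q11.2", "p13.2", "q24.13", "q22.12", "q33.1", "q25.1", "q25",
              "q24", "p13.1", "q22.3", "p13", "q36.1", "q12.2", "q35.1",
              "q13.11", "q21.3", "p13.2", "q26.2"),
    stringsAsFactors = FALSE)

#' Cytoband position of a panel gene
#'
#' Returns the chromosome, arm and symbolic band position of a gene from the
#' packaged leukemia-panel gene table. Used to decide whether a variant's
#' locus is covered by a copy-number event and whether an X/Y-linked variant
#' needs the hemizygous CCF context.
#'
#' @param gene gene symbol (e.g. "TP53").
#' @return A list with elements `chrom`, `arm`, `lo`, `hi` (symbolic band
#'   position, degenerate interval), or `NULL` when the gene is not in the
#'   packaged table.
#' @examples
#' geneBand("TP53")
#' @export
geneBand <- function(gene) {
    i <- match(gene, .GENE_BANDS$gene)
    if (is.na(i)) return(NULL)
    b <- .parseBand(.GENE_BANDS$band[i])
    list(chrom = .GENE_BANDS$chrom[i], arm = b$arm, lo = b$pos, hi = b$pos)
}
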