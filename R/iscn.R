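## Restricted ISCN karyotype parser.
##
## Covers the token subset seen in routine myeloid-neoplasia karyotypes:
## whole-chromosome gains/losses (+8, -17), del/dup with band intervals,
## isochromosomes, translocations, insertions, inversions, additional
## material of unknown origin (add), derivative chromosomes with an embedded
## translocation, marker chromosomes, and an xK copy multiplier. Ploidy/sex
## prefixes ("46,XX") are consumed and discarded. Zero-width Unicode
## characters, which publication tables are prone to carry, are stripped
## before tokenizing.

.ZW_CHARS <- "[\u200b\u200c\u200d\u2060\ufeff\u00a0]"

.iscnParseError <- function(token, offset) {
    structure(class = c("iscn_parse_error", "error", "condition"),
              list(message = sprintf(
                       "unsupported ISCN token '%s' at offset %d",
                       token, offset),
                   call = NULL, token = token, offset = offset))
}

.abRow <- function(id, kind, gene = NA_character_, hgvs = NA_character_,
                   iscn_token = NA_character_, chrom = NA_character_,
                   arm = NA_character_, band_start = NA_real_,
                   band_end = NA_real_, start = NA_real_, end = NA_real_,
                   cnv_direction = NA_character_, multiplicity = 1L) {
    data.frame(id = id, kind = kind, gene = gene, hgvs = hgvs,
               iscn_token = iscn_token, chrom = chrom, arm = arm,
               band_start = band_start, band_end = band_end,
               start = start, end = end, cnv_direction = cnv_direction,
               multiplicity = as.integer(multiplicity),
               stringsAsFactors = FALSE)
}

## Parse one cleaned ISCN token; NULL for ploidy/sex tokens, an aberration
## row otherwise, or an "iscn_parse_error" condition via stop().
.parseIscnToken <- function(token, offset) {
    tok <- sub("^\\?", "", token)
    mult <- 1L
    m <- regmatches(tok, regexec("^(.*)x([0-9]+)$", tok))[[1]]
    if (length(m) && grepl("[)0-9]$", m[2]) && grepl("\\(", m[2])) {
        tok <- m[2]
        mult <- as.integer(m[3])
    }
    ## ploidy / sex-chromosome prefix tokens: consumed, no aberration
    if (grepl("^[0-9]{2,3}(~[0-9]{2,3})?$", tok) || grepl("^X{1,3}Y{0,2}$|^Y$", tok))
        return(NULL)
    ## marker chromosomes: structural events of unknown locus
    if (grepl("^[+]?mar[0-9]*$", tok))
        return(.abRow(id = sub("^[+]", "", tok), kind = "sv",
                      iscn_token = token, multiplicity = mult))
    ## whole-chromosome gain/loss
    m <- regmatches(tok, regexec("^([+-])([0-9]{1,2}|X|Y)$", tok))[[1]]
    if (length(m)) {
        return(.abRow(id = tok, kind = "cnv", iscn_token = token,
                      chrom = m[3], arm = "*", band_start = 0,
                      band_end = Inf,
                      cnv_direction = if (m[2] == "+") "gain" else "loss",
                      multiplicity = mult))
    }
    ## derivative chromosome, optionally gained, with embedded translocation
    m <- regmatches(tok, regexec(
        "^[+]?der\\(([0-9XY]+)\\)(t\\([0-9XY;]+\\)(\\([^()]+\\))?)?$", tok))[[1]]
    if (length(m))
        return(.abRow(id = tok, kind = "sv", iscn_token = token,
                      chrom = m[2], multiplicity = mult))
    ## interstitial deletion / duplication with band interval
    m <- regmatches(tok, regexec(
        "^(del|dup)\\(([0-9XY]+)\\)\\(([^()]+)\\)$", tok))[[1]]
    if (length(m)) {
        iv <- .parseBandInterval(m[4])
        if (is.null(iv)) stop(.iscnParseError(token, offset))
        return(.abRow(id = tok, kind = "cnv", iscn_token = token,
                      chrom = m[3], arm = iv$arm, band_start = iv$lo,
                      band_end = iv$hi,
                      cnv_direction = if (m[2] == "del") "loss" else "gain",
                      multiplicity = mult))
    }
    ## isochromosome: net gain of the designated arm
    m <- regmatches(tok, regexec(
        "^i\\(([0-9XY]+)\\)\\(([pq])10\\)$", tok))[[1]]
    if (length(m))
        return(.abRow(id = tok, kind = "cnv", iscn_token = token,
                      chrom = m[2], arm = m[3], band_start = 0,
                      band_end = Inf, cnv_direction = "gain",
                      multiplicity = mult))
    ## translocation / insertion / inversion / added material
    m <- regmatches(tok, regexec(
        "^(t|ins|inv|add)\\(([0-9XY;]+)\\)(\\(([^()]+)\\))?$", tok))[[1]]
    if (length(m)) {
        chroms <- strsplit(m[3], ";")[[1]]
        arm <- NA_character_; lo <- NA_real_; hi <- NA_real_
        if (nzchar(m[5]) && !grepl(";", m[5])) {
            iv <- .parseBandInterval(m[5])
            if (!is.null(iv)) { arm <- iv$arm; lo <- iv$lo; hi <- iv$hi }
        }
        return(.abRow(id = tok, kind = "sv", iscn_token = token,
                      chrom = chroms[1], arm = arm, band_start = lo,
                      band_end = hi, multiplicity = mult))
    }
    stop(.iscnParseError(token, offset))
}

#' Parse an ISCN clone description into aberrations
#'
#' Tokenizes a comma-separated ISCN clone string over the restricted grammar
#' (+N, -N, del, dup, i, add, t, der(...)t(...), ins, inv, mar, with an
#' optional xK multiplier) and returns one aberration per token. Numeric
#' gains/losses, del/dup and isochromosomes map to copy-number aberrations
#' with a direction; t/ins/inv/add/der/mar map to structural variants. A
#' modal ploidy/sex prefix such as "46,XX" is consumed and discarded.
#'
#' @param clone_string ISCN clone description; zero-width Unicode characters
#'   and whitespace are stripped before tokenizing.
#' @return A data.frame of aberrations (see [PatientBundle-class] for the
#'   columns); zero rows for an empty string or a normal karyotype.
#' @examples
#' parseIscn("46,XX,del(5)(q14q33),-17,+mar1")
#' parseIscn("i(8)(q10)x2")   # single aberration, multiplicity 2
#' @seealso [formatIscn()] for re-serialization.
#' @export
parseIscn <- function(clone_string) {
    out <- .emptyAberrations()
    if (is.na(clone_string)) return(out)
    clean <- gsub(.ZW_CHARS, "", clone_string)
    clean <- gsub("\\s", "", clean)
    if (clean %in% c("", "-", "\u2013")) return(out)
    tokens <- strsplit(clean, ",", fixed = TRUE)[[1]]
    offsets <- c(0L, cumsum(nchar(tokens) + 1L))[seq_along(tokens)]
    for (i in seq_along(tokens)) {
        if (!nzchar(tokens[i])) next
        row <- .parseIscnToken(tokens[i], offsets[i] + 1L)
        if (!is.null(row)) out <- rbind(out, row)
    }
    out
}

#' Re-serialize aberrations to an ISCN token sequence
#'
#' Inverse of [parseIscn()] up to whitespace: reproduces the cleaned token
#' sequence, re-attaching xK multipliers.
#'
#' @param aberrations aberration data.frame as returned by [parseIscn()].
#' @return A single comma-separated ISCN string.
#' @export
formatIscn <- function(aberrations) {
    if (!nrow(aberrations)) return("")
    tok <- ifelse(is.na(aberrations$iscn_token), aberrations$id,
                  gsub(.ZW_CHARS, "", aberrations$iscn_token))
    base <- sub("x[0-9]+$", "", tok)
    needs_mult <- aberrations$multiplicity > 1L & !grepl("x[0-9]+$", tok)
    tok[needs_mult] <- paste0(base[needs_mult], "x",
                              aberrations$multiplicity[needs_mult])
    paste(tok, collapse = ",")
}
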