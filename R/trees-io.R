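## JSON serialization of clone trees. Reconstruction output and simulator
## truth files share this schema, so a recovered tree can be diffed against
## the truth directly.

#' Write clone trees to JSON
#'
#' @param trees list of [CloneTree-class] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrees <- function(trees, path) {
    payload <- lapply(trees, function(tr) {
        list(rank = tr@rank,
             pattern = tr@pattern,
             case_label = tr@caseLabel,
             timepoints = tr@timepoints,
             parents = tr@parent,
             clones = lapply(seq_along(tr@members), function(i)
                 list(id = i, aberrations = tr@members[[i]],
                      ccf = unname(tr@ccf[i, ]))),
             aberrations = if (nrow(tr@aberrations)) tr@aberrations else NULL)
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    invisible(path)
}

#' Read clone trees from JSON
#'
#' @param path file written by [writeTrees()].
#' @return List of [CloneTree-class] objects.
#' @export
readTrees <- function(path) {
    payload <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(payload, function(x) {
        nT <- length(x$timepoints)
        members <- lapply(x$clones, function(cl)
            as.character(unlist(cl$aberrations)))
        ccf <- do.call(rbind, lapply(x$clones, function(cl)
            as.numeric(unlist(cl$ccf))))
        colnames(ccf) <- as.integer(unlist(x$timepoints))
        ab <- if (!is.null(x$aberrations)) {
            ## absent keys (serialized NA) default back to NA, column types
            ## follow the canonical aberration table
            proto <- .emptyAberrations()
            df <- do.call(rbind, lapply(x$aberrations, function(r) {
                row <- proto[NA_integer_, , drop = FALSE]
                for (k in .ABERRATION_COLS) {
                    v <- r[[k]]
                    if (is.null(v)) next
                    if (identical(v, "Inf")) v <- Inf
                    row[[k]] <- v
                }
                row
            }))
            rownames(df) <- NULL
            df$multiplicity <- as.integer(ifelse(is.na(df$multiplicity), 1L,
                                                 df$multiplicity))
            df
        } else .emptyAberrations()
        new("CloneTree", members = members, ccf = ccf,
            parent = as.integer(unlist(x$parents)),
            pattern = x$pattern %||% NA_character_,
            rank = as.integer(x$rank %||% 1L),
            caseLabel = x$case_label %||% "",
            aberrations = ab,
            timepoints = as.integer(unlist(x$timepoints)))
    })
}
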