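## Fishplot export and rendering.
##
## The export converts a clone tree into the fraction-matrix + parent-vector
## form that stream-graph ("fishplot") renderers consume, in percent units.
## The renderer draws nested clone bodies as SVG with monotone cubic
## interpolation between time points; it writes the SVG text itself so that
## identical inputs yield identical bytes.

#' Export a clone tree in fishplot form
#'
#' Fractions are converted to percent. A clone that is present before and
#' after an intermediate zero time point is floored at `floor_pct` at the
#' interior points (and its ancestors lifted accordingly) so that its
#' rendered body stays topologically connected; every applied floor is
#' recorded in the `floors` slot.
#'
#' @param tree an admissible [CloneTree-class].
#' @param floor_pct interior floor in percent, default 0.1.
#' @param slack largest tolerated nesting excess in percent points (default
#'   5, matching the reconstruction slack delta = 0.05): excesses up to
#'   `slack` are normalized away by scaling the offending subtrees, larger
#'   ones are an error.
#' @return A [FishplotExport-class].
#' @export
exportFishplot <- function(tree, floor_pct = 0.1, slack = 5) {
    stopifnot(is(tree, "CloneTree"))
    validObject(tree)
    fr <- tree@ccf * 100
    n <- nrow(fr); nT <- ncol(fr)
    ## verify nesting within the reconstruction slack, then normalize:
    ## scale an over-full set of children (and their subtrees) down to the
    ## parent so every column obeys the strict sums
    scaleSubtree <- function(i, j, f) {
        fr[i, j] <<- fr[i, j] * f
        for (c in which(tree@parent == i)) scaleSubtree(c, j, f)
    }
    bfs <- integer()
    queue <- which(tree@parent == 0L)
    while (length(queue)) {
        bfs <- c(bfs, queue[1])
        queue <- c(queue[-1], which(tree@parent == queue[1]))
    }
    for (j in seq_len(nT)) {
        roots <- which(tree@parent == 0L)
        rsum <- sum(fr[roots, j])
        if (rsum > 100 + slack + 1e-6)
            stop("inadmissible tree: root clones exceed 100%")
        if (rsum > 100)
            for (r in roots) scaleSubtree(r, j, 100 / rsum)
        for (i in bfs) {
            ch <- which(tree@parent == i)
            if (!length(ch)) next
            csum <- sum(fr[ch, j])
            if (csum > fr[i, j] + slack + 1e-6)
                stop("inadmissible tree: children exceed parent CCF")
            if (csum > fr[i, j] && csum > 0)
                for (c in ch) scaleSubtree(c, j, fr[i, j] / csum)
        }
    }
    floors <- data.frame(clone = integer(), timepoint = integer(),
                         value = numeric())
    if (nT >= 3) for (i in seq_len(n)) {
        pos <- which(fr[i, ] > 0)
        if (length(pos) < 2) next
        interior <- setdiff(seq(min(pos), max(pos)), pos)
        for (j in interior) {
            fr[i, j] <- floor_pct
            floors <- rbind(floors, data.frame(
                clone = i, timepoint = tree@timepoints[j], value = floor_pct))
            ## lift ancestors so column sums stay nested
            a <- tree@parent[i]
            while (a != 0L) {
                ch <- which(tree@parent == a)
                fr[a, j] <- max(fr[a, j], sum(fr[ch, j]))
                a <- tree@parent[a]
            }
        }
    }
    fr <- pmin(fr, 100)
    labels <- vapply(tree@members, function(m)
        paste(m, collapse = ", "), character(1))
    ann <- data.frame(position = as.numeric(tree@timepoints),
                      marker = "analysis", stringsAsFactors = FALSE)
    new("FishplotExport", fractions = fr, parent = tree@parent,
        positions = as.numeric(tree@timepoints), annotations = ann,
        floors = floors, cloneLabels = labels)
}

#' Add a transplant marker to a fishplot export
#'
#' @param export a [FishplotExport-class].
#' @param position axis position (e.g. halfway between two time points).
#' @return The export with a "transplant" annotation appended.
#' @export
addTransplantMarker <- function(export, position) {
    export@annotations <- rbind(export@annotations, data.frame(
        position = position, marker = "transplant", stringsAsFactors = FALSE))
    export
}

#' Write fishplot CSV pair
#'
#' Writes `fractions.csv` (clones x time points, percent) and `parents.csv`
#' (clone, parent, label), the inputs that established fishplot renderers
#' consume, for cross-validation outside this package.
#'
#' @param export a [FishplotExport-class].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeFishplotCsv <- function(export, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fr <- as.data.frame(export@fractions)
    colnames(fr) <- paste0("t", export@positions)
    utils::write.csv(cbind(clone = seq_len(nrow(fr)), fr),
                     file.path(dir, "fractions.csv"), row.names = FALSE)
    utils::write.csv(data.frame(clone = seq_along(export@parent),
                                parent = export@parent,
                                label = export@cloneLabels),
                     file.path(dir, "parents.csv"), row.names = FALSE)
    invisible(dir)
}

## Monotone cubic (Fritsch-Carlson) interpolation of each clone's height on
## a dense grid; no overshoot, so interpolated heights stay non-negative.
.denseHeights <- function(fr, positions, samples_per_segment) {
    nT <- length(positions)
    if (nT == 1L) {
        xg <- positions
    } else {
        xg <- unique(unlist(lapply(seq_len(nT - 1L), function(j)
            seq(positions[j], positions[j + 1L],
                length.out = samples_per_segment + 1L))))
    }
    H <- matrix(0, nrow(fr), length(xg))
    for (i in seq_len(nrow(fr))) {
        H[i, ] <- if (nT == 1L) fr[i, 1L] else
            stats::splinefun(positions, fr[i, ], method = "monoH.FC")(xg)
        H[i, ] <- pmax(H[i, ], 0)
    }
    list(x = xg, H = H)
}

## Vertical spans per clone at one grid column: siblings are stacked,
## centered inside their parent's span; children scaled down if
## interpolation transiently overshoots the parent.
.stackColumn <- function(h, parent) {
    n <- length(h)
    lo <- numeric(n); hi <- numeric(n)
    place <- function(children, span_lo, span_hi) {
        avail <- span_hi - span_lo
        tot <- sum(h[children])
        scale <- if (tot > avail && tot > 0) avail / tot else 1
        pad <- max(0, avail - tot * scale) / 2
        cur <- span_lo + pad
        for (c in children) {
            hh <- h[c] * scale
            lo[c] <<- cur; hi[c] <<- cur + hh
            kids <- which(parent == c)
            if (length(kids)) place(kids, lo[c], hi[c])
            cur <- cur + hh
        }
    }
    place(which(parent == 0L), 0, 100)
    list(lo = lo, hi = hi)
}

.FISH_PALETTE <- c("#3C5488", "#E64B35", "#4DBBD5", "#00A087", "#F39B7F",
                   "#8491B4", "#91D1C2", "#DC0000", "#7E6148", "#B09C85",
                   "#E6A817", "#5F559B")

#' Render a fishplot export to SVG
#'
#' Draws nested clone bodies with monotone cubic interpolation between time
#' points, black triangles at analyzed time points and white triangles at
#' transplant markers. The SVG text is generated directly with fixed number
#' formatting: rendering is pure, and identical inputs produce identical
#' bytes.
#'
#' @param export a [FishplotExport-class].
#' @param file output path (".svg").
#' @param width,height canvas size in pixels.
#' @param palette clone fill colors, recycled as needed.
#' @param samples_per_segment interpolation density between adjacent time
#'   points.
#' @return `file`, invisibly.
#' @export
renderFishplot <- function(export, file, width = 800, height = 400,
                           palette = .FISH_PALETTE,
                           samples_per_segment = 24L) {
    stopifnot(is(export, "FishplotExport"))
    validObject(export)
    fr <- export@fractions
    n <- nrow(fr)
    pos <- export@positions
    margin <- c(30, 40, 30, 20)   # top, bottom, left, right
    xr <- range(pos)
    if (diff(xr) < 1e-9) xr <- xr + c(-0.5, 0.5)
    px <- function(x) margin[3] + (x - xr[1]) / diff(xr) *
        (width - margin[3] - margin[4])
    py <- function(y) margin[1] + (100 - y) / 100 * (height - margin[1] - margin[2])
    fmt <- function(v) sprintf("%.2f", v)
    lines <- c(sprintf(
        '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
        width, height, width, height),
        sprintf('<rect width="%d" height="%d" fill="white"/>', width, height))
    if (n > 0) {
        dh <- .denseHeights(fr, pos, samples_per_segment)
        nz <- length(dh$x)
        LO <- matrix(0, n, nz); HI <- matrix(0, n, nz)
        for (j in seq_len(nz)) {
            st <- .stackColumn(dh$H[, j], export@parent)
            LO[, j] <- st$lo; HI[, j] <- st$hi
        }
        ## draw parents before children so nested bodies sit on top
        depth <- integer(n)
        for (i in seq_len(n)) {
            d <- 0L; j <- i
            while (export@parent[j] != 0L) { j <- export@parent[j]; d <- d + 1L }
            depth[i] <- d
        }
        for (i in order(depth, seq_len(n))) {
            if (all(HI[i, ] - LO[i, ] <= 1e-9)) next
            top <- paste(sprintf("%s,%s", fmt(px(dh$x)), fmt(py(HI[i, ]))),
                         collapse = " ")
            bot <- paste(sprintf("%s,%s", fmt(px(rev(dh$x))),
                                 fmt(py(LO[i, rev(seq_len(nz))]))),
                         collapse = " ")
            col <- palette[(i - 1L) %% length(palette) + 1L]
            lines <- c(lines, sprintf(
                '<polygon points="%s %s" fill="%s" fill-opacity="0.85" stroke="%s" stroke-width="0.5"/>',
                top, bot, col, col))
        }
    }
    for (r in seq_len(nrow(export@annotations))) {
        xpx <- px(export@annotations$position[r])
        black <- export@annotations$marker[r] == "analysis"
        lines <- c(lines, sprintf(
            '<polygon points="%s,%s %s,%s %s,%s" fill="%s" stroke="black" stroke-width="0.8"/>',
            fmt(xpx - 5), fmt(margin[1] - 14), fmt(xpx + 5),
            fmt(margin[1] - 14), fmt(xpx), fmt(margin[1] - 5),
            if (black) "black" else "white"))
    }
    lines <- c(lines, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="1"/>',
        fmt(px(xr[1])), fmt(py(0)), fmt(px(xr[2])), fmt(py(0))),
        '</svg>')
    con <- file(file, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    invisible(file)
}
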