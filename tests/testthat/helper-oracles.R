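# Independent oracles and in-code fixtures shared across test files.

# Brute-force clone-tree enumeration: scan every parent vector (0 = root)
# and keep those satisfying acyclicity, appearance order and the nesting
# sums. Independent of the package's pruned DFS.
bruteForceTrees <- function(ccf, delta) {
    n <- nrow(ccf)
    first_tp <- apply(ccf, 1, function(x) {
        nz <- which(x > 1e-9); if (length(nz)) nz[1] else Inf })
    grids <- rep(list(0:n), n)
    all_vec <- as.matrix(expand.grid(grids))
    keep <- list()
    for (r in seq_len(nrow(all_vec))) {
        p <- as.integer(all_vec[r, ])
        if (any(p == seq_len(n))) next
        # acyclic?
        ok <- TRUE
        for (i in seq_len(n)) {
            seen <- logical(n); j <- i
            while (ok && p[j] != 0L) {
                j <- p[j]
                if (seen[j]) ok <- FALSE
                seen[j] <- TRUE
            }
            if (!ok) break
        }
        if (!ok) next
        # appearance order
        for (i in seq_len(n)) {
            if (p[i] != 0L && first_tp[p[i]] > first_tp[i]) { ok <- FALSE; break }
        }
        if (!ok) next
        # nesting sums at every time point
        for (tp in seq_len(ncol(ccf))) {
            if (sum(ccf[p == 0L, tp]) > 1 + delta + 1e-12) { ok <- FALSE; break }
            for (i in seq_len(n)) {
                ch <- which(p == i)
                if (length(ch) && sum(ccf[ch, tp]) > ccf[i, tp] + delta + 1e-12) {
                    ok <- FALSE; break
                }
            }
            if (!ok) break
        }
        if (ok) keep[[length(keep) + 1L]] <- p
    }
    keep
}

# 0.05-step simplex grid of (w, x, y, z) fractions summing to 1.
simplexGrid <- function(step = 0.05) {
    k <- round(1 / step)
    out <- list()
    for (i in 0:k) for (j in 0:(k - i)) for (l in 0:(k - i - j)) {
        out[[length(out) + 1L]] <- c(i, j, l, k - i - j - l) * step
    }
    do.call(rbind, out)
}

# A 4-clone branched truth tree over two time points: a cytogenetic
# stemline and three variant subclones with well-separated CCFs.
makeTruthTree <- function() {
    ab <- rbind(
        clonalCCF:::.abRow(id = "del(5)(q14q33)", kind = "cnv",
                           iscn_token = "del(5)(q14q33)", chrom = "5",
                           arm = "q", band_start = 1.4, band_end = 3.3,
                           cnv_direction = "loss"),
        clonalCCF:::.abRow(id = "DNMT3A c.2645G>A", kind = "snv",
                           gene = "DNMT3A", hgvs = "c.2645G>A"),
        clonalCCF:::.abRow(id = "TET2 c.1455del", kind = "indel",
                           gene = "TET2", hgvs = "c.1455del"),
        clonalCCF:::.abRow(id = "RUNX1 c.420T>G", kind = "snv",
                           gene = "RUNX1", hgvs = "c.420T>G"))
    ccf <- matrix(c(0.95, 0.95,
                    0.60, 0.70,
                    0.25, 0.05,
                    0.00, 0.35), 4, 2, byrow = TRUE,
                  dimnames = list(NULL, c(0, 1)))
    methods::new("CloneTree",
                 members = list("del(5)(q14q33)", "DNMT3A c.2645G>A",
                                "TET2 c.1455del", "RUNX1 c.420T>G"),
                 ccf = ccf, parent = c(0L, 1L, 1L, 2L), pattern = "branched",
                 rank = 1L, timepoints = c(0L, 1L), aberrations = ab)
}

# binomial standard errors of the truth clone CCFs under the simulated
# sampling design (variants: depth reads at VAF = CCF/2, rescaled by 2;
# cytogenetics: metaphases and FISH nuclei combined by precision).
truthCloneSE <- function(tree, depth, n_metaphases, n_nuclei) {
    ccf <- cloneCCF(tree)
    kinds <- aberrations(tree)$kind[match(vapply(cloneMembers(tree), `[`, "", 1),
                                          aberrations(tree)$id)]
    se <- ccf
    for (i in seq_len(nrow(ccf))) for (j in seq_len(ncol(ccf))) {
        f <- ccf[i, j]
        if (kinds[i] %in% c("snv", "indel")) {
            v <- f / 2
            se[i, j] <- 2 * sqrt(v * (1 - v) / depth)
        } else {
            s_k <- sqrt(f * (1 - f) / n_metaphases)
            s_f <- sqrt(f * (1 - f) / n_nuclei)
            se[i, j] <- if (f %in% c(0, 1)) 0 else
                1 / sqrt(1 / s_k^2 + 1 / s_f^2)
        }
    }
    se
}

# Build a loadable patient directory from in-code tables.
writePatientDir <- function(dir, config, variants = NULL, karyotype = NULL,
                            fish = NULL, cgh = NULL) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    yaml::write_yaml(config, file.path(dir, "config.yaml"))
    wt <- function(x, f) utils::write.table(
        x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(variants)) wt(variants, config$files$variants)
    if (!is.null(karyotype)) wt(karyotype, config$files$karyotype)
    if (!is.null(fish)) wt(fish, config$files$fish)
    if (!is.null(cgh)) wt(cgh, config$files$cgh)
    dir
}
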