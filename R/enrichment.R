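#' Summarize a group of profiles by median and quantile band
#'
#' @param m numeric matrix, sites x 10 time points (e.g. a subset of
#'   [profileMatrix()] rows); must be non-empty.
#' @param band length-2 quantile pair; default `c(0.05, 0.95)` (central 90%),
#'   use `c(0.25, 0.75)` for an interquartile band.
#' @return data.frame per time point: `time`, `median`, `lower`, `upper`,
#'   `n_sites`.
#' @export
summarizeGroup <- function(m, band = c(0.05, 0.95)) {
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    if (nrow(m) == 0L) stop("empty profile group")
    stopifnot(length(band) == 2L, band[1L] <= band[2L])
    data.frame(time = timeGrid(),
               median = apply(m, 2L, stats::median),
               lower = apply(m, 2L, stats::quantile, probs = band[1L]),
               upper = apply(m, 2L, stats::quantile, probs = band[2L]),
               n_sites = nrow(m))
}

#' Plot a group profile summary
#'
#' Median line with the quantile band, base graphics.
#'
#' @param summary output of [summarizeGroup()].
#' @param main plot title.
#' @param col line/band colour.
#' @return invisibly, `NULL`.
#' @export
plotGroupSummary <- function(summary, main = "", col = "black") {
    graphics::plot(summary$time, summary$median, type = "n",
                   ylim = range(summary$lower, summary$upper),
                   xlab = "time after release (min)",
                   ylab = "log2 intensity (anchored)", main = main)
    graphics::polygon(c(summary$time, rev(summary$time)),
                      c(summary$lower, rev(summary$upper)),
                      col = grDevices::adjustcolor(col, 0.2), border = NA)
    graphics::lines(summary$time, summary$median, col = col, lwd = 2)
    invisible(NULL)
}

#' Positional residue enrichment of a foreground window set
#'
#' For every offset -6..+6 (excluding 0) and residue, compares the
#' foreground frequency against the background frequency from the whole
#' dataset. The percentage difference is foreground minus background
#' frequency in percentage points; each cell's p-value is a two-sided exact
#' binomial test of the foreground count against the background frequency,
#' significant below the detection threshold (default p = 0.01, per cell, no
#' multiple-testing correction). Padding characters are excluded from the
#' frequency denominators; offsets where either set holds only padding are
#' skipped.
#'
#' @param fg_windows foreground 13-mers (non-empty).
#' @param bg_windows background 13-mers (the dataset the foreground was
#'   extracted from).
#' @param p_threshold per-cell detection threshold; default 0.01.
#' @return data.frame sorted by `|pct_diff|` descending: `offset`,
#'   `residue`, `fg_freq`, `bg_freq`, `pct_diff`, `p_value`, `significant`.
#' @export
icelogoEnrich <- function(fg_windows, bg_windows, p_threshold = 0.01) {
    if (!length(fg_windows)) stop("empty foreground window set")
    stopifnot(all(nchar(c(fg_windows, bg_windows)) == 13L))
    rows <- list()
    for (off in setdiff(-6:6, 0L)) {
        idx <- off + 7L
        fg <- substr(fg_windows, idx, idx)
        bg <- substr(bg_windows, idx, idx)
        fg <- fg[fg != "_"]; bg <- bg[bg != "_"]
        if (!length(fg) || !length(bg)) next
        bg_tab <- table(bg) / length(bg)
        for (res in sort(unique(c(fg, names(bg_tab))))) {
            k <- sum(fg == res)
            p_bg <- if (res %in% names(bg_tab)) as.numeric(bg_tab[[res]]) else 0
            pv <- stats::binom.test(k, length(fg), p_bg)$p.value
            rows[[length(rows) + 1L]] <- data.frame(
                offset = off, residue = res,
                fg_freq = k / length(fg), bg_freq = p_bg,
                pct_diff = 100 * (k / length(fg) - p_bg),
                p_value = pv, significant = pv < p_threshold,
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out <- out[order(-abs(out$pct_diff), out$offset, out$residue), ]
    rownames(out) <- NULL
    out
}

#' Rank sites by distance to an expected profile
#'
#' Computes, per site, the root-mean-square Euclidean distance between its
#' anchored profile (concatenated over the conditions the template defines)
#' and the template, and returns the `k` closest sites. Dividing by the
#' dimension count makes single- and two-condition templates comparable.
#' Ties are broken by site key, so the ranking is independent of input
#' order.
#'
#' @param x an anchored `PhosphoSet`.
#' @param template list with `name` and `ctrl` and/or `mut` length-10
#'   profiles (conditions absent from the template are ignored).
#' @param k number of sites to return (> 0).
#' @return data.frame of the top-`k` sites ascending by `distance`.
#' @export
templateMatch <- function(x, template, k = 29L) {
    if (k <= 0) stop("k must be positive")
    conds <- intersect(c("ctrl", "mut"), names(template))
    conds <- conds[!vapply(template[conds], is.null, TRUE)]
    if (!length(conds)) stop("template defines no condition profiles")
    tvec <- unlist(template[conds], use.names = FALSE)
    m <- do.call(cbind, lapply(conds, function(cc) profileMatrix(x, cc)))
    stopifnot(ncol(m) == length(tvec))
    d <- sqrt(rowMeans(sweep(m, 2L, tvec)^2))
    keys <- siteKeys(x)
    ord <- order(d, keys)
    rd <- SummarizedExperiment::rowData(x)
    k <- min(k, nrow(x))
    sel <- ord[seq_len(k)]
    data.frame(protein_id = rd$protein_id[sel], position = rd$position[sel],
               residue = rd$residue[sel], distance = d[sel],
               rank = seq_len(k), stringsAsFactors = FALSE)
}

#' Complete-linkage hierarchical clustering of profiles
#'
#' Euclidean distances between anchored control profiles (optionally
#' concatenated with the mutant), complete agglomeration, and a cut into
#' `n_subtrees` clusters. The absolute (unscaled) log2 values are used so
#' differences in phosphorylation level are preserved. Cluster labels are
#' relabelled in order of each cluster's median time-of-extreme so label 1
#' is the earliest-responding cluster.
#'
#' @param x an anchored `PhosphoSet` with at least `n_subtrees` sites.
#' @param n_subtrees number of clusters to cut (default 12).
#' @param conditions which condition profiles feed the distance.
#' @return list: `labels` (named integer vector by site key), `tree`
#'   (the [stats::hclust] object), `n_subtrees`.
#' @export
hierCluster <- function(x, n_subtrees = 12L, conditions = "ctrl") {
    if (nrow(x) < n_subtrees)
        stop("fewer sites (", nrow(x), ") than requested subtrees (",
             n_subtrees, ")")
    m <- do.call(cbind, lapply(conditions, function(cc) profileMatrix(x, cc)))
    rownames(m) <- siteKeys(x)
    tree <- stats::hclust(stats::dist(m, method = "euclidean"),
                          method = "complete")
    raw <- stats::cutree(tree, k = n_subtrees)
    # deterministic relabelling: by median time at which members peak
    t_ext <- timeGrid()[apply(abs(m[, seq_len(10L), drop = FALSE]), 1L,
                              which.max)]
    med_t <- vapply(split(t_ext, raw), stats::median, numeric(1))
    new_order <- order(med_t, as.integer(names(med_t)))
    relabel <- integer(n_subtrees)
    relabel[as.integer(names(med_t))[new_order]] <- seq_len(n_subtrees)
    labels <- relabel[raw]
    names(labels) <- names(raw)
    list(labels = labels, tree = tree, n_subtrees = n_subtrees)
}
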