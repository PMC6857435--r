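#' Filter phosphosites by quality and plex-group completeness
#'
#' Retains sites from singly phosphorylated peptides (`multiplicity == 1`)
#' with localization probability strictly greater than `cfg$loc_prob_min`
#' that were quantified in all 10 channels of at least one plex group
#' (5 time points x 2 conditions). The boundary is strict: a localization
#' probability of exactly 0.75 is rejected under the default cutoff.
#'
#' @param x a `PhosphoSet`.
#' @param cfg a [dynamicsConfig()].
#' @return list with `retained` (a `PhosphoSet`) and `rejects` (data.frame
#'   with the failed rule per dropped site: one of `"multiplicity"`,
#'   `"loc_prob"`, `"incomplete_plex"`; the first failing rule in that order
#'   is reported).
#' @export
filterSites <- function(x, cfg = dynamicsConfig()) {
    rd <- SummarizedExperiment::rowData(x)
    cd <- SummarizedExperiment::colData(x)
    vals <- SummarizedExperiment::assays(x)[["log2intensity"]]
    completeA <- rowSums(is.na(vals[, cd$plex_group == "A", drop = FALSE])) == 0L
    completeB <- rowSums(is.na(vals[, cd$plex_group == "B", drop = FALSE])) == 0L
    reason <- rep(NA_character_, nrow(x))
    reason[!(completeA | completeB)] <- "incomplete_plex"
    reason[!(rd$loc_prob > cfg$loc_prob_min)] <- "loc_prob"
    reason[rd$multiplicity != 1L] <- "multiplicity"
    keep <- is.na(reason)
    if (!any(keep))
        warning("no sites pass the filters")
    rejects <- data.frame(protein_id = rd$protein_id[!keep],
                          position = rd$position[!keep],
                          residue = rd$residue[!keep],
                          reason = reason[!keep],
                          stringsAsFactors = FALSE)
    list(retained = x[keep, ], rejects = rejects)
}

#' Channel- and site-median normalization
#'
#' Two sequential median subtractions on the log2 scale: first, each channel
#' (one condition x time column) is centred by subtracting the median over
#' all sites measured in that channel; second, each site is centred by
#' subtracting the median of its own values across all of its channels (both
#' plex groups and both conditions). After the second step every site's
#' median over its present values is 0 by construction.
#'
#' @param x a `PhosphoSet` with `scaleTag(x) == "raw_log2"`.
#' @return the normalized `PhosphoSet`, `scaleTag == "median_normalized"`.
#' @export
medianNormalize <- function(x) {
    if (scaleTag(x) != "raw_log2")
        stop("medianNormalize expects a raw_log2 PhosphoSet, got ",
             scaleTag(x))
    vals <- SummarizedExperiment::assays(x)[["log2intensity"]]
    chan_med <- apply(vals, 2L, stats::median, na.rm = TRUE)
    empty <- !is.finite(chan_med)
    if (any(empty))
        stop("channel(s) with no measured values: ",
             paste(colnames(vals)[empty], collapse = ", "))
    vals <- sweep(vals, 2L, chan_med)
    site_med <- apply(vals, 1L, stats::median, na.rm = TRUE)
    vals <- sweep(vals, 1L, site_med)
    SummarizedExperiment::assays(x)[["log2intensity"]] <- vals
    S4Vectors::metadata(x)$scale_tag <- "median_normalized"
    x
}

# per-condition imputation of one site row given grid-ordered values
.imputeRow <- function(v) {
    miss <- which(is.na(v))
    out <- v
    irregular <- FALSE
    for (i in miss) {
        if (i == 1L) {
            nb <- v[2L]
        } else if (i == 10L) {
            nb <- v[9L]
        } else {
            left <- v[i - 1L]; right <- v[i + 1L]
            nb <- if (!is.na(left) && !is.na(right)) mean(c(left, right))
                  else NA_real_
        }
        if (is.na(nb)) {
            # irregular gap: nearest measured neighbour on the grid
            meas <- which(!is.na(v))
            if (!length(meas)) stop("site with no measured values")
            nb <- v[meas[which.min(abs(meas - i))]]
            irregular <- TRUE
        }
        out[i] <- nb
    }
    list(values = out, imputed = miss, irregular = irregular)
}

#' Impute missing time points from adjacent measurements
#'
#' A missing value at an interior grid position becomes the mean of the
#' values at the two immediately adjacent grid times, which are measured by
#' design when a whole alternating plex group is absent. A missing 0-minute
#' value copies the 5-minute value and a missing 90-minute value copies the
#' 60-minute value. Imputed cells are flagged `status = "imputed"`; cells in
#' irregular gaps (both neighbours missing) are filled from the nearest
#' measured time point with a warning. The fraction of values imputed is
#' recorded in `metadata(x)$imputed_fraction`.
#'
#' @param x a `PhosphoSet` (any scale; normally after [medianNormalize()]).
#' @return the imputed `PhosphoSet` with no missing values.
#' @export
imputeMissing <- function(x) {
    vals <- SummarizedExperiment::assays(x)[["log2intensity"]]
    stat <- SummarizedExperiment::assays(x)[["status"]]
    cd <- SummarizedExperiment::colData(x)
    irregular_sites <- character(0)
    for (cond in .CONDITIONS) {
        sel <- which(cd$condition == cond)
        sel <- sel[order(cd$time[sel])]
        sub <- vals[, sel, drop = FALSE]
        rows <- which(rowSums(is.na(sub)) > 0L)
        for (r in rows) {
            imp <- .imputeRow(sub[r, ])
            vals[r, sel] <- imp$values
            stat[r, sel[imp$imputed]] <- "imputed"
            if (imp$irregular)
                irregular_sites <- c(irregular_sites, rownames(vals)[r])
        }
    }
    if (length(irregular_sites))
        warning("irregular gaps (both neighbours missing) filled from ",
                "nearest measured time point for: ",
                paste(unique(irregular_sites), collapse = ", "))
    SummarizedExperiment::assays(x)[["log2intensity"]] <- vals
    SummarizedExperiment::assays(x)[["status"]] <- stat
    S4Vectors::metadata(x)$imputed_fraction <- mean(stat == "imputed")
    x
}

# simultaneous-update smoothing of one grid-ordered row
.smoothRow <- function(v, mode) {
    n <- length(v)
    out <- v
    if (mode == "paper") {
        out[1L] <- v[2L]
        out[n] <- v[n - 1L]
        for (i in 2:(n - 1L)) out[i] <- (v[i - 1L] + v[i + 1L]) / 2
    } else {  # centered3
        out[1L] <- (v[1L] + v[2L]) / 2
        out[n] <- (v[n - 1L] + v[n]) / 2
        for (i in 2:(n - 1L)) out[i] <- (v[i - 1L] + v[i] + v[i + 1L]) / 3
    }
    out
}

#' Smooth profiles by neighbour averaging
#'
#' Default mode `"paper"` replaces every value by the mean of its two grid
#' neighbours' pre-smoothing values (a simultaneous update, so the result
#' does not depend on traversal order); the 0-minute value is replaced by
#' the pre-smoothing 5-minute value and the 90-minute value by the 60-minute
#' value. Mode `"centered3"` instead takes the mean of each value and its
#' two neighbours, which leaves index-linear profiles unchanged. Cells whose
#' value changed are flagged `status = "smoothed"`.
#'
#' @param x a fully imputed `PhosphoSet`.
#' @param mode `"paper"` or `"centered3"`.
#' @return the smoothed `PhosphoSet`.
#' @export
smoothProfiles <- function(x, mode = c("paper", "centered3")) {
    mode <- match.arg(mode)
    vals <- SummarizedExperiment::assays(x)[["log2intensity"]]
    if (anyNA(vals))
        stop("smoothing requires a fully imputed matrix")
    stat <- SummarizedExperiment::assays(x)[["status"]]
    cd <- SummarizedExperiment::colData(x)
    for (cond in .CONDITIONS) {
        sel <- which(cd$condition == cond)
        sel <- sel[order(cd$time[sel])]
        sub <- vals[, sel, drop = FALSE]
        sm <- t(apply(sub, 1L, .smoothRow, mode = mode))
        changed <- sm != sub
        vals[, sel] <- sm
        st <- stat[, sel, drop = FALSE]
        st[changed] <- "smoothed"
        stat[, sel] <- st
    }
    SummarizedExperiment::assays(x)[["log2intensity"]] <- vals
    SummarizedExperiment::assays(x)[["status"]] <- stat
    S4Vectors::metadata(x)$smooth_mode <- mode
    x
}

#' Anchor profiles at time zero
#'
#' Per site and condition, subtracts the 0-minute value so every profile
#' starts at exactly 0 (a metaphase-release anchor). Differences between
#' time points are unchanged; constant offsets vanish.
#'
#' @param x a `PhosphoSet` with `scaleTag == "median_normalized"`.
#' @return the anchored `PhosphoSet`, `scaleTag == "t0_normalized"`.
#' @export
anchorT0 <- function(x) {
    if (scaleTag(x) != "median_normalized")
        stop("anchorT0 expects a median_normalized PhosphoSet, got ",
             scaleTag(x))
    vals <- SummarizedExperiment::assays(x)[["log2intensity"]]
    cd <- SummarizedExperiment::colData(x)
    for (cond in .CONDITIONS) {
        sel <- which(cd$condition == cond)
        t0col <- sel[cd$time[sel] == 0L]
        vals[, sel] <- vals[, sel, drop = FALSE] - vals[, t0col]
    }
    SummarizedExperiment::assays(x)[["log2intensity"]] <- vals
    S4Vectors::metadata(x)$scale_tag <- "t0_normalized"
    x
}

#' Run the full preprocessing chain
#'
#' filter -> median normalize -> impute -> smooth (optional) -> anchor,
#' the fixed stage order enforced by the scale tag.
#'
#' @param x a raw `PhosphoSet`.
#' @param cfg a [dynamicsConfig()].
#' @param smooth logical; set `FALSE` for sensitivity checks without the
#'   smoothing pass.
#' @param smooth_mode `"paper"` or `"centered3"`.
#' @return list with `profiles` (anchored `PhosphoSet`) and `rejects`.
#' @export
preprocessPhospho <- function(x, cfg = dynamicsConfig(), smooth = TRUE,
                              smooth_mode = "paper") {
    flt <- filterSites(x, cfg)
    y <- medianNormalize(flt$retained)
    y <- imputeMissing(y)
    if (smooth)
        y <- smoothProfiles(y, smooth_mode)
    y <- anchorT0(y)
    list(profiles = y, rejects = flt$rejects)
}

#' Fraction of values imputed during preprocessing
#'
#' @param x a `PhosphoSet` that has passed [imputeMissing()].
#' @return numeric fraction in `[0,1]`.
#' @export
imputedFraction <- function(x) {
    f <- S4Vectors::metadata(x)$imputed_fraction
    if (is.null(f)) stop("object has not been through imputeMissing()")
    f
}
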