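#' Classify one anchored profile into a dynamics category
#'
#' Implements the run-based rule: a 1.5-fold decrease (or increase) in
#' phosphosite abundance sustained over at least `min_run` consecutive time
#' points qualifies a site as dephosphorylated (or phosphorylated); a
#' qualifying excursion that is later followed by at least `return_run`
#' consecutive points strictly inside the threshold band is transient; a
#' profile that never sustains a qualifying run in either direction is
#' stable. Threshold comparisons are inclusive (`<= -theta`, `>= +theta`
#' with `theta = log2(fold_threshold)`), so the three rules partition all
#' profiles. If both directions qualify, the temporally earlier run decides
#' the category and the other direction is noted in `secondary_flag`.
#' Timing is the grid time of the first point of the qualifying run.
#'
#' @param profile numeric length-10 anchored log2 series on [timeGrid()]
#'   (`profile[1] == 0`); no missing values.
#' @param cfg a [dynamicsConfig()].
#' @return list: `category` (one of dephosphorylated, phosphorylated,
#'   transient_down, transient_up, stable), `timing_min` (minutes, `NA` for
#'   stable) and `secondary_flag` (`NA` or the opposite direction).
#' @export
classifySite <- function(profile, cfg = dynamicsConfig()) {
    if (anyNA(profile))
        stop("profile contains missing values; preprocessing contract violated")
    n <- length(profile)
    th <- cfg$theta
    firstRun <- function(flags, len) {
        r <- rle(flags)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        hit <- which(r$values & r$lengths >= len)
        if (!length(hit)) NULL else c(starts[hit[1L]], ends[hit[1L]])
    }
    down <- firstRun(profile <= -th, cfg$min_run)
    up <- firstRun(profile >= th, cfg$min_run)
    if (is.null(down) && is.null(up))
        return(list(category = "stable", timing_min = NA_real_,
                    secondary_flag = NA_character_))
    if (is.null(up) || (!is.null(down) && down[1L] < up[1L])) {
        run <- down; dir <- "down"
        secondary <- if (is.null(up)) NA_character_ else "up"
    } else {
        run <- up; dir <- "up"
        secondary <- if (is.null(down)) NA_character_ else "down"
    }
    inside <- abs(profile) < th
    returned <- FALSE
    if (run[2L] < n) {
        later <- inside[(run[2L] + 1L):n]
        ret <- firstRun(later, cfg$return_run)
        returned <- !is.null(ret)
    }
    category <- if (dir == "down") {
        if (returned) "transient_down" else "dephosphorylated"
    } else {
        if (returned) "transient_up" else "phosphorylated"
    }
    list(category = category, timing_min = as.numeric(timeGrid()[run[1L]]),
         secondary_flag = secondary)
}

#' Classify every site of one condition
#'
#' @param x an anchored `PhosphoSet` (`scaleTag == "t0_normalized"`).
#' @param cfg a [dynamicsConfig()].
#' @param condition `"ctrl"` or `"mut"`.
#' @return data.frame of category calls: protein_id, position, residue,
#'   condition, category, timing_min, secondary_flag.
#' @export
classifyProfiles <- function(x, cfg = dynamicsConfig(), condition = "ctrl") {
    if (scaleTag(x) != "t0_normalized")
        stop("classification expects t0-anchored profiles")
    m <- profileMatrix(x, condition)
    rd <- SummarizedExperiment::rowData(x)
    out <- data.frame(protein_id = rd$protein_id, position = rd$position,
                      residue = rd$residue, condition = condition,
                      category = NA_character_, timing_min = NA_real_,
                      secondary_flag = NA_character_,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(m))) {
        cl <- classifySite(m[i, ], cfg)
        out$category[i] <- cl$category
        out$timing_min[i] <- cl$timing_min
        out$secondary_flag[i] <- cl$secondary_flag
    }
    out
}

#' Group sites by threshold-crossing time
#'
#' Partitions non-stable calls of one condition into timing classes (one per
#' grid time at which sites first cross the threshold) and computes each
#' class's mean profile.
#'
#' @param calls output of [classifyProfiles()] for one condition.
#' @param x the anchored `PhosphoSet` the calls came from.
#' @param categories which categories to include (default lasting
#'   dephosphorylation, the classical timing analysis).
#' @return list keyed by timing (minutes, ascending); each element holds
#'   `site_keys`, `n` and `mean_profile` (length 10).
#' @export
timingGroups <- function(calls, x,
                         categories = "dephosphorylated") {
    stopifnot(length(unique(calls$condition)) <= 1L)
    if (!nrow(calls)) return(list())
    sel <- calls$category %in% categories & !is.na(calls$timing_min)
    if (!any(sel)) return(list())
    calls <- calls[sel, , drop = FALSE]
    cond <- calls$condition[1L]
    m <- profileMatrix(x, cond)
    keys <- siteKeys(x)
    out <- list()
    for (tm in sort(unique(calls$timing_min))) {
        ck <- paste(calls$protein_id[calls$timing_min == tm],
                    calls$position[calls$timing_min == tm],
                    calls$residue[calls$timing_min == tm], sep = "_")
        rows <- match(ck, keys)
        out[[as.character(tm)]] <- list(
            site_keys = ck, n = length(ck),
            mean_profile = colMeans(m[rows, , drop = FALSE]))
    }
    out
}

#' Cardinalities of every region of a Venn partition
#'
#' @param sets named list (>= 2) of site-key character vectors.
#' @return data.frame with one row per non-empty membership pattern
#'   (`region`, e.g. `"A&B"`) and the exclusive count `n`; region counts sum
#'   to the size of the union.
#' @export
overlapSets <- function(sets) {
    stopifnot(length(sets) >= 2L, !is.null(names(sets)))
    sets <- lapply(sets, unique)
    all_keys <- unique(unlist(sets))
    membership <- vapply(sets, function(s) all_keys %in% s,
                         logical(length(all_keys)))
    if (length(all_keys) == 1L) membership <- matrix(membership, nrow = 1L)
    pattern <- apply(membership, 1L, function(row)
        paste(names(sets)[row], collapse = "&"))
    tab <- table(pattern)
    data.frame(region = names(tab), n = as.integer(tab),
               stringsAsFactors = FALSE)
}

.DIVERGENT_MODES <- c("stable_ctrl_dephos_mut", "dephos_ctrl_stable_mut")

#' Select sites whose dynamics diverge between control and mutant
#'
#' Mode `"stable_ctrl_dephos_mut"` selects sites stable or phosphorylated in
#' the control but dephosphorylated in the mutant (phosphatase-sustained
#' phosphorylation); `"dephos_ctrl_stable_mut"` selects sites
#' dephosphorylated in the control but stable in the mutant
#' (phosphatase-dependent dephosphorylation). The divergence score is the
#' mean over the last three time points (40/60/90 min) of the mutant minus
#' control anchored values, sign-adjusted so that larger means more
#' divergent in the mode's direction.
#'
#' @param control_calls,mutant_calls [classifyProfiles()] outputs sharing
#'   site keys.
#' @param x the anchored `PhosphoSet`.
#' @param mode one of the two selectors above.
#' @return data.frame: site identity, control_category, mutant_category,
#'   divergence_score.
#' @export
selectDivergent <- function(control_calls, mutant_calls, x,
                            mode = "stable_ctrl_dephos_mut") {
    if (!mode %in% .DIVERGENT_MODES)
        stop("unknown mode: ", mode, " (expected one of ",
             paste(.DIVERGENT_MODES, collapse = ", "), ")")
    ck <- paste(control_calls$protein_id, control_calls$position,
                control_calls$residue, sep = "_")
    mk <- paste(mutant_calls$protein_id, mutant_calls$position,
                mutant_calls$residue, sep = "_")
    shared <- intersect(ck, mk)
    ci <- match(shared, ck); mi <- match(shared, mk)
    cc <- control_calls$category[ci]
    mc <- mutant_calls$category[mi]
    sel <- if (mode == "stable_ctrl_dephos_mut") {
        cc %in% c("stable", "phosphorylated") & mc == "dephosphorylated"
    } else {
        cc == "dephosphorylated" & mc == "stable"
    }
    keys <- shared[sel]
    mc_m <- profileMatrix(x, "mut")
    mc_c <- profileMatrix(x, "ctrl")
    rows <- match(keys, siteKeys(x))
    late <- which(timeGrid() %in% c(40L, 60L, 90L))
    diff_late <- rowMeans(mc_m[rows, late, drop = FALSE] -
                          mc_c[rows, late, drop = FALSE])
    sign_adj <- if (mode == "stable_ctrl_dephos_mut") -1 else 1
    data.frame(protein_id = control_calls$protein_id[ci][sel],
               position = control_calls$position[ci][sel],
               residue = control_calls$residue[ci][sel],
               control_category = cc[sel], mutant_category = mc[sel],
               divergence_score = sign_adj * diff_late,
               stringsAsFactors = FALSE)
}

#' Rank divergent sites by how strongly they are affected
#'
#' @param divergent output of [selectDivergent()].
#' @param n how many top sites to return; if more than available, all are
#'   returned with a warning.
#' @return the top-`n` rows, descending by `divergence_score`, ties broken
#'   by site key.
#' @export
rankAffected <- function(divergent, n = 40L) {
    if (n > nrow(divergent)) {
        warning("requested ", n, " sites but only ", nrow(divergent),
                " available; returning all")
        n <- nrow(divergent)
    }
    key <- paste(divergent$protein_id, divergent$position,
                 divergent$residue, sep = "_")
    ord <- order(-divergent$divergence_score, key)
    out <- divergent[ord[seq_len(n)], , drop = FALSE]
    rownames(out) <- NULL
    out
}
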