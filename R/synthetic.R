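#' Configuration for the synthetic time-course generator
#'
#' Defines the study conditions emulated by [generateDataset()]: a 10-point
#' control/mutant TMT time course in which roughly equal fractions of sites
#' lose or gain phosphorylation (defaults 12% each, inside the 10--14% band
#' typical of mitotic-exit datasets), a small transient set, lognormal
#' reporter intensities with Gaussian log2 noise, a mutant phenotype of
#' delayed and attenuated changes, and whole-plex-group missingness for a
#' fraction of sites (default 0.4, which yields about 20% imputed values
#' after preprocessing since each affected site has 5 of its 10 time points
#' imputed per condition).
#'
#' @param n_sites number of phosphosites to simulate.
#' @param frac_dephos,frac_phos fractions of lasting decreases/increases.
#' @param frac_transient_down,frac_transient_up fractions of transient
#'   excursions.
#' @param effect_log2 mean absolute log2 change of affected sites.
#' @param noise_sd_log2 SD of Gaussian noise added on the log2 scale.
#' @param mutant_delay_min additive delay of the mutant response, minutes.
#' @param mutant_attenuation attenuation of the mutant effect in `[0,1]`:
#'   the mutant log2 effect is `(1 - mutant_attenuation)` times the control
#'   effect, so 0 reproduces the control and 1 abolishes the change.
#' @param frac_one_group_only fraction of sites quantified in only one plex
#'   group (the other group's 10 channels are withheld).
#' @param motif_coupling named list: per category, a named probability vector
#'   over motif labels (`cdk_full_S`, `cdk_full_T`, `plk`, `plk_T`,
#'   `aurora`, `ndr_hxrxxs`); remaining mass yields unconstrained windows.
#' @param base_log2_mean,base_log2_sd location/spread of baseline log2
#'   intensities (lognormal intensities).
#' @param seed integer seed; all randomness flows from it.
#' @return validated config list.
#' @export
simConfig <- function(n_sites = 1000L,
                      frac_dephos = 0.12, frac_phos = 0.12,
                      frac_transient_down = 0.03, frac_transient_up = 0.03,
                      effect_log2 = 1.5, noise_sd_log2 = 0.15,
                      mutant_delay_min = 15, mutant_attenuation = 0.5,
                      frac_one_group_only = 0.4,
                      motif_coupling = defaultMotifCoupling(),
                      base_log2_mean = 23, base_log2_sd = 2,
                      seed = 1L) {
    fr <- c(frac_dephos, frac_phos, frac_transient_down, frac_transient_up)
    if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
        stop("category fractions must lie in [0,1] and sum to at most 1")
    stopifnot(n_sites >= 1, noise_sd_log2 >= 0,
              mutant_attenuation >= 0, mutant_attenuation <= 1,
              frac_one_group_only >= 0, frac_one_group_only <= 1)
    list(n_sites = as.integer(n_sites),
         frac_dephos = frac_dephos, frac_phos = frac_phos,
         frac_transient_down = frac_transient_down,
         frac_transient_up = frac_transient_up,
         effect_log2 = effect_log2, noise_sd_log2 = noise_sd_log2,
         mutant_delay_min = mutant_delay_min,
         mutant_attenuation = mutant_attenuation,
         frac_one_group_only = frac_one_group_only,
         motif_coupling = motif_coupling,
         base_log2_mean = base_log2_mean, base_log2_sd = base_log2_sd,
         seed = as.integer(seed))
}

.MOTIF_LABELS <- c("cdk_full_S", "cdk_full_T", "plk", "plk_T",
                   "aurora", "ndr_hxrxxs")

#' Default motif coupling of the generator
#'
#' Sites losing phosphorylation are enriched for full Cdk consensus
#' (serine-biased) and Plk consensus windows; sites gaining phosphorylation
#' for Aurora and NDR consensus; transient increases for threonine-directed
#' Plk (NxT) and threonine Cdk windows; stable sites are unconstrained.
#'
#' @return named list of per-category motif probability vectors.
#' @export
defaultMotifCoupling <- function() {
    list(dephosphorylated = c(cdk_full_S = 0.30, cdk_full_T = 0.10, plk = 0.15),
         phosphorylated   = c(aurora = 0.20, ndr_hxrxxs = 0.10),
         transient_up     = c(plk_T = 0.30, cdk_full_T = 0.10),
         transient_down   = c(cdk_full_S = 0.20),
         stable           = c())
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate 13-mer phosphosite windows
#'
#' Random amino-acid windows with the phosphoacceptor at position 0 (string
#' index 7), optionally constrained to a kinase consensus motif. Uses the
#' current RNG state.
#'
#' @param n number of windows.
#' @param motif one of `"none"`, `"cdk_full_S"`, `"cdk_full_T"`, `"plk"`,
#'   `"plk_T"`, `"aurora"`, `"ndr_hxrxxs"` (recycled along `n`).
#' @return list with `window` (character 13-mers) and `residue`.
#' @export
simulateWindows <- function(n, motif = "none") {
    motif <- rep_len(motif, n)
    stopifnot(all(motif %in% c("none", .MOTIF_LABELS)))
    m <- matrix(sample(.AA20, 13L * n, replace = TRUE), nrow = n)
    residue <- ifelse(stats::runif(n) < 0.8, "S", "T")
    residue[motif == "cdk_full_S"] <- "S"
    residue[motif %in% c("cdk_full_T", "plk_T")] <- "T"
    residue[motif == "ndr_hxrxxs"] <- "S"
    # offsets relative to the acceptor: column 7 is position 0
    pickN <- function(idx, choices)
        sample(choices, length(idx), replace = TRUE)
    i <- which(motif %in% c("cdk_full_S", "cdk_full_T"))
    if (length(i)) {
        m[i, 8L] <- "P"
        m[i, 10L] <- pickN(i, c("K", "R"))
    }
    i <- which(motif == "plk")
    if (length(i)) m[i, 5L] <- pickN(i, c("D", "E", "N"))
    i <- which(motif == "plk_T")
    if (length(i)) m[i, 5L] <- "N"
    i <- which(motif == "aurora")
    if (length(i)) m[i, 5L] <- pickN(i, c("R", "K"))
    i <- which(motif == "ndr_hxrxxs")
    if (length(i)) { m[i, 2L] <- "H"; m[i, 4L] <- "R" }
    m[, 7L] <- residue
    list(window = apply(m, 1L, paste, collapse = ""), residue = residue)
}

# Trajectory families, one row per site. Lasting changes are logistic in
# time; the midpoint is placed halfway between the intended crossing time
# and the preceding grid time, with the slope scaled to that gap so the
# crossing point sits at ~88% of the amplitude and the preceding point at
# ~12%. This keeps the first threshold crossing at the intended grid time
# with a wide margin even after smoothing. Transient excursions are
# Gaussian bumps (width 10 min) centred at 20 or 25 min, negligible at t0,
# that exceed the threshold for >= 2 grid points and then return.
.trajectories <- function(category, A, m, times, width = 10) {
    n <- length(category)
    traj <- matrix(0, n, length(times))
    grid <- timeGrid()
    for (i in seq_len(n)) {
        cat_i <- category[i]
        if (cat_i == "stable") next
        if (cat_i %in% c("dephosphorylated", "phosphorylated")) {
            prev <- max(grid[grid < m[i]], 0)
            gap <- m[i] - prev
            mid <- m[i] - gap / 2
            slope <- 4 / gap
            f <- stats::plogis(slope * (times - mid))
            traj[i, ] <- if (cat_i == "dephosphorylated") -A[i] * f else A[i] * f
        } else {
            f <- exp(-((times - m[i]) / width)^2)
            traj[i, ] <- if (cat_i == "transient_down") -A[i] * f else A[i] * f
        }
    }
    traj
}

.CATEGORIES <- c("dephosphorylated", "phosphorylated",
                 "transient_down", "transient_up", "stable")

#' Generate a synthetic control/mutant phosphosite dataset with ground truth
#'
#' Emits a raw-scale [PhosphoSet] (lognormal reporter intensities, Gaussian
#' log2 noise) together with a per-site truth table. Control trajectories of
#' lasting changes follow a logistic in time whose midpoint sets the
#' threshold-crossing time; transient sites follow a Gaussian excursion wide
#' enough to cross the 1.5-fold threshold for at least two grid points and
#' then return. Mutant trajectories are delayed by `mutant_delay_min` and
#' attenuated by `mutant_attenuation`. For `frac_one_group_only` of the
#' sites, one whole plex group (both conditions) is withheld. True category
#' and timing are obtained by applying the run-based classification rule to
#' the noiseless anchored control trajectory.
#'
#' @param cfg a [simConfig()].
#' @param cfg_dyn a [dynamicsConfig()] used to derive true categories.
#' @return list with elements `sites` (a `PhosphoSet`, scale `"raw_log2"`)
#'   and `truth` (data.frame: protein_id, position, residue, true_category,
#'   true_timing, true_motif, base_log2, effect, plex_withheld).
#' @export
generateDataset <- function(cfg, cfg_dyn = dynamicsConfig()) {
    set.seed(cfg$seed)
    n <- cfg$n_sites
    times <- timeGrid()
    probs <- c(cfg$frac_dephos, cfg$frac_phos, cfg$frac_transient_down,
               cfg$frac_transient_up)
    probs <- c(probs, 1 - sum(probs))
    category <- sample(.CATEGORIES, n, replace = TRUE, prob = probs)

    A <- pmin(pmax(stats::rnorm(n, cfg$effect_log2, 0.2), 1.3), 3)
    m <- numeric(n)
    lasting <- category %in% c("dephosphorylated", "phosphorylated")
    transient <- category %in% c("transient_down", "transient_up")
    m[lasting] <- sample(c(10, 15, 20, 25, 30, 40, 60), sum(lasting),
                         replace = TRUE)
    m[transient] <- sample(c(20, 25), sum(transient), replace = TRUE)

    ctrl <- .trajectories(category, A, m, times)
    A_mut <- (1 - cfg$mutant_attenuation) * A
    mut <- .trajectories(category, A_mut, m + cfg$mutant_delay_min, times)

    base <- stats::rnorm(n, cfg$base_log2_mean, cfg$base_log2_sd)
    noise_c <- matrix(stats::rnorm(n * 10L, 0, cfg$noise_sd_log2), n)
    noise_m <- matrix(stats::rnorm(n * 10L, 0, cfg$noise_sd_log2), n)
    vc <- base + ctrl + noise_c
    vm <- base + mut + noise_m

    # motif-coupled windows
    motif <- rep("none", n)
    for (cat in names(cfg$motif_coupling)) {
        p <- cfg$motif_coupling[[cat]]
        idx <- which(category == cat)
        if (!length(idx) || !length(p)) next
        draw <- sample(c(names(p), "none"), length(idx), replace = TRUE,
                       prob = c(p, 1 - sum(p)))
        motif[idx] <- draw
    }
    win <- simulateWindows(n, motif)

    design <- plexDesign()
    cd <- designColData(design)
    vals <- matrix(NA_real_, n, nrow(cd), dimnames = list(NULL, rownames(cd)))
    for (j in seq_len(nrow(cd))) {
        ti <- match(cd$time[j], times)
        vals[, j] <- if (cd$condition[j] == "ctrl") vc[, ti] else vm[, ti]
    }
    withheld <- rep(NA_character_, n)
    gap <- stats::runif(n) < cfg$frac_one_group_only
    withheld[gap] <- sample(c("A", "B"), sum(gap), replace = TRUE)
    for (g in c("A", "B")) {
        rows <- which(withheld == g)
        if (length(rows))
            vals[rows, cd$plex_group == g] <- NA_real_
    }

    protein_id <- sprintf("SYNP%04d", (seq_len(n) - 1L) %/% 5L + 1L)
    position <- 60L + ((seq_len(n) - 1L) %% 5L) * 45L

    rowData <- S4Vectors::DataFrame(
        protein_id = protein_id, position = position,
        residue = win$residue,
        loc_prob = round(stats::runif(n, 0.80, 1.00), 3),
        multiplicity = 1L, window = win$window)
    ps <- PhosphoSet(vals, rowData, scale_tag = "raw_log2", design = design)

    # truth: the classification rule applied to the noiseless anchored control
    anchored <- ctrl - ctrl[, 1L]
    true_category <- character(n)
    true_timing <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        cl <- classifySite(anchored[i, ], cfg_dyn)
        true_category[i] <- cl$category
        true_timing[i] <- if (is.na(cl$timing_min)) NA_real_ else cl$timing_min
    }
    truth <- data.frame(
        protein_id = protein_id, position = position, residue = win$residue,
        true_category = true_category, true_timing = true_timing,
        true_motif = motif, base_log2 = base, effect = A,
        plex_withheld = withheld, stringsAsFactors = FALSE)
    list(sites = ps, truth = truth)
}

#' Append sites that realize a given expected profile
#'
#' Generates `n` sites whose noiseless anchored profiles equal a template
#' (per condition where the template defines values; the other condition is
#' flat), with the configured log2 noise and baseline spread on top. Used to
#' plant known positives for the expected-profile search.
#'
#' @param cfg a [simConfig()] (supplies noise, baseline and seed; the seed is
#'   offset so template sites are independent of the background draw).
#' @param template list with `name`, and `ctrl` and/or `mut` numeric
#'   length-10 anchored log2 profiles.
#' @param n number of sites to generate (> 0).
#' @return list with `sites` (a `PhosphoSet`) and `truth` (data.frame with
#'   `true_category = "template"`).
#' @export
makeTemplateSites <- function(cfg, template, n) {
    if (n <= 0) stop("n must be positive")
    stopifnot(!is.null(template$ctrl) || !is.null(template$mut))
    for (cc in c("ctrl", "mut"))
        if (!is.null(template[[cc]]) && length(template[[cc]]) != 10L)
            stop("template ", cc, " profile must have length 10")
    set.seed(cfg$seed + 1000003L)
    times <- timeGrid()
    tc <- if (is.null(template$ctrl)) rep(0, 10) else as.numeric(template$ctrl)
    tm <- if (is.null(template$mut)) rep(0, 10) else as.numeric(template$mut)
    base <- stats::rnorm(n, cfg$base_log2_mean, cfg$base_log2_sd)
    vc <- base + rep(tc, each = n) + stats::rnorm(n * 10L, 0, cfg$noise_sd_log2)
    vm <- base + rep(tm, each = n) + stats::rnorm(n * 10L, 0, cfg$noise_sd_log2)
    dim(vc) <- c(n, 10L); dim(vm) <- c(n, 10L)
    design <- plexDesign()
    cd <- designColData(design)
    vals <- matrix(NA_real_, n, nrow(cd), dimnames = list(NULL, rownames(cd)))
    for (j in seq_len(nrow(cd))) {
        ti <- match(cd$time[j], times)
        vals[, j] <- if (cd$condition[j] == "ctrl") vc[, ti] else vm[, ti]
    }
    win <- simulateWindows(n, "none")
    protein_id <- sprintf("TMPL%04d", seq_len(n))
    rowData <- S4Vectors::DataFrame(
        protein_id = protein_id, position = 100L,
        residue = win$residue, loc_prob = 0.99, multiplicity = 1L,
        window = win$window)
    ps <- PhosphoSet(vals, rowData, scale_tag = "raw_log2", design = design)
    truth <- data.frame(
        protein_id = protein_id, position = 100L, residue = win$residue,
        true_category = "template", true_timing = NA_real_,
        true_motif = "none", base_log2 = base, effect = NA_real_,
        plex_withheld = NA_character_, stringsAsFactors = FALSE)
    list(sites = ps, truth = truth)
}

#' Row-bind two PhosphoSets sharing one design and scale
#'
#' @param x,y `PhosphoSet` objects with identical colData and scale tags.
#' @return combined `PhosphoSet`.
#' @export
combineSites <- function(x, y) {
    stopifnot(identical(scaleTag(x), scaleTag(y)))
    methods::new("PhosphoSet", rbind(methods::as(x, "SummarizedExperiment"),
                                     methods::as(y, "SummarizedExperiment")))
}
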