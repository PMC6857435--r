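test_that("classification matches the rule on the worked examples", {
    cfg <- dynamicsConfig()
    cases <- list(
        list(p = rep(0, 10), cat = "stable", t = NA_real_),
        list(p = c(0, 0, -0.7, -0.8, -0.9, -1, -1, -1, -1, -1),
             cat = "dephosphorylated", t = 10),
        list(p = c(0, 0.8, 0.9, 0.1, 0, 0, 0, 0, 0, 0),
             cat = "transient_up", t = 5),
        list(p = c(0, -1, 0, 0, 0, 0, 0, 0, 0, 0),
             cat = "stable", t = NA_real_),
        # crossing only at the last two points stays lasting (return run
        # of length < 2 cannot rescue transience)
        list(p = c(0, 0, 0, 0, 0, 0, 0, 0, -1, -1),
             cat = "dephosphorylated", t = 60),
        # down-run then later up-run: earlier run wins, other is flagged
        list(p = c(0, -1, -1, 0, 0, 1, 1, 1, 1, 1),
             cat = "transient_down", t = 5))
    for (cs in cases) {
        got <- classifySite(cs$p, cfg)
        expect_equal(got$category, cs$cat)
        expect_equal(got$timing_min, cs$t)
    }
    both <- classifySite(c(0, -1, -1, 0, 0, 1, 1, 1, 1, 1), cfg)
    expect_equal(both$secondary_flag, "up")
    expect_error(classifySite(c(0, NA, rep(0, 8))), "missing")
})

test_that("classifier and timing agree with the brute-force run scanner", {
    cfg <- dynamicsConfig()
    set.seed(99)
    for (i in 1:500) {
        p <- c(0, round(rnorm(9, sd = 0.8), 2))
        got <- classifySite(p, cfg)
        want <- oracle_classify(p)
        expect_identical(got$category, want$category)
        expect_identical(got$timing_min, want$timing)
    }
})

test_that("category partition is exhaustive and scale-equivariant", {
    set.seed(7)
    cats <- c("dephosphorylated", "phosphorylated", "transient_down",
              "transient_up", "stable")
    for (i in 1:200) {
        p <- c(0, rnorm(9))
        got <- classifySite(p)
        expect_true(got$category %in% cats)
        expect_equal(is.na(got$timing_min), got$category == "stable")
        # doubling the profile and the fold threshold (theta doubles)
        # leaves the call unchanged
        got2 <- classifySite(2 * p, dynamicsConfig(fold_threshold = 1.5^2))
        expect_identical(got2$category, got$category)
        expect_identical(got2$timing_min, got$timing_min)
    }
})

test_that("timing groups are keyed by grid time with mean profiles", {
    gen <- generateDataset(simConfig(n_sites = 600, seed = 5))
    pre <- preprocessPhospho(gen$sites)
    calls <- classifyProfiles(pre$profiles, condition = "ctrl")
    tg <- timingGroups(calls, pre$profiles)
    expect_gt(length(tg), 3L)
    tms <- as.numeric(names(tg))
    expect_equal(tms, sort(tms))
    expect_true(all(tms %in% setdiff(timeGrid(), 0)))
    for (g in tg) {
        expect_equal(g$n, length(g$site_keys))
        expect_length(g$mean_profile, 10L)
    }
    expect_equal(sum(vapply(tg, `[[`, 0, "n")),
                 sum(calls$category == "dephosphorylated"))
    expect_identical(timingGroups(calls[0, ], pre$profiles), list())
})

test_that("class mean profiles cross the threshold in class order", {
    theta <- log2(1.5)
    ok <- 0L
    for (s in 1:10) {
        gen <- generateDataset(simConfig(n_sites = 800, seed = 100 + s))
        pre <- preprocessPhospho(gen$sites)
        calls <- classifyProfiles(pre$profiles, condition = "ctrl")
        tg <- timingGroups(calls, pre$profiles)
        tg <- tg[vapply(tg, `[[`, 0, "n") >= 5]
        cross <- vapply(tg, function(g) {
            i <- which(g$mean_profile <= -theta)
            if (length(i)) timeGrid()[min(i)] else Inf
        }, 0)
        if (!is.unsorted(cross)) ok <- ok + 1L
    }
    expect_gte(ok, 9L)
})

test_that("overlap regions match brute-force membership counting", {
    expect_equal(overlapSets(list(A = c("x", "y"), B = c("y", "z")))$n[
        overlapSets(list(A = c("x", "y"), B = c("y", "z")))$region == "A&B"], 1L)
    sets <- list(A = letters[1:10], B = letters[1:10], C = letters[1:10])
    ov <- overlapSets(sets)
    expect_equal(ov$n[ov$region == "A&B&C"], 10L)
    expect_equal(nrow(ov), 1L)
    set.seed(2)
    sets <- list(A = sample(letters, 12), B = sample(letters, 15),
                 C = sample(letters, 8))
    ov <- overlapSets(sets)
    # exclusive regions sum to the union
    expect_equal(sum(ov$n), length(unique(unlist(sets))))
    # brute force every key
    for (k in unique(unlist(sets))) {
        pattern <- paste(names(sets)[vapply(sets, function(s) k %in% s, TRUE)],
                         collapse = "&")
        expect_true(pattern %in% ov$region)
    }
})

test_that("divergent-site selection recovers planted sites", {
    # attenuation 1 abolishes every mutant response: control-dephosphorylated
    # sites must surface as dephos_ctrl_stable_mut
    gen <- generateDataset(simConfig(n_sites = 1500, seed = 21,
                                     mutant_attenuation = 1,
                                     noise_sd_log2 = 0.05))
    pre <- preprocessPhospho(gen$sites)
    cc <- classifyProfiles(pre$profiles, condition = "ctrl")
    cm <- classifyProfiles(pre$profiles, condition = "mut")
    div <- selectDivergent(cc, cm, pre$profiles, "dephos_ctrl_stable_mut")
    tr <- gen$truth
    key <- paste(tr$protein_id, tr$position, tr$residue, sep = "_")
    planted <- key[tr$true_category == "dephosphorylated"]
    found <- paste(div$protein_id, div$position, div$residue, sep = "_")
    expect_gte(mean(planted %in% found), 0.95)
    expect_true(all(div$control_category == "dephosphorylated"))
    expect_true(all(div$mutant_category == "stable"))
    # scores are positive for genuinely persistent mutant phosphorylation
    expect_gt(median(div$divergence_score), 0)
    expect_error(selectDivergent(cc, cm, pre$profiles, "sideways"), "mode")
})

test_that("ranking most-affected sites is a deterministic sort", {
    div <- data.frame(protein_id = c("B", "A", "C"), position = c(1L, 2L, 3L),
                      residue = "S",
                      control_category = "dephosphorylated",
                      mutant_category = "stable",
                      divergence_score = c(0.3, 1.2, 0.3))
    top <- rankAffected(div, 3L)
    expect_equal(top$protein_id, c("A", "B", "C"))  # tie broken by key
    expect_equal(rankAffected(div, 1L)$protein_id, "A")
    expect_warning(all4 <- rankAffected(div, 10L), "available")
    expect_equal(nrow(all4), 3L)
    set.seed(5)
    div2 <- div[sample(3), ]
    expect_equal(rankAffected(div2, 3L), top)
})
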