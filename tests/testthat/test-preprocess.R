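test_that("filtering enforces multiplicity, strict loc_prob, plex completeness", {
    ctrl <- matrix(rep(12, 40), 4)
    vals <- vals_from_profiles(ctrl)
    vals[3, paste0("ctrl_t", c(0, 10))] <- NA   # incomplete group A...
    vals[3, paste0("mut_t", c(5, 15))] <- NA    # ...and incomplete group B
    ps <- make_ps(vals, scale_tag = "raw_log2",
                  loc_prob = c(0.93, 0.99, 0.99, 0.75),
                  multiplicity = c(1L, 2L, 1L, 1L))
    out <- filterSites(ps)
    expect_equal(siteKeys(out$retained), siteKeys(ps)[1])
    expect_equal(out$rejects$reason[match(c("P002", "P003", "P004"),
                                          out$rejects$protein_id)],
                 c("multiplicity", "incomplete_plex", "loc_prob"))
})

test_that("a site complete in one plex group only is retained", {
    ctrl <- matrix(rep(12, 10), 1)
    vals <- vals_from_profiles(ctrl)
    gB <- designColData()$plex_group == "B"
    vals[1, gB] <- NA
    ps <- make_ps(vals, scale_tag = "raw_log2")
    expect_equal(nrow(filterSites(ps)$retained), 1L)
})

test_that("median normalization matches hand computation and zeroes row medians", {
    # identical values everywhere -> all zeros
    ps <- make_ps(vals_from_profiles(matrix(rep(7, 30), 3)),
                  scale_tag = "raw_log2")
    z <- SummarizedExperiment::assays(medianNormalize(ps))[["log2intensity"]]
    expect_true(all(abs(z) < 1e-12))

    # hand-chosen small case: 3 sites, verify the two-step subtraction
    set.seed(42)
    vals <- vals_from_profiles(matrix(rnorm(30, 12), 3),
                               matrix(rnorm(30, 13), 3))
    vals[2, "ctrl_t5"] <- NA
    ps <- make_ps(vals, scale_tag = "raw_log2")
    out <- SummarizedExperiment::assays(medianNormalize(ps))[["log2intensity"]]
    step1 <- vals
    for (j in seq_len(ncol(vals)))
        step1[, j] <- vals[, j] - median(vals[, j], na.rm = TRUE)
    expected <- step1
    for (i in 1:3)
        expected[i, ] <- step1[i, ] - median(step1[i, ], na.rm = TRUE)
    expect_equal(out, expected, tolerance = 1e-12, ignore_attr = TRUE)
    # every row median over present values is 0 afterwards
    expect_true(all(abs(apply(out, 1, median, na.rm = TRUE)) < 1e-9))

    # wrong stage or an all-missing channel raise errors
    expect_error(medianNormalize(make_ps(vals)), "raw_log2")
    vals2 <- vals; vals2[, "mut_t90"] <- NA
    expect_error(medianNormalize(make_ps(vals2, scale_tag = "raw_log2")),
                 "mut_t90")
})

test_that("imputation applies the neighbour-mean and endpoint rules", {
    # full alternating gap: measured (0,0.4,0.8,1.2,1.6) at group A times
    ctrl <- matrix(NA_real_, 1, 10)
    ctrl[match(c(0, 10, 20, 30, 60), timeGrid())] <- c(0, 0.4, 0.8, 1.2, 1.6)
    ps <- make_ps(vals_from_profiles(ctrl, matrix(rep(1, 10), 1)))
    out <- imputeMissing(ps)
    prof <- profileMatrix(out, "ctrl")[1, ]
    expect_equal(prof[paste0("t", c(5, 15, 25, 40, 90))],
                 c(t5 = 0.2, t15 = 0.6, t25 = 1.0, t40 = 1.4, t90 = 1.6))
    st <- statusMatrix(out)[1, ]
    expect_setequal(names(st)[st == "imputed"],
                    paste0("ctrl_t", c(5, 15, 25, 40, 90)))
    expect_equal(imputedFraction(out), 5 / 20)

    # group A absent: the 0-minute endpoint copies the 5-minute value
    ctrlB <- matrix(NA_real_, 1, 10)
    ctrlB[match(c(5, 15, 25, 40, 90), timeGrid())] <- c(1.2, 1, 1, 1, 1)
    out2 <- imputeMissing(make_ps(vals_from_profiles(ctrlB,
                                                     matrix(rep(1, 10), 1))))
    expect_equal(unname(profileMatrix(out2, "ctrl")[1, "t0"]), 1.2)

    # isolated interior gap: plain mean of the two neighbours
    ctrlC <- matrix(seq(0, 2.7, 0.3), 1)
    ctrlC[4] <- NA  # t15; neighbours 1.0-ish
    ctrlC[3] <- 1; ctrlC[5] <- 3
    out3 <- imputeMissing(make_ps(vals_from_profiles(ctrlC,
                                                     matrix(rep(1, 10), 1))))
    expect_equal(unname(profileMatrix(out3, "ctrl")[1, "t15"]), 2)

    # irregular gap (both neighbours missing) warns and fills from the
    # nearest measured time point
    ctrlD <- matrix(1, 1, 10); ctrlD[1, 3:5] <- NA; ctrlD[1, 6] <- 5
    expect_warning(
        out4 <- imputeMissing(make_ps(vals_from_profiles(
            ctrlD, matrix(rep(1, 10), 1)))),
        "irregular")
    expect_equal(unname(profileMatrix(out4, "ctrl")[1, 4]), 1)  # nearest is t5
})

test_that("smoothing modes behave as specified", {
    # constant profile is a fixed point
    cst <- matrix(3, 1, 10)
    ps <- make_ps(vals_from_profiles(cst))
    sm <- smoothProfiles(ps)
    expect_equal(unname(profileMatrix(sm, "ctrl")[1, ]), rep(3, 10))

    # alternating profile swaps parity under the simultaneous update
    alt <- matrix(rep(c(0, 1), 5), 1)
    sm2 <- smoothProfiles(make_ps(vals_from_profiles(alt)))
    expect_equal(unname(profileMatrix(sm2, "ctrl")[1, ]),
                 rep(c(1, 0), 5))
    # changed cells are flagged smoothed
    expect_true(all(statusMatrix(sm2)[1, ] == "smoothed"))

    # index-linear profiles are fixed points of the centered3 mode interior
    lin <- matrix(as.numeric(1:10), 1)
    sm3 <- smoothProfiles(make_ps(vals_from_profiles(lin)), mode = "centered3")
    expect_equal(unname(profileMatrix(sm3, "ctrl")[1, 2:9]), as.numeric(2:9))

    expect_error(smoothProfiles(make_ps(vals_from_profiles(
        matrix(c(NA, 1:9), 1)))), "imputed")
})

test_that("anchoring zeroes t0 and is shift-invariant", {
    set.seed(1)
    prof <- matrix(rnorm(20), 2)
    ps <- anchorT0(make_ps(vals_from_profiles(prof)))
    m <- profileMatrix(ps, "ctrl")
    expect_equal(unname(m[, "t0"]), c(0, 0))
    ps2 <- anchorT0(make_ps(vals_from_profiles(prof + 5)))
    expect_equal(profileMatrix(ps2, "ctrl"), m)
    expect_equal(scaleTag(ps), "t0_normalized")
    # stage order is enforced
    expect_error(anchorT0(ps2), "median_normalized")
})

test_that("status flags reconcile with injected missingness", {
    cfg <- simConfig(n_sites = 400, seed = 11)
    gen <- generateDataset(cfg)
    flt <- filterSites(gen$sites)
    y <- imputeMissing(medianNormalize(flt$retained))
    st <- statusMatrix(y)
    expect_true(all(st %in% c("measured", "imputed")))
    tr <- gen$truth
    key <- paste(tr$protein_id, tr$position, tr$residue, sep = "_")
    withheld <- tr$plex_withheld[match(siteKeys(y), key)]
    # every withheld site has exactly 10 imputed cells, others none
    n_imp <- rowSums(st == "imputed")
    expect_true(all(n_imp[!is.na(withheld)] == 10L))
    expect_true(all(n_imp[is.na(withheld)] == 0L))
    expect_equal(imputedFraction(y), mean(!is.na(withheld)) / 2,
                 tolerance = 1e-12)
})
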