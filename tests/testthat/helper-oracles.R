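# Independent brute-force oracles, written as literal rule transcriptions
# with explicit loops so they share no code path with the package.

# run-scanner oracle for the dynamics rule
oracle_classify <- function(v, fold = 1.5, min_run = 2L, return_run = 2L) {
    th <- log2(fold)
    n <- length(v)
    qual_start <- function(dir) {
        for (s in seq_len(n - min_run + 1L)) {
            ok <- TRUE
            for (j in s:(s + min_run - 1L))
                if (!(dir * v[j] >= th)) { ok <- FALSE; break }
            if (ok) return(s)
        }
        NA_integer_
    }
    sdn <- qual_start(-1)
    sup <- qual_start(1)
    if (is.na(sdn) && is.na(sup))
        return(list(category = "stable", timing = NA_real_))
    if (!is.na(sdn) && (is.na(sup) || sdn < sup)) {
        s <- sdn; dir <- -1
    } else {
        s <- sup; dir <- 1
    }
    e <- s
    while (e < n && dir * v[e + 1L] >= th) e <- e + 1L
    trans <- FALSE
    if (e + return_run <= n) {
        for (r in (e + 1L):(n - return_run + 1L)) {
            inside_all <- TRUE
            for (j in r:(r + return_run - 1L))
                if (!(abs(v[j]) < th)) { inside_all <- FALSE; break }
            if (inside_all) { trans <- TRUE; break }
        }
    }
    category <- if (dir < 0) {
        if (trans) "transient_down" else "dephosphorylated"
    } else {
        if (trans) "transient_up" else "phosphorylated"
    }
    list(category = category, timing = as.numeric(timeGrid()[s]))
}

# position-by-position motif checker
oracle_motif <- function(window, residue) {
    at <- function(off) substr(window, off + 7L, off + 7L)
    st <- residue == "S" || residue == "T"
    list(cdk_full = st && at(1) == "P" && (at(3) == "K" || at(3) == "R"),
         cdk_minimal = st && at(1) == "P",
         plk = st && at(-2) %in% c("D", "E", "N"),
         aurora = st && at(-2) %in% c("R", "K"),
         ndr_hxrxxs = st && at(-5) == "H" && at(-3) == "R",
         ndr_rxxs = st && at(-3) == "R")
}

# naive O(n*m) sliding-window docking matcher
oracle_dock <- function(sequence, motif, variant = "printed") {
    classes <- if (motif == "LxxIxE") {
        if (variant == "printed")
            list(strsplit("LCVMIF", "")[[1]], c("S", "T"), "P",
                 c("I", "L", "V", "M"), NULL, "E")
        else list("L", NULL, NULL, "I", NULL, "E")
    } else list("P", NULL, "L")
    len <- length(classes)
    chars <- strsplit(sequence, "")[[1]]
    hits <- integer(0)
    if (length(chars) >= len) {
        for (s in seq_len(length(chars) - len + 1L)) {
            ok <- TRUE
            for (j in seq_len(len)) {
                cl <- classes[[j]]
                if (!is.null(cl) && !(chars[s + j - 1L] %in% cl)) {
                    ok <- FALSE; break
                }
            }
            if (ok) hits <- c(hits, s)
        }
    }
    hits
}

# complete-linkage agglomeration by exhaustive pair search
oracle_complete_linkage_heights <- function(m) {
    clusters <- as.list(seq_len(nrow(m)))
    d <- as.matrix(stats::dist(m))
    heights <- numeric(0)
    while (length(clusters) > 1L) {
        best <- c(NA, NA); best_d <- Inf
        for (i in seq_along(clusters)) {
            for (j in seq_along(clusters)) {
                if (j <= i) next
                dd <- max(d[clusters[[i]], clusters[[j]]])
                if (dd < best_d) { best_d <- dd; best <- c(i, j) }
            }
        }
        heights <- c(heights, best_d)
        clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
        clusters[[best[2]]] <- NULL
    }
    heights
}

# a minimal hand-built PhosphoSet: one value matrix on the 20-channel
# design, default windows/quality fields
make_ps <- function(vals, residue = NULL, window = NULL,
                    scale_tag = "median_normalized", loc_prob = 0.99,
                    multiplicity = 1L) {
    n <- nrow(vals)
    if (is.null(residue)) residue <- rep("S", n)
    if (is.null(window))
        window <- paste0("AAAAAA", residue, "AAAAAA")
    rd <- S4Vectors::DataFrame(
        protein_id = sprintf("P%03d", seq_len(n)), position = 10L,
        residue = residue, loc_prob = rep_len(loc_prob, n),
        multiplicity = rep_len(multiplicity, n), window = window)
    PhosphoSet(vals, rd, scale_tag = scale_tag)
}

# value matrix from per-condition site x time matrices (grid order)
vals_from_profiles <- function(ctrl, mut = ctrl) {
    cd <- designColData()
    vals <- matrix(NA_real_, nrow(ctrl), nrow(cd),
                   dimnames = list(NULL, rownames(cd)))
    for (j in seq_len(nrow(cd))) {
        ti <- match(cd$time[j], timeGrid())
        vals[, j] <- if (cd$condition[j] == "ctrl") ctrl[, ti] else mut[, ti]
    }
    vals
}

recovery_stats <- function(gen, profiles, calls) {
    tr <- gen$truth
    key <- paste(tr$protein_id, tr$position, tr$residue, sep = "_")
    m <- match(siteKeys(profiles), key)
    tcat <- tr$true_category[m]
    tt <- tr$true_timing[m]
    lasting <- tcat %in% c("dephosphorylated", "phosphorylated")
    transient <- tcat %in% c("transient_down", "transient_up")
    hit <- calls$category == tcat
    ok <- lasting & hit
    within1 <- mapply(function(call_t, true_t) {
        i <- match(true_t, timeGrid())
        call_t >= timeGrid()[max(i - 1L, 1L)] &&
            call_t <= timeGrid()[min(i + 1L, 10L)]
    }, calls$timing_min[ok], tt[ok])
    list(lasting = mean(hit[lasting]),
         transient = if (any(transient)) mean(hit[transient]) else NA,
         timing_within1 = sum(within1) / sum(lasting))
}
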