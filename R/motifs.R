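#' Annotate phosphosite windows with kinase consensus motifs
#'
#' Positions are offsets from the acceptor (string index 7 = position 0) and
#' a `'_'` pad never matches. Flags: full Cdk consensus `(S/T)Px(K/R)`
#' (P at +1 and K/R at +3), minimal Cdk consensus (P at +1), Plk consensus
#' `(D/E/N)x(S/T)` (D/E/N at -2), Aurora consensus `(R/K)x(S/T)` (R/K at
#' -2), and the NDR consensus pair `HxRxxS` (H at -5 and R at -3) and
#' `RxxS` (R at -3). A single `primary_class` is assigned by precedence
#' cdk_full > plk > aurora > ndr > cdk_minimal > other, with full Cdk sites
#' split by acceptor into `cdk_full_S` / `cdk_full_T`. Tyrosine acceptors
#' are classed `other`.
#'
#' @param window character vector of 13-mers.
#' @param residue acceptor residue(s), recycled along `window`.
#' @return data.frame of logical flags plus `primary_class`.
#' @export
annotateWindow <- function(window, residue) {
    stopifnot(all(nchar(window) == 13L))
    residue <- rep_len(residue, length(window))
    at <- function(off) substr(window, off + 7L, off + 7L)
    st <- residue %in% c("S", "T")
    cdk_minimal <- st & at(1L) == "P"
    cdk_full <- cdk_minimal & at(3L) %in% c("K", "R")
    plk <- st & at(-2L) %in% c("D", "E", "N")
    aurora <- st & at(-2L) %in% c("R", "K")
    ndr_hxrxxs <- st & at(-5L) == "H" & at(-3L) == "R"
    ndr_rxxs <- st & at(-3L) == "R"
    # precedence climbs: later assignments override weaker classes
    primary <- rep("other", length(window))
    primary[cdk_minimal] <- "cdk_minimal"
    primary[ndr_hxrxxs | ndr_rxxs] <- "ndr"
    primary[aurora] <- "aurora"
    primary[plk] <- "plk"
    primary[cdk_full & residue == "S"] <- "cdk_full_S"
    primary[cdk_full & residue == "T"] <- "cdk_full_T"
    data.frame(cdk_full = cdk_full, cdk_minimal = cdk_minimal, plk = plk,
               aurora = aurora, ndr_hxrxxs = ndr_hxrxxs,
               ndr_rxxs = ndr_rxxs, primary_class = primary,
               stringsAsFactors = FALSE)
}

#' Motif calls for every site of a PhosphoSet
#'
#' @param x a `PhosphoSet`.
#' @return data.frame: site identity columns plus [annotateWindow()] output.
#' @export
annotateMotifs <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    cbind(data.frame(protein_id = rd$protein_id, position = rd$position,
                     residue = rd$residue, stringsAsFactors = FALSE),
          annotateWindow(rd$window, rd$residue))
}

.DOCKING_PATTERNS <- list(
    LxxIxE = list(printed = "[LCVMIF][ST]P[ILVM].E",
                  canonical = "L..I.E", len = 6L),
    PxL = list(printed = "P.L", canonical = "P.L", len = 3L))

#' Scan a protein sequence for phosphatase docking motifs
#'
#' `"LxxIxE"` (PP2A-B56/Rts1 docking) matches, by default, the published
#' 6-position character-class pattern `[LCVMIF][ST]P[ILVM]xE`; a
#' `"canonical"` variant matching the literal motif name (`L..I.E`) is
#' available. `"PxL"` (Cdc14 docking) matches `P.L`. All overlapping
#' matches are reported with 1-based start positions.
#'
#' @param sequence uppercase amino-acid string.
#' @param motif `"LxxIxE"` or `"PxL"`.
#' @param variant `"printed"` (default) or `"canonical"`.
#' @return data.frame with `motif`, `start`, `matched`.
#' @export
scanDocking <- function(sequence, motif = c("LxxIxE", "PxL"),
                        variant = c("printed", "canonical")) {
    motif <- match.arg(motif)
    variant <- match.arg(variant)
    if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", sequence))
        stop("sequence contains non-amino-acid characters")
    spec <- .DOCKING_PATTERNS[[motif]]
    hits <- gregexpr(paste0("(?=", spec[[variant]], ")"), sequence,
                     perl = TRUE)[[1L]]
    if (hits[1L] == -1L)
        return(data.frame(motif = character(0), start = integer(0),
                          matched = character(0), stringsAsFactors = FALSE))
    starts <- as.integer(hits)
    data.frame(motif = motif, start = starts,
               matched = substring(sequence, starts, starts + spec$len - 1L),
               stringsAsFactors = FALSE)
}

#' Scan a whole proteome for a docking motif
#'
#' @param proteome named character vector as from [readProteomeFasta()].
#' @param motif,variant as in [scanDocking()].
#' @return data.frame with `protein_id`, `motif`, `start`, `matched`.
#' @export
scanProteome <- function(proteome, motif = "LxxIxE", variant = "printed") {
    out <- lapply(names(proteome), function(id) {
        hits <- scanDocking(proteome[[id]], motif, variant)
        if (nrow(hits)) cbind(protein_id = id, hits) else NULL
    })
    out <- do.call(rbind, out)
    if (is.null(out))
        out <- data.frame(protein_id = character(0), motif = character(0),
                          start = integer(0), matched = character(0),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Phosphoacceptor preference: serine versus threonine abundance
#'
#' Summarizes each site by the median of its 10 time-point values in one
#' condition, groups sites by acceptor (tyrosines excluded), and compares
#' the serine and threonine per-site median distributions with an unpaired
#' two-sample t test (pooled variance by default, Welch optional).
#'
#' @param x a median-normalized or anchored `PhosphoSet`.
#' @param condition `"ctrl"` or `"mut"`.
#' @param var.equal passed to [stats::t.test()]; default `TRUE` (classic
#'   unpaired t test).
#' @return list: `site_medians` (data.frame residue/median), `group_medians`
#'   (named S/T), `p_value` (`NA` with a warning if a group has fewer than 2
#'   sites), `n` (group sizes).
#' @export
acceptorPreference <- function(x, condition = "ctrl", var.equal = TRUE) {
    m <- profileMatrix(x, condition)
    rd <- SummarizedExperiment::rowData(x)
    keep <- rd$residue %in% c("S", "T")
    med <- apply(m[keep, , drop = FALSE], 1L, stats::median)
    res <- rd$residue[keep]
    s <- med[res == "S"]; t <- med[res == "T"]
    p <- NA_real_
    if (length(s) < 2L || length(t) < 2L) {
        warning("fewer than 2 sites in an acceptor group; test skipped")
    } else {
        p <- stats::t.test(s, t, var.equal = var.equal)$p.value
    }
    list(site_medians = data.frame(residue = res, median = med,
                                   stringsAsFactors = FALSE),
         group_medians = c(S = stats::median(s), T = stats::median(t)),
         p_value = p,
         n = c(S = length(s), T = length(t)))
}
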