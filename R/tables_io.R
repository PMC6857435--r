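#' The 10-point sampling grid of the time course
#'
#' Minutes after metaphase release at which samples were taken. Two
#' interleaved 5-point subsets make up the two TMT10plex groups (see
#' [plexDesign()]).
#'
#' @return integer vector of length 10, strictly increasing.
#' @export
timeGrid <- function() c(0L, 5L, 10L, 15L, 20L, 25L, 30L, 40L, 60L, 90L)

#' The two-plex labelling design
#'
#' Each TMT10plex mixture ("plex group") carries five alternating time points
#' of the control together with the same five of the mutant. Group A holds
#' times 0/10/20/30/60 min, group B holds 5/15/25/40/90 min; the groups
#' partition the grid.
#'
#' @return list with `group_A`, `group_B` (integer time subsets) and
#'   `conditions` (`c("ctrl","mut")`).
#' @export
plexDesign <- function() {
    list(group_A = c(0L, 10L, 20L, 30L, 60L),
         group_B = c(5L, 15L, 25L, 40L, 90L),
         conditions = .CONDITIONS)
}

#' Channel-level column metadata for a plex design
#'
#' @param design a [plexDesign()] list.
#' @return DataFrame with one row per channel (condition x time), rownames
#'   `<condition>_t<minutes>`, ordered ctrl then mut, each by time.
#' @export
designColData <- function(design = plexDesign()) {
    times <- sort(c(design$group_A, design$group_B))
    grp <- ifelse(times %in% design$group_A, "A", "B")
    cd <- S4Vectors::DataFrame(
        condition = rep(design$conditions, each = length(times)),
        time = rep(times, times = 2L),
        plex_group = rep(grp, times = 2L))
    rownames(cd) <- paste0(cd$condition, "_t", cd$time)
    cd
}

#' Parameters of the dynamics classification
#'
#' @param fold_threshold fold change that counts as a change; the log2
#'   threshold used everywhere is `log2(fold_threshold)`. Default 1.5.
#' @param min_run consecutive time points a change must persist to qualify.
#'   Default 2.
#' @param return_run consecutive inside-band points after an excursion that
#'   make it transient. Default 2.
#' @param loc_prob_min localization-probability cutoff (strict `>`).
#'   Default 0.75.
#' @param window_halfwidth residues kept either side of the acceptor.
#'   Default 6.
#' @return list of validated parameters.
#' @export
dynamicsConfig <- function(fold_threshold = 1.5, min_run = 2L,
                           return_run = 2L, loc_prob_min = 0.75,
                           window_halfwidth = 6L) {
    stopifnot(fold_threshold > 1, min_run >= 1, return_run >= 1,
              loc_prob_min >= 0, loc_prob_min <= 1)
    list(fold_threshold = fold_threshold,
         theta = log2(fold_threshold),
         min_run = as.integer(min_run),
         return_run = as.integer(return_run),
         loc_prob_min = loc_prob_min,
         window_halfwidth = as.integer(window_halfwidth))
}

.intensityCols <- function(design = plexDesign()) {
    rownames(designColData(design))
}

#' Read a native phosphosite quantification table
#'
#' Reads a tab-separated site table (columns `protein_id`, `position`,
#' `residue`, `loc_prob`, `multiplicity`, `window`, then the 20 intensity
#' columns `ctrl_t0` ... `mut_t90`) into a [PhosphoSet]. Intensities that are
#' empty, `"NA"` or non-numeric become missing; zeros are treated as not
#' quantified. Row order is preserved.
#'
#' @param path file path to a TSV.
#' @param design a [plexDesign()].
#' @param scale_tag `"raw_log2"` if the file holds raw intensities (they are
#'   log2-transformed at load), or `"median_normalized"` /
#'   `"t0_normalized"` if the table is already on a processed log2 scale (in
#'   which case values are taken as-is).
#' @return a `PhosphoSet`.
#' @export
readSiteTable <- function(path, design = plexDesign(),
                          scale_tag = "raw_log2") {
    scale_tag <- match.arg(scale_tag, .SCALE_TAGS)
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE)
    need <- c("protein_id", "position", "residue", "loc_prob",
              "multiplicity", "window", .intensityCols(design))
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("site table is missing required column(s): ",
             paste(miss, collapse = ", "))
    key <- paste(df$protein_id, df$position, sep = "_")
    if (anyDuplicated(key))
        stop("duplicate (protein_id, position) keys: ",
             paste(unique(key[duplicated(key)]), collapse = ", "))
    ic <- .intensityCols(design)
    raw <- suppressWarnings(
        matrix(as.numeric(as.matrix(df[, ic, drop = FALSE])),
               nrow = nrow(df), dimnames = list(NULL, ic)))
    raw[!is.na(raw) & raw <= 0] <- NA_real_
    vals <- if (scale_tag == "raw_log2") log2(raw) else raw
    rowData <- S4Vectors::DataFrame(
        protein_id = df$protein_id,
        position = as.integer(df$position),
        residue = df$residue,
        loc_prob = as.numeric(df$loc_prob),
        multiplicity = as.integer(df$multiplicity),
        window = toupper(df$window))
    PhosphoSet(vals, rowData, scale_tag = scale_tag, design = design)
}

#' Read a MaxQuant-style Phospho(STY)Sites table
#'
#' Thin adapter mapping MaxQuant column conventions onto the native schema:
#' `Protein`, `Position`, `Amino acid`, `Localization prob`, and per plex
#' group the ten `Reporter intensity corrected <0..9> <group label>` columns.
#' Within one group, channels 0..4 are the control and 5..9 the mutant at
#' that group's five time points in ascending order. Multiplicity is taken
#' from a `Multiplicity` column if present, else 1. The sequence window is
#' trimmed/padded to the 13-mer convention from `Sequence window` if present.
#'
#' @param path TSV file path.
#' @param design a [plexDesign()].
#' @param group_labels character(2), the labels naming the two plex groups in
#'   the reporter columns, in (A, B) order.
#' @param scale_tag as in [readSiteTable()].
#' @return a `PhosphoSet`.
#' @export
readMaxQuantSites <- function(path, design = plexDesign(),
                              group_labels = c("A", "B"),
                              scale_tag = "raw_log2") {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            colClasses = "character", check.names = FALSE)
    need <- c("Protein", "Position", "Amino acid", "Localization prob")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop("MaxQuant table is missing required column(s): ",
             paste(miss, collapse = ", "))
    n <- nrow(df)
    ic <- .intensityCols(design)
    raw <- matrix(NA_real_, n, length(ic), dimnames = list(NULL, ic))
    groups <- list(A = sort(design$group_A), B = sort(design$group_B))
    for (g in c(1L, 2L)) {
        gtimes <- groups[[g]]
        for (ch in 0:9) {
            col <- paste("Reporter intensity corrected", ch, group_labels[g])
            if (!col %in% colnames(df))
                stop("MaxQuant table is missing reporter column: ", col)
            cond <- if (ch < 5) "ctrl" else "mut"
            tm <- gtimes[(ch %% 5) + 1L]
            raw[, paste0(cond, "_t", tm)] <-
                suppressWarnings(as.numeric(df[[col]]))
        }
    }
    raw[!is.na(raw) & raw <= 0] <- NA_real_
    vals <- if (scale_tag == "raw_log2") log2(raw) else raw
    win <- if ("Sequence window" %in% colnames(df)) {
        w <- toupper(df[["Sequence window"]])
        half <- (nchar(w) - 1L) %/% 2L
        substr(w, half - 5L, half + 7L)
    } else {
        paste0("______", df[["Amino acid"]], "______")
    }
    mult <- if ("Multiplicity" %in% colnames(df))
        as.integer(df[["Multiplicity"]]) else rep(1L, n)
    rowData <- S4Vectors::DataFrame(
        protein_id = df$Protein,
        position = as.integer(df$Position),
        residue = df[["Amino acid"]],
        loc_prob = as.numeric(df[["Localization prob"]]),
        multiplicity = mult,
        window = win)
    PhosphoSet(vals, rowData, scale_tag = scale_tag, design = design)
}

#' Export a PhosphoSet as a native site table
#'
#' Inverse of [readSiteTable()]: writes the TSV schema the reader consumes.
#' Values are written on the object's current scale; for `"raw_log2"` objects
#' the linear intensities (`2^value`) are emitted so that
#' `readSiteTable(writeSiteTable(x))` round-trips.
#'
#' @param x a `PhosphoSet`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSiteTable <- function(x, path) {
    m <- SummarizedExperiment::assays(x)[["log2intensity"]]
    out <- if (scaleTag(x) == "raw_log2") 2^m else m
    rd <- SummarizedExperiment::rowData(x)
    df <- data.frame(protein_id = rd$protein_id, position = rd$position,
                     residue = rd$residue, loc_prob = rd$loc_prob,
                     multiplicity = rd$multiplicity, window = rd$window,
                     as.data.frame(out), check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}

.format6 <- function(x) {
    if (is.numeric(x)) {
        out <- formatC(x, format = "f", digits = 6)
        out[is.na(x)] <- ""
        out
    } else x
}

#' Write result tables deterministically
#'
#' Writes each table in a named list to `<out_dir>/<name>.tsv` with rows
#' ordered by `protein_id` then `position` (when those columns exist) and all
#' numeric columns fixed to 6 decimals, so that re-running on identical input
#' produces byte-identical files.
#'
#' @param tables non-empty named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
writeResults <- function(tables, out_dir) {
    stopifnot(length(tables) > 0, !is.null(names(tables)),
              all(nzchar(names(tables))))
    if (!dir.exists(out_dir))
        dir.create(out_dir, recursive = TRUE)
    if (file.access(out_dir, mode = 2L) != 0L)
        stop("output directory is not writable: ", out_dir)
    paths <- character(0)
    for (nm in names(tables)) {
        df <- as.data.frame(tables[[nm]])
        if (nrow(df) > 0 && all(c("protein_id", "position") %in% colnames(df)))
            df <- df[order(df$protein_id, df$position), , drop = FALSE]
        df[] <- lapply(df, .format6)
        p <- file.path(out_dir, paste0(nm, ".tsv"))
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE, na = "")
        paths <- c(paths, p)
    }
    invisible(paths)
}

#' Read a proteome FASTA into a named sequence vector
#'
#' Sequences are uppercased and keyed by the first whitespace-delimited token
#' of each header. Non-standard amino-acid characters raise an error.
#'
#' @param path FASTA file path.
#' @return named character vector of protein sequences (possibly empty, with
#'   a warning, for an empty file).
#' @export
readProteomeFasta <- function(path) {
    if (file.size(path) == 0) {
        warning("empty FASTA file: ", path)
        return(stats::setNames(character(0), character(0)))
    }
    # BStringSet keeps unexpected characters so validation can see them
    aa <- Biostrings::readBStringSet(path)
    if (length(aa) == 0) {
        warning("no records in FASTA file: ", path)
        return(stats::setNames(character(0), character(0)))
    }
    seqs <- toupper(as.character(aa))
    names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
    bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", seqs)
    if (any(bad))
        stop("non-amino-acid characters in sequence(s): ",
             paste(names(seqs)[bad], collapse = ", "))
    seqs
}
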