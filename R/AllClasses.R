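#' PhosphoSet: a container for TMT time-course phosphosite quantifications
#'
#' `PhosphoSet` extends [SummarizedExperiment::SummarizedExperiment] to hold
#' one phosphoproteomics time course: rows are phosphosites, columns are the
#' 20 reporter channels (2 conditions x 10 time points). Two assays are
#' carried in parallel: `"log2intensity"` (numeric, `NA` where a channel was
#' not quantified) and `"status"` (character; `"measured"`, `"imputed"` or
#' `"smoothed"`, `NA` while a value is still missing).
#'
#' Row metadata records site identity and quality: `protein_id`, 1-based
#' `position`, acceptor `residue` (S/T/Y), localization probability
#' `loc_prob`, peptide `multiplicity` and the 13-residue sequence `window`
#' centred on the acceptor ('_'-padded at protein termini). Column metadata
#' records `condition` ("ctrl"/"mut"), `time` in minutes and the TMT
#' `plex_group` ("A" for times 0/10/20/30/60, "B" for 5/15/25/40/90).
#'
#' `metadata(x)$scale_tag` tracks the processing stage and only moves
#' forward: `"raw_log2"` -> `"median_normalized"` -> `"t0_normalized"`.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @aliases PhosphoSet-class
#' @exportClass PhosphoSet
setClass("PhosphoSet", contains = "SummarizedExperiment")

.SCALE_TAGS <- c("raw_log2", "median_normalized", "t0_normalized")
.STATUS_LEVELS <- c("measured", "imputed", "smoothed")
.CONDITIONS <- c("ctrl", "mut")

.validPhosphoSet <- function(object) {
    msg <- character()
    a <- SummarizedExperiment::assayNames(object)
    if (!all(c("log2intensity", "status") %in% a))
        msg <- c(msg, "assays must include 'log2intensity' and 'status'")
    cd <- SummarizedExperiment::colData(object)
    need_cd <- c("condition", "time", "plex_group")
    if (!all(need_cd %in% colnames(cd))) {
        msg <- c(msg, paste0("colData must have columns: ",
                             paste(need_cd, collapse = ", ")))
    } else {
        if (!all(cd$condition %in% .CONDITIONS))
            msg <- c(msg, "condition must be 'ctrl' or 'mut'")
        if (!all(cd$time %in% timeGrid()))
            msg <- c(msg, "time must lie on the 10-point grid")
    }
    rd <- SummarizedExperiment::rowData(object)
    need_rd <- c("protein_id", "position", "residue", "loc_prob",
                 "multiplicity", "window")
    if (!all(need_rd %in% colnames(rd))) {
        msg <- c(msg, paste0("rowData must have columns: ",
                             paste(need_rd, collapse = ", ")))
    } else if (nrow(rd) > 0L) {
        if (!all(nchar(rd$window) == 13L))
            msg <- c(msg, "windows must be 13-mers")
        else if (!all(substr(rd$window, 7L, 7L) == rd$residue))
            msg <- c(msg, "window position 0 (index 7) must equal residue")
        if (!all(rd$residue %in% c("S", "T", "Y")))
            msg <- c(msg, "residue must be S, T or Y")
    }
    tag <- S4Vectors::metadata(object)$scale_tag
    if (is.null(tag) || !tag %in% .SCALE_TAGS)
        msg <- c(msg, "metadata scale_tag must be one of raw_log2, median_normalized, t0_normalized")
    st <- SummarizedExperiment::assays(object)[["status"]]
    if (!is.null(st) && !all(st[!is.na(st)] %in% .STATUS_LEVELS))
        msg <- c(msg, "status values must be measured/imputed/smoothed")
    if (length(msg)) msg else TRUE
}
setValidity("PhosphoSet", .validPhosphoSet)

#' Construct a PhosphoSet
#'
#' @param log2intensity numeric matrix, sites x 20 channels, columns named
#'   `<ctrl|mut>_t<minutes>` in design order; `NA` = not quantified.
#' @param rowData DataFrame/data.frame with protein_id, position, residue,
#'   loc_prob, multiplicity, window.
#' @param status optional character matrix matching `log2intensity`
#'   ("measured" where a value is present by default).
#' @param scale_tag processing stage tag; default `"raw_log2"`.
#' @param design a [plexDesign()] list used to build colData.
#' @return a `PhosphoSet`.
#' @examples
#' ps <- generateDataset(simConfig(n_sites = 20, seed = 1))$sites
#' ps
#' @export
PhosphoSet <- function(log2intensity, rowData, status = NULL,
                       scale_tag = "raw_log2", design = plexDesign()) {
    cd <- designColData(design)
    stopifnot(ncol(log2intensity) == nrow(cd))
    colnames(log2intensity) <- rownames(cd)
    if (is.null(status)) {
        status <- matrix(NA_character_, nrow(log2intensity), ncol(log2intensity),
                         dimnames = dimnames(log2intensity))
        status[!is.na(log2intensity)] <- "measured"
    }
    rowData <- S4Vectors::DataFrame(rowData)
    rn <- paste(rowData$protein_id, rowData$position, rowData$residue, sep = "_")
    rownames(log2intensity) <- rn
    rownames(status) <- rn
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2intensity = log2intensity, status = status),
        rowData = rowData, colData = cd)
    S4Vectors::metadata(se)$scale_tag <- scale_tag
    methods::new("PhosphoSet", se)
}

#' @describeIn PhosphoSet compact display
#' @param object a PhosphoSet
#' @export
setMethod("show", "PhosphoSet", function(object) {
    cat("PhosphoSet with", nrow(object), "phosphosites x",
        ncol(object), "channels\n")
    cat("  scale:", S4Vectors::metadata(object)$scale_tag, "\n")
    st <- SummarizedExperiment::assays(object)[["status"]]
    tab <- table(factor(st, levels = .STATUS_LEVELS), useNA = "ifany")
    cat("  status:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    res <- table(SummarizedExperiment::rowData(object)$residue)
    cat("  acceptors:", paste(names(res), res, sep = "=", collapse = " "), "\n")
    invisible(NULL)
})
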