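#' @name mitophos-accessors
#' @title Accessors for PhosphoSet objects
#'
#' @description Small accessor layer over the `PhosphoSet` slots:
#' `scaleTag()` reads/advances the processing-stage tag, `siteKeys()` returns
#' the canonical `(protein_id, position, residue)` key strings,
#' `siteWindows()` the 13-mer sequence windows, `profileMatrix()` a
#' sites-by-time matrix for one condition in time-grid order, and
#' `statusMatrix()` the measured/imputed/smoothed provenance flags.
#'
#' @param x a `PhosphoSet`.
#' @param condition `"ctrl"` or `"mut"`.
#' @param value replacement value.
NULL

#' @rdname mitophos-accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))

#' @rdname mitophos-accessors
#' @export
setGeneric("scaleTag<-", function(x, value) standardGeneric("scaleTag<-"))

#' @rdname mitophos-accessors
#' @export
setGeneric("siteKeys", function(x) standardGeneric("siteKeys"))

#' @rdname mitophos-accessors
#' @export
setGeneric("siteWindows", function(x) standardGeneric("siteWindows"))

#' @rdname mitophos-accessors
#' @export
setGeneric("profileMatrix", function(x, condition = "ctrl")
    standardGeneric("profileMatrix"))

#' @rdname mitophos-accessors
#' @export
setGeneric("statusMatrix", function(x) standardGeneric("statusMatrix"))

#' @rdname mitophos-accessors
#' @export
setMethod("scaleTag", "PhosphoSet", function(x)
    S4Vectors::metadata(x)$scale_tag)

#' @rdname mitophos-accessors
#' @export
setReplaceMethod("scaleTag", "PhosphoSet", function(x, value) {
    old <- match(S4Vectors::metadata(x)$scale_tag, .SCALE_TAGS)
    new <- match(value, .SCALE_TAGS)
    if (is.na(new))
        stop("unknown scale_tag: ", value)
    if (new < old)
        stop("scale_tag may only advance (", .SCALE_TAGS[old],
             " -> ", value, " is backwards)")
    S4Vectors::metadata(x)$scale_tag <- value
    methods::validObject(x)
    x
})

#' @rdname mitophos-accessors
#' @export
setMethod("siteKeys", "PhosphoSet", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    paste(rd$protein_id, rd$position, rd$residue, sep = "_")
})

#' @rdname mitophos-accessors
#' @export
setMethod("siteWindows", "PhosphoSet", function(x)
    SummarizedExperiment::rowData(x)$window)

#' @rdname mitophos-accessors
#' @export
setMethod("profileMatrix", "PhosphoSet", function(x, condition = "ctrl") {
    condition <- match.arg(condition, .CONDITIONS)
    cd <- SummarizedExperiment::colData(x)
    sel <- which(cd$condition == condition)
    sel <- sel[order(cd$time[sel])]
    m <- SummarizedExperiment::assays(x)[["log2intensity"]][, sel, drop = FALSE]
    colnames(m) <- paste0("t", cd$time[sel])
    m
})

#' @rdname mitophos-accessors
#' @export
setMethod("statusMatrix", "PhosphoSet", function(x)
    SummarizedExperiment::assays(x)[["status"]])
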