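#' Accessors for RDItools objects
#'
#' \code{featureCounts} returns the feature-by-repertoire count matrix;
#' \code{repertoireSizes} the per-repertoire totals (column sums);
#' \code{featureType} the label of the feature axis (e.g. \code{"v_gene"});
#' \code{repertoireTruth} the simulated ground-truth deviations recorded in
#' \code{colData} (or \code{NULL} for real data); \code{rdiValues} the
#' symmetric value matrix of an \code{\linkS4class{RDIMatrix}};
#' \code{rdiParams} its parameter object; \code{resolvedSubsampleSize} the
#' common subsampling depth it was computed at.
#'
#' @param x a \code{\linkS4class{RepertoireCounts}} or
#'   \code{\linkS4class{RDIMatrix}} object.
#' @return See each accessor's description.
#' @name accessors
#' @examples
#' rc <- simulatePerturbedSet(defaultBaseline(10), sigmas = c(0.5, 1),
#'     nSeq = 200, nBaseline = 2, seed = 1)
#' featureType(rc)
#' repertoireSizes(rc)
#' repertoireTruth(rc)
NULL

#' @rdname accessors
#' @export
setGeneric("featureCounts", function(x) standardGeneric("featureCounts"))

#' @rdname accessors
#' @export
setMethod("featureCounts", "RepertoireCounts", function(x)
    SummarizedExperiment::assay(x, "counts"))

#' @rdname accessors
#' @export
setGeneric("repertoireSizes", function(x) standardGeneric("repertoireSizes"))

#' @rdname accessors
#' @export
setMethod("repertoireSizes", "RepertoireCounts", function(x)
    colSums(featureCounts(x)))

#' @rdname accessors
#' @export
setGeneric("featureType", function(x) standardGeneric("featureType"))

#' @rdname accessors
#' @export
setMethod("featureType", "RepertoireCounts", function(x) {
    fn <- S4Vectors::metadata(x)$featureName
    if (is.null(fn)) "feature" else fn
})

#' @rdname accessors
#' @export
setGeneric("repertoireTruth", function(x) standardGeneric("repertoireTruth"))

#' @rdname accessors
#' @export
setMethod("repertoireTruth", "RepertoireCounts", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if (!all(c("true_log2fc", "true_pct_change") %in% names(cd)))
        return(NULL)
    data.frame(repertoire_id = colnames(x),
        true_log2fc = cd$true_log2fc,
        true_pct_change = cd$true_pct_change,
        row.names = NULL)
})

#' @rdname accessors
#' @export
setGeneric("rdiValues", function(x) standardGeneric("rdiValues"))

#' @rdname accessors
#' @export
setMethod("rdiValues", "RDIMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("rdiParams", function(x) standardGeneric("rdiParams"))

#' @rdname accessors
#' @export
setMethod("rdiParams", "RDIMatrix", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("resolvedSubsampleSize",
    function(x) standardGeneric("resolvedSubsampleSize"))

#' @rdname accessors
#' @export
setMethod("resolvedSubsampleSize", "RDIMatrix", function(x)
    x@resolvedSubsampleSize)

#' @export
#' @rdname accessors
#' @param ... ignored.
setMethod("as.matrix", "RDIMatrix", function(x, ...) x@values)

#' Ladder and calibration accessors
#'
#' \code{ladderEntries} returns the (deviation, mean_rdi, sd_rdi) table of an
#' \code{\linkS4class{RDILadder}}; \code{deviationUnits} the unit of the
#' deviation axis (\code{"log2fc"} or \code{"pct_change"});
#' \code{calibrationSettings} the simulation/RDI settings a calibration model
#' is valid for; \code{nullSample} its stored baseline-vs-baseline RDI values.
#'
#' @param x an \code{\linkS4class{RDILadder}} or
#'   \code{\linkS4class{RDICalibration}}.
#' @return See each accessor's description.
#' @name ladder-accessors
NULL

#' @rdname ladder-accessors
#' @export
setGeneric("ladderEntries", function(x) standardGeneric("ladderEntries"))

#' @rdname ladder-accessors
#' @export
setMethod("ladderEntries", "RDILadder", function(x) x@entries)

#' @rdname ladder-accessors
#' @export
setGeneric("deviationUnits", function(x) standardGeneric("deviationUnits"))

#' @rdname ladder-accessors
#' @export
setMethod("deviationUnits", "RDILadder", function(x) x@units)

#' @rdname ladder-accessors
#' @export
setMethod("deviationUnits", "RDICalibration", function(x) x@units)

#' @rdname ladder-accessors
#' @export
setGeneric("calibrationSettings",
    function(x) standardGeneric("calibrationSettings"))

#' @rdname ladder-accessors
#' @export
setMethod("calibrationSettings", "RDICalibration", function(x) x@settings)

#' @rdname ladder-accessors
#' @export
setGeneric("nullSample", function(x) standardGeneric("nullSample"))

#' @rdname ladder-accessors
#' @export
setMethod("nullSample", "RDICalibration", function(x) x@nullSample)

setMethod("show", "RDIParams", function(object) {
    ss <- if (is.na(object@subsampleSize)) "auto (minimum repertoire size)"
        else format(object@subsampleSize)
    cat("RDIParams\n",
        "  subsample size: ", ss, "\n",
        "  normalization constant: ", object@normConstant, "\n",
        "  transform: ", object@transform, "\n",
        "  iterations: ", object@nIterations, "\n",
        "  distance mode: ", object@distanceMode, "\n", sep = "")
})

setMethod("show", "RepertoireCounts", function(object) {
    cat("RepertoireCounts: ", ncol(object), " repertoires x ", nrow(object),
        " features (", featureType(object), ")\n", sep = "")
    sz <- repertoireSizes(object)
    cat("  sizes: ", paste(range(sz), collapse = "-"), "\n", sep = "")
    if (!is.null(repertoireTruth(object)))
        cat("  simulated set with recorded ground-truth deviations\n")
})

setMethod("show", "RDIMatrix", function(object) {
    cat("RDIMatrix: ", nrow(object@values), " repertoires, subsampled to ",
        object@resolvedSubsampleSize, "\n", sep = "")
    off <- object@values[upper.tri(object@values)]
    if (length(off))
        cat("  RDI range: ", format(min(off), digits = 4), " - ",
            format(max(off), digits = 4), "\n", sep = "")
    cat("  transform: ", object@params@transform, ", iterations: ",
        object@params@nIterations, "\n", sep = "")
})

setMethod("show", "RDICalibration", function(object) {
    s <- object@settings
    cat("RDICalibration (", object@units, ")\n", sep = "")
    cat("  fitted on ", nrow(object@points), " perturbation vectors, ",
        "deviation range 0-", format(max(object@grid), digits = 3),
        "\n", sep = "")
    cat("  settings: ", s$nFeatures, " features, ", s$nSeq,
        " sequences, transform ", s$transform, "\n", sep = "")
    cat("  null sample: ", length(object@nullSample), " values\n", sep = "")
})

setMethod("show", "RDILadder", function(object) {
    cat("RDILadder (", object@units, "): ", nrow(object@entries),
        " entries\n", sep = "")
    if (nrow(object@entries)) print(object@entries, row.names = FALSE)
})
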