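#' @import methods
#' @importFrom stats approx dist dnorm isoreg predict rhyper
#'   rmultinom rnorm sd smooth.spline uniroot runif
#' @importFrom utils read.delim write.table count.fields
NULL

.TRANSFORMS <- c("none", "asinh")
.DISTANCE_MODES <- c("euclidean", "rmsd")
.COLLAPSE_LEVELS <- c("allele", "gene", "family")
.DEVIATION_UNITS <- c("log2fc", "pct_change")

#' Parameters controlling an RDI computation
#'
#' An \code{RDIParams} object bundles the tunable settings of the five-step
#' RDI procedure: the common subsampling depth, the normalization constant,
#' the optional ArcSinh transform, the number of subsampling iterations, and
#' whether distances are reported as plain Euclidean distance or as
#' root-mean-square deviation (Euclidean divided by the square root of the
#' number of features).
#'
#' @slot subsampleSize numeric(1); the common depth every repertoire is
#'   subsampled to. \code{NA} (the default) means "auto": the smallest
#'   repertoire total at the time \code{\link{calcRDI}} is called.
#' @slot normConstant numeric(1); total that each subsampled count vector is
#'   rescaled to before the transform (default 500).
#' @slot transform character(1); \code{"asinh"} (default) or \code{"none"}.
#'   With \code{"asinh"} the RDI tracks average log2 fold changes; without it,
#'   average percent changes.
#' @slot nIterations integer(1); number of subsampling realizations averaged
#'   into the final RDI (default 100).
#' @slot distanceMode character(1); \code{"euclidean"} (default) or
#'   \code{"rmsd"}.
#'
#' @seealso \code{\link{calcRDI}}
#' @export
setClass("RDIParams",
    representation(
        subsampleSize = "numeric",
        normConstant = "numeric",
        transform = "character",
        nIterations = "integer",
        distanceMode = "character"
    ),
    prototype(
        subsampleSize = NA_real_,
        normConstant = 500,
        transform = "asinh",
        nIterations = 100L,
        distanceMode = "euclidean"
    )
)

setValidity("RDIParams", function(object) {
    msg <- character()
    ss <- object@subsampleSize
    if (length(ss) != 1L)
        msg <- c(msg, "subsampleSize must be a single number or NA (auto)")
    else if (!is.na(ss) && (ss < 1 || ss != floor(ss)))
        msg <- c(msg, "subsampleSize must be a positive integer or NA (auto)")
    if (length(object@normConstant) != 1L || !is.finite(object@normConstant) ||
        object@normConstant <= 0)
        msg <- c(msg, "normConstant must be a single positive number")
    if (length(object@transform) != 1L ||
        !object@transform %in% .TRANSFORMS)
        msg <- c(msg, sprintf("transform must be one of: %s",
            paste(.TRANSFORMS, collapse = ", ")))
    if (length(object@nIterations) != 1L || is.na(object@nIterations) ||
        object@nIterations < 1L)
        msg <- c(msg, "nIterations must be a positive integer")
    if (length(object@distanceMode) != 1L ||
        !object@distanceMode %in% .DISTANCE_MODES)
        msg <- c(msg, sprintf("distanceMode must be one of: %s",
            paste(.DISTANCE_MODES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' @param subsampleSize,normConstant,transform,nIterations,distanceMode see
#'   the corresponding slots.
#' @return \code{RDIParams()} returns a validated parameter object.
#' @examples
#' RDIParams()
#' RDIParams(transform = "none", nIterations = 25)
#' @rdname RDIParams-class
#' @export
RDIParams <- function(subsampleSize = NA, normConstant = 500,
                      transform = c("asinh", "none"), nIterations = 100,
                      distanceMode = c("euclidean", "rmsd")) {
    new("RDIParams",
        subsampleSize = as.numeric(subsampleSize),
        normConstant = as.numeric(normConstant),
        transform = match.arg(transform),
        nIterations = as.integer(nIterations),
        distanceMode = match.arg(distanceMode))
}

#' Repertoires-by-features count container
#'
#' \code{RepertoireCounts} holds the universal input to the RDI: a
#' non-negative integer matrix of feature counts (gene segments as rows,
#' repertoires as columns), stored as the \code{"counts"} assay of a
#' \code{\link[SummarizedExperiment]{SummarizedExperiment}}. Simulated sets
#' additionally carry per-repertoire ground truth in \code{colData} (columns
#' \code{true_log2fc}, \code{true_pct_change}) and the baseline probability
#' vector in \code{metadata(x)$baseline}.
#'
#' @seealso \code{\link{tabulateFeatures}}, \code{\link{simulatePerturbedSet}},
#'   \code{\link{calcRDI}}
#' @export
#' @import SummarizedExperiment
setClass("RepertoireCounts", contains = "SummarizedExperiment")

setValidity("RepertoireCounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    m <- SummarizedExperiment::assay(object, "counts")
    if (!is.numeric(m))
        msg <- c(msg, "counts must be numeric")
    else {
        if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(abs(m - round(m)) > 1e-8))
            msg <- c(msg, "counts must be integral")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature labels (rownames) must be set and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "repertoire ids (colnames) must be set and unique")
    if (length(msg)) msg else TRUE
})

#' @param counts feature-by-repertoire integer matrix with dimnames, or a
#'   repertoire-by-feature matrix if \code{repertoiresAsRows = TRUE}.
#' @param featureName character(1) describing the feature axis (e.g.
#'   \code{"v_gene"}).
#' @param repertoiresAsRows logical(1); set \code{TRUE} when \code{counts} has
#'   repertoires in rows (the orientation of the CSV interchange format).
#' @param colData optional \code{DataFrame} of per-repertoire annotations.
#' @return \code{RepertoireCounts()} returns a validated object.
#' @examples
#' m <- matrix(c(5L, 3L, 0L, 2L), nrow = 2,
#'     dimnames = list(c("IGHV1-2", "IGHV3-23"), c("rep_a", "rep_b")))
#' rc <- RepertoireCounts(m, featureName = "v_gene")
#' repertoireSizes(rc)
#' @rdname RepertoireCounts-class
#' @export
RepertoireCounts <- function(counts, featureName = "feature",
                             repertoiresAsRows = FALSE, colData = NULL) {
    if (repertoiresAsRows) counts <- t(counts)
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(colData))
        colData <- S4Vectors::DataFrame(row.names = colnames(counts))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), colData = colData)
    S4Vectors::metadata(se)$featureName <- featureName
    new("RepertoireCounts", se)
}

#' Symmetric matrix of averaged RDI values
#'
#' The result of \code{\link{calcRDI}}: a symmetric non-negative matrix with a
#' zero diagonal, together with the parameters that produced it. RDI scores
#' only have a defined meaning relative to scores computed with the same
#' settings (in particular the same resolved subsample size), so those
#' settings travel with the values.
#'
#' @slot values symmetric numeric matrix of averaged distances.
#' @slot params the \code{\linkS4class{RDIParams}} used.
#' @slot resolvedSubsampleSize integer(1); the common depth actually used.
#' @slot seed numeric(1); seed recorded at computation time (NA if unseeded).
#' @export
setClass("RDIMatrix",
    representation(
        values = "matrix",
        params = "RDIParams",
        resolvedSubsampleSize = "integer",
        seed = "numeric"
    )
)

setValidity("RDIMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
    if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
        msg <- c(msg, "values must carry identical row/column repertoire ids")
    if (any(v < 0)) msg <- c(msg, "RDI values must be non-negative")
    if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "values must be symmetric")
    if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
    if (object@resolvedSubsampleSize < 1L)
        msg <- c(msg, "resolvedSubsampleSize must be positive")
    if (length(msg)) msg else TRUE
})

#' Calibration between RDI and true average deviation
#'
#' A fitted, monotone smoothing-spline mapping from the true average deviation
#' of a repertoire pair (average absolute log2 fold change, or average
#' absolute percent change for the untransformed metric) to the expected RDI
#' under the simulation protocol, with a rolling-window estimate of the local
#' residual standard deviation and the stored baseline-vs-baseline (null) RDI
#' sample. Built by \code{\link{buildCalibration}}.
#'
#' @slot points data.frame with columns \code{deviation} and \code{mean_rdi}:
#'   one point per perturbation vector.
#' @slot grid,fitted numeric; the monotonized spline evaluated on an even
#'   deviation grid (the forward map used by \code{\link{predictRDI}} and
#'   inverted by \code{\link{rdiToFold}}).
#' @slot sdCenters data.frame with columns \code{deviation} and \code{sd}:
#'   rolling-window residual SD, linearly interpolated between centers.
#' @slot units \code{"log2fc"} or \code{"pct_change"}.
#' @slot settings list of the simulation/RDI settings the model is valid for
#'   (nFeatures, nSeq, transform, distanceMode, normConstant, nIterations).
#' @slot nullSample numeric; baseline-vs-baseline RDI values (deviation 0).
#' @export
setClass("RDICalibration",
    representation(
        points = "data.frame",
        grid = "numeric",
        fitted = "numeric",
        sdCenters = "data.frame",
        units = "character",
        settings = "list",
        nullSample = "numeric"
    )
)

setValidity("RDICalibration", function(object) {
    msg <- character()
    if (length(object@grid) != length(object@fitted))
        msg <- c(msg, "grid and fitted must have equal length")
    if (is.unsorted(object@grid, strictly = TRUE))
        msg <- c(msg, "grid must be strictly increasing")
    if (any(diff(object@fitted) < -1e-9))
        msg <- c(msg, "fitted spline must be non-decreasing")
    if (!object@units %in% .DEVIATION_UNITS)
        msg <- c(msg, "units must be 'log2fc' or 'pct_change'")
    if (length(msg)) msg else TRUE
})

#' Reference ladder of RDI distributions at fixed deviations
#'
#' A set of (deviation, mean RDI, SD of RDI) entries read off an
#' \code{\linkS4class{RDICalibration}}; each entry parameterizes an
#' approximate Gaussian reference distribution of RDI values for repertoire
#' pairs differing by that average fold/percent change. Built by
#' \code{\link{makeLadder}}.
#'
#' @slot entries data.frame with columns \code{deviation}, \code{mean_rdi},
#'   \code{sd_rdi}; deviations strictly increasing.
#' @slot units \code{"log2fc"} or \code{"pct_change"}.
#' @export
setClass("RDILadder",
    representation(entries = "data.frame", units = "character")
)

setValidity("RDILadder", function(object) {
    e <- object@entries
    msg <- character()
    if (!all(c("deviation", "mean_rdi", "sd_rdi") %in% names(e)))
        return("entries must have columns deviation, mean_rdi, sd_rdi")
    if (nrow(e) > 1L && is.unsorted(e$deviation, strictly = TRUE))
        msg <- c(msg, "deviations must be strictly increasing")
    if (nrow(e) > 0L && any(e$sd_rdi <= 0))
        msg <- c(msg, "sd_rdi must be positive")
    if (length(msg)) msg else TRUE
})
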