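# Core of the five-step RDI procedure: subsample without replacement to a
# common depth, normalize to a fixed total, optionally ArcSinh-transform,
# take Euclidean / RMS deviation between every pair, and average over
# repeated subsampling realizations.

# Run expr with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards. seed = NULL leaves the global stream alone.
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(expr)
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        runif(1L)
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    expr
}

# Multivariate hypergeometric draw: a chain of univariate hypergeometric
# draws over features. A full draw (m == sum) or an exhausted remainder
# short-circuits, so it is exact and cheap at the boundaries.
.subsampleVector <- function(v, m) {
    out <- integer(length(v))
    remTot <- sum(v)
    if (m == remTot) return(as.integer(v))
    remDraw <- m
    for (i in seq_along(v)) {
        if (remDraw == 0L) break
        ki <- v[i]
        remTot <- remTot - ki
        if (remTot == 0L) {  # everything left must be drawn
            out[i] <- remDraw
            break
        }
        xi <- rhyper(1L, ki, remTot, remDraw)
        out[i] <- xi
        remDraw <- remDraw - xi
    }
    out
}

# Column j of a features x repertoires matrix is subsampled without
# replacement to m[j] elements. Columns are processed in order, each through
# .subsampleVector, so the RNG stream is consumed repertoire by repertoire —
# composing subsampleCounts() by hand over the same stream gives identical
# draws.
.subsampleMatrix <- function(counts, m) {
    nrep <- ncol(counts)
    tot <- colSums(counts)
    m <- rep(as.numeric(m), length.out = nrep)
    if (any(m > tot))
        stop("subsample size exceeds repertoire total (",
             paste(colnames(counts)[m > tot], collapse = ", "), ")")
    out <- matrix(0L, nrow(counts), nrep, dimnames = dimnames(counts))
    for (j in seq_len(nrep))
        out[, j] <- .subsampleVector(counts[, j], m[j])
    out
}

#' Subsample a count vector without replacement
#'
#' Draws \code{m} of the \code{sum(counts)} pooled elements without
#' replacement and tallies them per feature: a multivariate hypergeometric
#' draw. This is Step 1 of the RDI procedure, applied to every repertoire so
#' that all are compared at the same depth.
#'
#' @param counts non-negative integer vector of feature counts.
#' @param m number of elements to draw; must not exceed \code{sum(counts)}.
#' @return integer vector of the same length as \code{counts}, summing to
#'   \code{m}, with each entry bounded by the original count.
#' @examples
#' set.seed(1)
#' subsampleCounts(c(8, 2), 5)
#' @export
subsampleCounts <- function(counts, m) {
    if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
        stop("counts must be non-negative integers")
    if (length(m) != 1L || m < 0 || m != floor(m))
        stop("m must be a single non-negative integer")
    if (m > sum(counts))
        stop("m (", m, ") exceeds the total count (", sum(counts), ")")
    out <- .subsampleMatrix(cbind(as.integer(round(counts))), m)[, 1L]
    names(out) <- names(counts)
    out
}

#' Normalize counts to a fixed total
#'
#' Rescales a count vector so it sums to \code{constant} (Step 3a); the
#' default constant of 500 matches the standard RDI settings.
#'
#' @param counts numeric vector with positive sum.
#' @param constant positive total to rescale to.
#' @return numeric vector summing to \code{constant}.
#' @examples
#' normalizeCounts(c(1, 1, 2), 500)
#' @export
normalizeCounts <- function(counts, constant = 500) {
    s <- sum(counts)
    if (s <= 0) stop("cannot normalize a vector with non-positive sum")
    if (constant <= 0) stop("constant must be positive")
    counts * (constant / s)
}

#' Optionally ArcSinh-transform normalized counts
#'
#' Step 3b: the inverse hyperbolic sine, \code{log(x + sqrt(x^2 + 1))}, is
#' approximately linear near zero and logarithmic above one, so with the
#' transform the RDI tracks average log2 fold changes rather than being
#' dominated by percentage changes in the most prevalent genes. No cofactor
#' is applied.
#'
#' @param v non-negative numeric vector.
#' @param method \code{"asinh"} or \code{"none"} (identity).
#' @return transformed numeric vector.
#' @examples
#' transformCounts(c(0, 1, 500), "asinh")
#' @export
transformCounts <- function(v, method = c("asinh", "none")) {
    method <- match.arg(method)
    if (method == "none") v else asinh(v)
}

#' Euclidean or root-mean-square distance between two feature vectors
#'
#' Step 4 of the RDI procedure. \code{"rmsd"} is the Euclidean distance
#' divided by the square root of the number of features; the two differ only
#' by a constant factor that calibration absorbs.
#'
#' @param a,b numeric vectors of equal length.
#' @param mode \code{"euclidean"} or \code{"rmsd"}.
#' @return a single non-negative number; zero iff \code{a == b}.
#' @examples
#' vectorDistance(c(250, 0, 250), c(0, 250, 250))
#' @export
vectorDistance <- function(a, b, mode = c("euclidean", "rmsd")) {
    mode <- match.arg(mode)
    if (length(a) != length(b))
        stop("vectors must have equal length")
    if (!length(a)) stop("vectors must be non-empty")
    d <- sqrt(sum((a - b)^2))
    if (mode == "rmsd") d <- d / sqrt(length(a))
    d
}

# One subsampling realization: counts (features x repertoires) -> full
# symmetric distance matrix on the normalized, transformed profiles.
.realizationDistances <- function(counts, m, params) {
    s <- .subsampleMatrix(counts, m)
    f <- s * (params@normConstant / m)
    if (params@transform == "asinh") f <- asinh(f)
    d <- as.matrix(dist(t(f)))
    if (params@distanceMode == "rmsd") d <- d / sqrt(nrow(counts))
    d
}

#' Compute the Repertoire Dissimilarity Index between all repertoire pairs
#'
#' Runs the five-step procedure on a feature count table: in each of
#' \code{nIterations} realizations every repertoire is independently
#' subsampled without replacement to the common depth, normalized to the
#' normalization constant, optionally ArcSinh transformed, and all pairwise
#' Euclidean/RMS deviations are computed; the final RDI matrix is the
#' elementwise mean over realizations. Self-distances are 0 by convention
#' (two independent subsamples of the same repertoire would not give exactly
#' zero; the diagonal is defined, not estimated).
#'
#' When every repertoire total equals the resolved subsample size, the
#' without-replacement draw returns the full counts, every realization is
#' identical, and the distances are computed once.
#'
#' RDI values depend on the resolved subsample size and the other settings,
#' so scores are only comparable across matrices computed with equal
#' settings; the settings are recorded in the result.
#'
#' @param x a \code{\linkS4class{RepertoireCounts}} object, or a numeric
#'   matrix with repertoires in rows and features in columns.
#' @param params an \code{\link{RDIParams}} object.
#' @param seed optional integer; when given, the computation is run on a
#'   private RNG stream seeded with it (the caller's stream is untouched) and
#'   the result is reproducible.
#' @return an \code{\linkS4class{RDIMatrix}}.
#' @examples
#' m <- rbind(rep_a = c(20, 0), rep_b = c(0, 20))
#' colnames(m) <- c("V1", "V2")
#' rdiValues(calcRDI(m, RDIParams(transform = "none"), seed = 1))
#' @export
setGeneric("calcRDI", function(x, params = RDIParams(), seed = NULL)
    standardGeneric("calcRDI"))

#' @rdname calcRDI
#' @export
setMethod("calcRDI", "RepertoireCounts", function(x, params = RDIParams(),
                                                  seed = NULL) {
    .calcRDI(featureCounts(x), params, seed)
})

#' @rdname calcRDI
#' @export
setMethod("calcRDI", "matrix", function(x, params = RDIParams(),
                                        seed = NULL) {
    if (is.null(rownames(x)))
        rownames(x) <- paste0("repertoire_", seq_len(nrow(x)))
    .calcRDI(t(x), params, seed)
})

.calcRDI <- function(counts, params, seed = NULL) {
    validObject(params)
    if (ncol(counts) < 2L)
        stop("need at least 2 repertoires")
    tot <- colSums(counts)
    if (any(tot == 0))
        stop("repertoire(s) with zero total count: ",
             paste(colnames(counts)[tot == 0], collapse = ", "))
    m <- params@subsampleSize
    if (is.na(m)) m <- min(tot)
    if (m > min(tot))
        stop("subsample size (", m, ") exceeds the smallest repertoire (",
             min(tot), ": ", colnames(counts)[which.min(tot)], ")")
    nIter <- params@nIterations
    # identity subsampling: every realization is the same
    if (all(tot == m)) nIter <- 1L
    acc <- .withSeed(seed, {
        a <- .realizationDistances(counts, m, params)
        for (it in seq_len(nIter - 1L))
            a <- a + .realizationDistances(counts, m, params)
        a
    })
    vals <- acc / nIter
    vals <- (vals + t(vals)) / 2
    diag(vals) <- 0
    new("RDIMatrix", values = vals, params = params,
        resolvedSubsampleSize = as.integer(m),
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Shannon entropy of a feature count vector
#'
#' Diversity summary in bits: \eqn{-\sum_i p_i \log_2 p_i} over the features
#' with positive frequency, where \eqn{p_i} is the count fraction. Used as an
#' independent cross-check against RDI-derived fold changes (clonal expansion
#' lowers entropy while raising dissimilarity to the naive repertoire).
#'
#' @param counts non-negative numeric vector with positive sum.
#' @return entropy in bits.
#' @examples
#' shannonEntropy(c(250, 250))   # 1 bit
#' shannonEntropy(c(1, 1, 1, 1)) # 2 bits
#' @export
shannonEntropy <- function(counts) {
    if (any(counts < 0)) stop("counts must be non-negative")
    s <- sum(counts)
    if (s <= 0) stop("cannot compute entropy of an all-zero vector")
    p <- counts[counts > 0] / s
    -sum(p * log2(p))
}

#' Read and write an RDI matrix with its parameter sidecar
#'
#' The matrix is written as a square CSV (header row and first column of
#' repertoire ids); the parameters, resolved subsample size and seed go to a
#' JSON sidecar at \code{<path>.json} so downstream steps can verify that two
#' RDI computations are comparable.
#'
#' @param x an \code{\linkS4class{RDIMatrix}}.
#' @param path CSV path; the sidecar is written next to it.
#' @return \code{writeRDIMatrix} returns \code{path} invisibly;
#'   \code{readRDIMatrix} returns the reconstructed \code{RDIMatrix}.
#' @export
writeRDIMatrix <- function(x, path) {
    v <- rdiValues(x)
    df <- data.frame(repertoire_id = rownames(v), v, check.names = FALSE,
        row.names = NULL)
    write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
    p <- rdiParams(x)
    side <- list(
        subsample_size = if (is.na(p@subsampleSize)) "auto"
            else p@subsampleSize,
        resolved_subsample_size = x@resolvedSubsampleSize,
        norm_constant = p@normConstant,
        transform = p@transform,
        n_iterations = p@nIterations,
        distance_mode = p@distanceMode,
        seed = if (is.na(x@seed)) NULL else x@seed)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
        digits = NA)
    invisible(path)
}

#' @rdname writeRDIMatrix
#' @export
readRDIMatrix <- function(path) {
    if (!file.exists(path)) stop("input file not found: ", path)
    sidePath <- paste0(path, ".json")
    if (!file.exists(sidePath))
        stop("parameter sidecar not found: ", sidePath)
    df <- read.delim(path, sep = ",", header = TRUE, check.names = FALSE,
        stringsAsFactors = FALSE)
    v <- as.matrix(df[, -1L, drop = FALSE])
    rownames(v) <- df[[1L]]
    side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
    params <- RDIParams(
        subsampleSize = if (identical(side$subsample_size, "auto")) NA
            else side$subsample_size,
        normConstant = side$norm_constant,
        transform = side$transform,
        nIterations = side$n_iterations,
        distanceMode = side$distance_mode)
    new("RDIMatrix", values = v, params = params,
        resolvedSubsampleSize = as.integer(side$resolved_subsample_size),
        seed = if (is.null(side$seed)) NA_real_ else as.numeric(side$seed))
}
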