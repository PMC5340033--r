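# Calibration of the RDI against simulations with known truth: perturbed
# datasets matched to a real table's feature count and subsampled depth are
# compared to baseline datasets, a smoothing spline of mean RDI against true
# deviation is fitted and monotonized, and its residuals give local SD
# estimates for the reference "ladder".

.GRID_N <- 512L

#' Build an RDI-to-deviation calibration model
#'
#' Simulates the calibration protocol against a real (or simulated) count
#' table: the baseline probability vector is the table's average gene
#' frequency; \code{nPerturb} perturbation vectors are generated whose
#' realized average deviations form an even grid from 0 (no change) up to
#' \code{maxLog2fc} (2^8 = 256-fold by default); one dataset is drawn from
#' each perturbed vector and \code{nBaseline} datasets from the baseline, all
#' with the same number of sequences and features as the subsampled real
#' data; each perturbed dataset's RDI against every baseline dataset is
#' averaged; and a smoothing spline of mean RDI on realized deviation is
#' fitted, monotonized by isotonic projection, and equipped with a
#' rolling-window residual SD. The baseline-vs-baseline RDI values are kept
#' as the model's null sample.
#'
#' For the ArcSinh-transformed metric the deviation axis is in average
#' absolute log2 fold change; for the untransformed metric it is in average
#' absolute percent change.
#'
#' @param x the \code{\linkS4class{RepertoireCounts}} table the model must
#'   match (its feature count and minimum depth set the simulation size).
#' @param params \code{\link{RDIParams}} that will be used on the real data.
#' @param nPerturb number of perturbation vectors (2000 for the full
#'   protocol; a few hundred give a usable model for smaller studies).
#' @param nBaseline number of baseline datasets.
#' @param maxLog2fc largest average absolute log2 fold change simulated.
#' @param seed optional integer for a private, reproducible RNG stream.
#' @return an \code{\linkS4class{RDICalibration}}.
#' @examples
#' rs <- simulatePerturbedSet(defaultBaseline(20), sigmas = rep(0.5, 4),
#'     nSeq = 500, nBaseline = 2, seed = 7)
#' cal <- buildCalibration(rs, RDIParams(nIterations = 10), nPerturb = 60,
#'     nBaseline = 5, seed = 7)
#' cal
#' @export
buildCalibration <- function(x, params = RDIParams(), nPerturb = 2000,
                             nBaseline = 20, maxLog2fc = 8, seed = NULL) {
    validObject(params)
    stopifnot(nPerturb >= 10, nBaseline >= 2, maxLog2fc > 0)
    pBase <- baselineFromCounts(x)
    pBase <- pBase[pBase > 0]
    nFeatures <- length(pBase)
    tot <- repertoireSizes(x)
    nSeq <- if (is.na(params@subsampleSize)) min(tot)
        else as.integer(params@subsampleSize)
    units <- if (params@transform == "asinh") "log2fc" else "pct_change"

    .withSeed(seed, {
        targets <- seq(0, maxLog2fc, length.out = nPerturb)
        counts <- matrix(0L, nFeatures, nPerturb + nBaseline)
        devs <- numeric(nPerturb)
        for (j in seq_len(nPerturb)) {
            r <- perturbationAtDeviation(pBase, targets[j])
            pFc <- perturbProbabilities(pBase, r)
            devs[j] <- trueDeviation(pFc, pBase, units)
            counts[, j] <- drawRepertoire(pFc, nSeq)
        }
        for (j in seq_len(nBaseline))
            counts[, nPerturb + j] <- drawRepertoire(pBase, nSeq)
        dimnames(counts) <- list(names(pBase),
            c(sprintf("perturbed_%04d", seq_len(nPerturb)),
              sprintf("baseline_%03d", seq_len(nBaseline))))
        # every simulated dataset has exactly nSeq sequences, so calcRDI's
        # subsampling is the identity and the full matrix is cheap
        simParams <- params
        simParams@subsampleSize <- as.numeric(nSeq)
        vals <- rdiValues(.calcRDI(counts, simParams))
        pIdx <- seq_len(nPerturb)
        bIdx <- nPerturb + seq_len(nBaseline)
        meanRDI <- rowMeans(vals[pIdx, bIdx, drop = FALSE])
        nullVals <- vals[bIdx, bIdx][upper.tri(diag(nBaseline))]
        .fitCalibration(devs, meanRDI, nullVals, units,
            settings = list(nFeatures = nFeatures, nSeq = nSeq,
                transform = params@transform,
                distanceMode = params@distanceMode,
                normConstant = params@normConstant,
                nIterations = params@nIterations))
    })
}

# Fit spline + isotonic projection + rolling residual SD from
# (deviation, mean RDI) points. The baseline-vs-baseline values are
# deviation-0 observations of the same quantity, so their mean enters the
# fit as an anchor point at 0 weighted by the null sample size; without it a
# natural cubic spline shows boundary bias at the elbow where the curve
# leaves the null floor.
.fitCalibration <- function(devs, meanRDI, nullVals, units, settings) {
    ord <- order(devs)
    devs <- devs[ord]
    meanRDI <- meanRDI[ord]
    if (length(nullVals))
        fit <- smooth.spline(c(0, devs), c(mean(nullVals), meanRDI),
            w = c(length(nullVals), rep(1, length(devs))))
    else
        fit <- smooth.spline(devs, meanRDI)
    grid <- seq(0, max(devs), length.out = .GRID_N)
    pred <- predict(fit, grid)$y
    mono <- isoreg(grid, pred)$yf
    if (max(mono) - min(mono) < 1e-8)
        stop("calibration failure: fitted spline is flat; ",
             "increase nPerturb or the simulated depth")
    fitted_at <- approx(grid, mono, xout = devs, rule = 2)$y
    res <- meanRDI - fitted_at
    n <- length(devs)
    w <- max(20L, ceiling(0.1 * n))
    w <- min(w, n)
    centers <- seq(1L, n - w + 1L)
    sdDev <- vapply(centers, function(i) mean(devs[i:(i + w - 1L)]),
        numeric(1L))
    sdVal <- vapply(centers, function(i) sd(res[i:(i + w - 1L)]),
        numeric(1L))
    sdVal[!is.finite(sdVal) | sdVal <= 0] <- max(sdVal[is.finite(sdVal)],
        1e-12)
    new("RDICalibration",
        points = data.frame(deviation = devs, mean_rdi = meanRDI),
        grid = grid, fitted = mono,
        sdCenters = data.frame(deviation = sdDev, sd = sdVal),
        units = units, settings = settings, nullSample = nullVals)
}

#' Evaluate the fitted calibration spline
#'
#' The expected RDI at a given true average deviation, from the monotonized
#' spline (linear interpolation on the fitted grid).
#'
#' @param model an \code{\linkS4class{RDICalibration}}.
#' @param deviation numeric vector of deviations within the fitted range.
#' @return expected RDI values.
#' @export
predictRDI <- function(model, deviation) {
    if (any(deviation < 0 | deviation > max(model@grid)))
        stop("deviation outside the fitted range [0, ",
             format(max(model@grid), digits = 4), "]")
    approx(model@grid, model@fitted, xout = deviation, rule = 2)$y
}

# local residual SD, linearly interpolated between window centers
.residualSd <- function(model, deviation) {
    approx(model@sdCenters$deviation, model@sdCenters$sd, xout = deviation,
        rule = 2)$y
}

#' Convert observed RDI values into average fold/percent change
#'
#' Numerically inverts the monotone calibration spline. Values at or below
#' the spline's level at deviation 0 (the null level) are clamped to 0 — no
#' detectable change; values above the fitted range are clamped to the
#' maximum fitted deviation with a warning. The result carries a
#' \code{"clamp"} attribute (\code{"none"}, \code{"low"} or \code{"high"}
#' per value).
#'
#' @param model an \code{\linkS4class{RDICalibration}}.
#' @param rdi non-negative numeric vector of RDI values, computed with the
#'   same settings the model was built for.
#' @param checkSettings optional named list of the settings the values were
#'   computed with (as in \code{calibrationSettings(model)}); mismatches
#'   raise an error.
#' @return estimated deviations in \code{deviationUnits(model)} with a
#'   \code{"clamp"} attribute.
#' @examples
#' rs <- simulatePerturbedSet(defaultBaseline(20), sigmas = rep(0.5, 4),
#'     nSeq = 500, nBaseline = 2, seed = 7)
#' cal <- buildCalibration(rs, RDIParams(nIterations = 10), nPerturb = 60,
#'     nBaseline = 5, seed = 7)
#' rdiToFold(cal, predictRDI(cal, 2))
#' @export
rdiToFold <- function(model, rdi, checkSettings = NULL) {
    if (any(rdi < 0)) stop("rdi values must be non-negative")
    if (!is.null(checkSettings)) {
        s <- model@settings
        common <- intersect(names(checkSettings), names(s))
        bad <- common[!vapply(common, function(k)
            isTRUE(all.equal(checkSettings[[k]], s[[k]])), logical(1L))]
        if (length(bad))
            stop("settings mismatch between model and RDI values: ",
                 paste(vapply(bad, function(k) sprintf("%s (%s vs %s)", k,
                     format(checkSettings[[k]]), format(s[[k]])),
                     character(1L)), collapse = ", "))
    }
    lo <- model@fitted[1L]
    hi <- model@fitted[length(model@fitted)]
    # strictly increasing branch for the inverse interpolation
    keep <- c(TRUE, diff(model@fitted) > 0)
    fx <- model@fitted[keep]
    gx <- model@grid[keep]
    est <- numeric(length(rdi))
    clamp <- rep("none", length(rdi))
    low <- rdi <= lo
    high <- rdi >= hi
    mid <- !low & !high
    est[low] <- 0
    clamp[low] <- "low"
    est[high] <- max(model@grid)
    clamp[high] <- "high"
    if (any(mid))
        est[mid] <- approx(fx, gx, xout = rdi[mid])$y
    if (any(high))
        warning(sum(high), " RDI value(s) above the fitted range; ",
                "clamped to deviation ", format(max(model@grid),
                digits = 4))
    attr(est, "clamp") <- clamp
    est
}

#' Build an RDI reference ladder
#'
#' Reads local mean and SD off the calibration model at a set of
#' pre-specified deviations, producing reference distributions for visual or
#' numeric comparison with observed RDI values (e.g. fold changes 1, 1.2 and
#' 1.5 correspond to log2 deviations 0, log2(1.2) and log2(1.5)).
#'
#' @param model an \code{\linkS4class{RDICalibration}}.
#' @param deviations strictly increasing deviations within the fitted range.
#' @return an \code{\linkS4class{RDILadder}}.
#' @examples
#' rs <- simulatePerturbedSet(defaultBaseline(20), sigmas = rep(0.5, 4),
#'     nSeq = 500, nBaseline = 2, seed = 7)
#' cal <- buildCalibration(rs, RDIParams(nIterations = 10), nPerturb = 60,
#'     nBaseline = 5, seed = 7)
#' makeLadder(cal, c(0, log2(1.2), log2(1.5)))
#' @export
makeLadder <- function(model, deviations) {
    if (!length(deviations))
        return(new("RDILadder",
            entries = data.frame(deviation = numeric(), mean_rdi = numeric(),
                sd_rdi = numeric()),
            units = model@units))
    if (is.unsorted(deviations, strictly = TRUE))
        stop("deviations must be strictly increasing")
    if (any(deviations < 0))
        stop("deviation below the fitted range (lower bound 0)")
    if (any(deviations > max(model@grid)))
        stop("deviation above the fitted range (upper bound ",
             format(max(model@grid), digits = 4), ")")
    new("RDILadder",
        entries = data.frame(
            deviation = deviations,
            mean_rdi = predictRDI(model, deviations),
            sd_rdi = .residualSd(model, deviations)),
        units = model@units)
}

#' Gaussian reference densities of a ladder
#'
#' Evaluates, for each ladder entry, the Normal(mean_rdi, sd_rdi^2) density
#' on a grid of RDI values — the approximate distribution of RDI scores for
#' repertoire pairs differing by that entry's deviation.
#'
#' @param ladder an \code{\linkS4class{RDILadder}}.
#' @param grid numeric vector of RDI values.
#' @return matrix with one row per grid point and one column per entry
#'   (columns named by deviation).
#' @export
ladderDensity <- function(ladder, grid) {
    e <- ladderEntries(ladder)
    out <- vapply(seq_len(nrow(e)), function(i)
        dnorm(grid, e$mean_rdi[i], e$sd_rdi[i]), numeric(length(grid)))
    out <- matrix(out, nrow = length(grid),
        dimnames = list(NULL, format(e$deviation, digits = 4)))
    out
}

#' Empirical tail probability of an observed RDI under the null
#'
#' Fraction of the model's stored baseline-vs-baseline (deviation-0) RDI
#' sample at or above the observed value, with add-one smoothing:
#' \code{(#\{null >= observed\} + 1) / (n + 1)}. Values near 1 mean the
#' observed distance is consistent with no difference; the floor is
#' \code{1/(n+1)}.
#'
#' @param model an \code{\linkS4class{RDICalibration}} with a non-empty null
#'   sample.
#' @param observed numeric vector of observed RDI values (same settings as
#'   the model).
#' @return numeric vector of tail fractions in (0, 1].
#' @export
nullTailFraction <- function(model, observed) {
    nul <- model@nullSample
    if (!length(nul))
        stop("model carries no null sample")
    vapply(observed, function(o) (sum(nul >= o) + 1) / (length(nul) + 1),
        numeric(1L))
}

#' Persist and restore a calibration model as JSON
#'
#' Everything needed to reproduce conversions is written: the fitted points,
#' the monotone spline grid, the residual-SD centers, the units, the
#' settings and the null sample.
#'
#' @param model an \code{\linkS4class{RDICalibration}}.
#' @param path JSON file path.
#' @return \code{writeCalibration} returns \code{path} invisibly;
#'   \code{readCalibration} the reconstructed model.
#' @export
writeCalibration <- function(model, path) {
    obj <- list(
        units = model@units,
        settings = model@settings,
        points = model@points,
        grid = model@grid,
        fitted = model@fitted,
        sd_centers = model@sdCenters,
        null_sample = model@nullSample)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
    if (!file.exists(path)) stop("input file not found: ", path)
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("RDICalibration",
        points = as.data.frame(obj$points),
        grid = as.numeric(obj$grid),
        fitted = as.numeric(obj$fitted),
        sdCenters = as.data.frame(obj$sd_centers),
        units = obj$units,
        settings = as.list(obj$settings),
        nullSample = as.numeric(obj$null_sample))
}

#' Write a ladder as CSV
#'
#' @param ladder an \code{\linkS4class{RDILadder}}.
#' @param path output CSV path (columns deviation, mean_rdi, sd_rdi).
#' @return \code{path}, invisibly.
#' @export
writeLadder <- function(ladder, path) {
    write.table(ladderEntries(ladder), path, sep = ",", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}
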