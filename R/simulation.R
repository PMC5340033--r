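# Synthetic repertoires with exactly known ground truth: a baseline
# gene-probability vector is perturbed on the log2 scale, renormalized, and
# multinomial datasets are drawn from it. The realized average deviation of
# every perturbed vector is recorded, so simulated sets carry their own
# answer key.

.checkProb <- function(p, what = "probability vector") {
    if (!is.numeric(p) || !length(p))
        stop(what, " must be a non-empty numeric vector")
    if (any(p < 0)) stop(what, " must be non-negative")
    if (abs(sum(p) - 1) > 1e-12)
        stop(what, " must sum to 1 (got ", format(sum(p)), ")")
    invisible(p)
}

#' Default baseline gene-probability vector
#'
#' A geometric-decay probability vector (entry \eqn{i} proportional to
#' \code{decay^(i-1)}) standing in for the skewed gene-segment usage seen in
#' real heavy-chain and TCR repertoires: a few prevalent segments and a long
#' tail of rare ones spanning orders of magnitude. The default of 50 features
#' matches the size of a typical V-gene pool.
#'
#' @param nFeatures number of gene segments.
#' @param decay geometric decay rate in (0, 1]; 1 gives a uniform vector.
#' @return named probability vector (names \code{TRBV1-1}, \code{TRBV2-1},
#'   ... so fixtures can exercise call collapsing).
#' @examples
#' p <- defaultBaseline(50)
#' sum(p)
#' @export
defaultBaseline <- function(nFeatures = 50, decay = 0.9) {
    stopifnot(nFeatures >= 1, decay > 0, decay <= 1)
    p <- decay^(seq_len(nFeatures) - 1)
    p <- p / sum(p)
    names(p) <- sprintf("TRBV%d-1", seq_len(nFeatures))
    p
}

#' Baseline probability vector from observed counts
#'
#' Averages the per-repertoire frequency vectors of a count table elementwise
#' and renormalizes, giving the baseline from which calibration simulations
#' are drawn (each repertoire contributes equally, regardless of depth).
#'
#' @param x a \code{\linkS4class{RepertoireCounts}} object.
#' @return named probability vector over the table's features.
#' @examples
#' m <- rbind(a = c(1, 1), b = c(3, 1))
#' colnames(m) <- c("V1", "V2")
#' baselineFromCounts(RepertoireCounts(m, repertoiresAsRows = TRUE))
#' @export
baselineFromCounts <- function(x) {
    counts <- featureCounts(x)
    tot <- colSums(counts)
    if (!ncol(counts) || all(tot == 0))
        stop("count table has no repertoire with positive total")
    freqs <- sweep(counts[, tot > 0, drop = FALSE], 2, tot[tot > 0], "/")
    p <- rowMeans(freqs)
    p / sum(p)
}

#' Draw a random log2-scale perturbation vector
#'
#' Independent Normal(0, sigma^2) offsets, one per feature, to be added to
#' the baseline on the log2 scale. \code{sigma = 0} gives the zero vector
#' (no perturbation).
#'
#' @param nFeatures number of features.
#' @param sigma standard deviation of the offsets on the log2 scale.
#' @return numeric vector of length \code{nFeatures}.
#' @examples
#' set.seed(1)
#' samplePerturbation(5, 1)
#' @export
samplePerturbation <- function(nFeatures, sigma) {
    stopifnot(nFeatures >= 1, sigma >= 0)
    if (sigma == 0) return(numeric(nFeatures))
    rnorm(nFeatures, 0, sigma)
}

#' Perturb a baseline probability vector on the log2 scale
#'
#' Computes the perturbed vector \eqn{2^{(\log_2 p + r)}} elementwise — i.e.
#' \eqn{p_i 2^{r_i}} — and renormalizes it to sum to 1. Features with zero
#' baseline probability stay at zero. Adding a constant to every entry of
#' \code{r} only rescales the unnormalized vector, so the result is invariant
#' to such shifts.
#'
#' @param pBase baseline probability vector.
#' @param r log2-scale perturbation vector of the same length.
#' @return perturbed probability vector (names carried over).
#' @examples
#' perturbProbabilities(c(0.5, 0.5), c(1, -1))  # 0.8, 0.2
#' @export
perturbProbabilities <- function(pBase, r) {
    .checkProb(pBase, "pBase")
    if (length(r) != length(pBase))
        stop("r must have the same length as pBase")
    if (any(!is.finite(r))) stop("r must be finite")
    p <- pBase * 2^r
    p / sum(p)
}

#' True average deviation between a perturbed and a baseline vector
#'
#' The ground-truth effect size a simulated dataset embodies: the mean over
#' features of the absolute log2 fold change (for the ArcSinh-transformed
#' RDI) or of the absolute percent change (for the untransformed RDI),
#' computed on the renormalized perturbed vector. Features at zero in both
#' vectors are excluded from the average; a feature that is zero in the
#' baseline but positive in the perturbed vector has no defined fold change
#' and raises an error.
#'
#' @param pFc perturbed (renormalized) probability vector.
#' @param pBase baseline probability vector of the same length.
#' @param units \code{"log2fc"} or \code{"pct_change"}.
#' @return a single non-negative number.
#' @examples
#' trueDeviation(c(0.8, 0.2), c(0.5, 0.5), "log2fc")      # 1
#' trueDeviation(c(0.8, 0.2), c(0.5, 0.5), "pct_change")  # 60
#' @export
trueDeviation <- function(pFc, pBase, units = c("log2fc", "pct_change")) {
    units <- match.arg(units)
    .checkProb(pFc, "pFc")
    .checkProb(pBase, "pBase")
    if (length(pFc) != length(pBase))
        stop("pFc and pBase must have equal length")
    if (any(pBase == 0 & pFc > 0))
        stop("feature with zero baseline probability but positive ",
             "perturbed probability: fold change undefined")
    keep <- pBase > 0
    pFc <- pFc[keep]
    pBase <- pBase[keep]
    if (units == "log2fc")
        mean(abs(log2(pFc / pBase)))
    else
        mean(100 * abs(pFc - pBase) / pBase)
}

#' Scale a random perturbation to hit an exact realized deviation
#'
#' Draws an iid Normal shape vector and rescales it by a single factor
#' (found by root-finding) so that the REALIZED average absolute log2 fold
#' change of the renormalized perturbed vector equals \code{deviation}
#' exactly. Because renormalization shifts every log2 ratio by a common
#' constant, the realized deviation of \code{sigma * r} is not simply
#' proportional to \code{sigma}; targeting the realized value removes that
#' slack.
#'
#' @param pBase baseline probability vector (all entries positive where the
#'   perturbation applies).
#' @param deviation target average absolute log2 fold change (>= 0).
#' @return a perturbation vector \code{r} such that
#'   \code{trueDeviation(perturbProbabilities(pBase, r), pBase, "log2fc")}
#'   equals \code{deviation} to root-finding tolerance.
#' @examples
#' set.seed(1)
#' r <- perturbationAtDeviation(defaultBaseline(20), 2)
#' trueDeviation(perturbProbabilities(defaultBaseline(20), r),
#'     defaultBaseline(20))
#' @export
perturbationAtDeviation <- function(pBase, deviation) {
    .checkProb(pBase, "pBase")
    stopifnot(deviation >= 0)
    n <- length(pBase)
    if (deviation == 0) return(numeric(n))
    shape <- rnorm(n)
    dev <- function(s)
        trueDeviation(perturbProbabilities(pBase, s * shape), pBase, "log2fc")
    upper <- 1
    while (dev(upper) < deviation && upper < 1e4) upper <- upper * 2
    s <- uniroot(function(s) dev(s) - deviation, c(0, upper),
        tol = .Machine$double.eps^0.5)$root
    s * shape
}

#' Draw a multinomial repertoire from a probability vector
#'
#' @param p probability vector over features.
#' @param n number of sequences to draw.
#' @return integer count vector summing to \code{n} (names carried over).
#' @examples
#' set.seed(1)
#' drawRepertoire(c(0.5, 0.5), 10)
#' @export
drawRepertoire <- function(p, n) {
    .checkProb(p)
    stopifnot(length(n) == 1L, n >= 1, n == floor(n))
    out <- as.integer(rmultinom(1L, n, p)[, 1L])
    names(out) <- names(p)
    out
}

#' Simulate a set of perturbed and baseline repertoires with known truth
#'
#' For each entry of \code{sigmas}, one perturbation vector is drawn at that
#' log2-scale SD, the baseline is perturbed and renormalized, the realized
#' deviation is recorded in both units, and one repertoire of \code{nSeq}
#' sequences is drawn from the perturbed vector. \code{nBaseline} additional
#' repertoires are drawn from the unperturbed baseline (truth 0).
#'
#' @param pBase baseline probability vector.
#' @param sigmas numeric vector of perturbation SDs, one perturbed repertoire
#'   each.
#' @param nSeq sequences per repertoire.
#' @param nBaseline number of baseline repertoires.
#' @param seed optional integer for a private, reproducible RNG stream.
#' @return a \code{\linkS4class{RepertoireCounts}} whose \code{colData}
#'   records \code{role} (\code{"perturbed"}/\code{"baseline"}),
#'   \code{true_log2fc} and \code{true_pct_change}, and whose metadata stores
#'   the baseline vector; see \code{\link{repertoireTruth}}.
#' @examples
#' rs <- simulatePerturbedSet(defaultBaseline(20), sigmas = c(0, 0.5, 1),
#'     nSeq = 500, nBaseline = 3, seed = 42)
#' repertoireTruth(rs)
#' @export
simulatePerturbedSet <- function(pBase, sigmas, nSeq, nBaseline = 1,
                                 seed = NULL) {
    .checkProb(pBase, "pBase")
    stopifnot(length(sigmas) >= 1, all(sigmas >= 0), nSeq >= 1,
              nBaseline >= 1)
    if (is.null(names(pBase)))
        names(pBase) <- sprintf("F%02d", seq_along(pBase))
    .withSeed(seed, {
        nP <- length(sigmas)
        counts <- matrix(0L, length(pBase), nP + nBaseline)
        l2 <- pct <- numeric(nP + nBaseline)
        for (j in seq_len(nP)) {
            r <- samplePerturbation(length(pBase), sigmas[j])
            pFc <- perturbProbabilities(pBase, r)
            l2[j] <- trueDeviation(pFc, pBase, "log2fc")
            pct[j] <- trueDeviation(pFc, pBase, "pct_change")
            counts[, j] <- drawRepertoire(pFc, nSeq)
        }
        for (j in seq_len(nBaseline))
            counts[, nP + j] <- drawRepertoire(pBase, nSeq)
        dimnames(counts) <- list(names(pBase),
            c(sprintf("perturbed_%02d", seq_len(nP)),
              sprintf("baseline_%02d", seq_len(nBaseline))))
        cd <- S4Vectors::DataFrame(
            role = rep(c("perturbed", "baseline"), c(nP, nBaseline)),
            true_log2fc = l2, true_pct_change = pct,
            row.names = colnames(counts))
        out <- RepertoireCounts(counts, featureName = "v_gene",
            colData = cd)
        S4Vectors::metadata(out)$baseline <- pBase
        out
    })
}

#' Randomly split one repertoire into two complementary halves
#'
#' Assigns every pooled element of \code{counts} to one of two groups: the
#' first is a without-replacement subsample of size \code{mSmall}, the second
#' is the elementwise remainder. The two halves come from one population, so
#' their RDI is a draw from the metric's null distribution at subsample depth
#' \code{mSmall} — the empirical analogue of a deviation-0 simulation.
#'
#' @param counts non-negative integer count vector.
#' @param mSmall size of the smaller half; must be below \code{sum(counts)}.
#' @return list with elements \code{small} and \code{large}, integer vectors
#'   summing elementwise to \code{counts}.
#' @examples
#' set.seed(1)
#' nullSplit(c(10, 10), 5)
#' @export
nullSplit <- function(counts, mSmall) {
    if (mSmall >= sum(counts))
        stop("mSmall (", mSmall, ") must be below the total count (",
             sum(counts), ")")
    small <- subsampleCounts(counts, mSmall)
    list(small = small, large = as.integer(round(counts)) - small)
}

#' Write the ground-truth table of a simulated set
#'
#' @param x a simulated \code{\linkS4class{RepertoireCounts}}.
#' @param path output CSV path (columns repertoire_id, true_log2fc,
#'   true_pct_change).
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(x, path) {
    tr <- repertoireTruth(x)
    if (is.null(tr))
        stop("object carries no ground-truth annotations")
    write.table(tr, path, sep = ",", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Expand a count table into an AIRR-style rearrangement TSV
#'
#' Writes one row per sequence with a synthetic allele-level gene call
#' (feature label plus \code{*01}), producing a file that exercises the full
#' read/collapse/tabulate path end to end. Intended for small fixtures.
#'
#' @param x a \code{\linkS4class{RepertoireCounts}}.
#' @param path output TSV path.
#' @param featureColumn name of the gene-call column to write.
#' @return \code{path}, invisibly.
#' @export
airrFromCounts <- function(x, path, featureColumn = "v_call") {
    counts <- featureCounts(x)
    ids <- rep(rep(colnames(counts), each = nrow(counts)), as.vector(counts))
    calls <- rep(rep.int(paste0(rownames(counts), "*01"), ncol(counts)),
                 as.vector(counts))
    df <- data.frame(repertoire_id = ids, call = calls)
    names(df)[2L] <- featureColumn
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
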