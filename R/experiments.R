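# Reusable synthetic experiment: does a pairwise distance matrix depend on
# the original sizes of the repertoires it compares?

#' Permutation test for sequencing-depth dependence of a distance matrix
#'
#' Regresses the pairwise distances on the smaller member's original
#' repertoire size and assesses the slope by a Mantel-style permutation of
#' repertoire labels (pairwise distances are not independent, so ordinary
#' regression p-values would be anticonservative). A naive Euclidean
#' distance on raw per-repertoire frequencies shows a significantly negative
#' slope — small repertoires look artificially distant — while the
#' subsampled RDI should show none.
#'
#' @param d symmetric distance matrix (or \code{\linkS4class{RDIMatrix}}).
#' @param sizes original per-repertoire totals, in matrix order.
#' @param nPermutations number of label permutations.
#' @return list with \code{slope} (OLS estimate of distance on the pair's
#'   smaller size) and \code{p.value} (two-sided permutation p).
#' @examples
#' set.seed(1)
#' p <- defaultBaseline(20)
#' sizes <- round(runif(12, 500, 3000))
#' counts <- t(sapply(sizes, function(n) drawRepertoire(p, n)))
#' rownames(counts) <- paste0("r", seq_along(sizes))
#' rdi <- calcRDI(counts, RDIParams(nIterations = 10), seed = 2)
#' sizeDependenceTest(rdi, sizes, nPermutations = 99)
#' @export
sizeDependenceTest <- function(d, sizes, nPermutations = 999) {
    if (is(d, "RDIMatrix")) d <- rdiValues(d)
    stopifnot(nrow(d) == length(sizes), nPermutations >= 1)
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    y <- d[pairs]
    slopeFor <- function(sz) {
        x <- pmin(sz[pairs[, 1L]], sz[pairs[, 2L]])
        stats::coef(stats::lm(y ~ x))[[2L]]
    }
    obs <- slopeFor(sizes)
    perm <- replicate(nPermutations, slopeFor(sample(sizes)))
    list(slope = obs,
         p.value = (sum(abs(perm) >= abs(obs)) + 1) / (nPermutations + 1))
}
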