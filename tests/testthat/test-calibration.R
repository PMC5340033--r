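# small-but-real calibration shared across tests in this file
.calFixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            rs <- simulatePerturbedSet(defaultBaseline(30),
                sigmas = rep(0.5, 4), nSeq = 1000, nBaseline = 2, seed = 18)
            cache <<- buildCalibration(rs, RDIParams(),
                nPerturb = 150, nBaseline = 10, maxLog2fc = 8, seed = 18)
        }
        cache
    }
})

# local SD read off the model through the ladder surface
.residualSdForTest <- function(cal, dev)
    ladderEntries(makeLadder(cal, dev))$sd_rdi

test_that("the calibration spline is monotone and anchored at the null", {
    cal <- .calFixture()
    expect_s4_class(cal, "RDICalibration")
    expect_true(all(diff(cal@fitted) >= -1e-9))
    expect_equal(deviationUnits(cal), "log2fc")

    s <- calibrationSettings(cal)
    expect_equal(s$nFeatures, 30)
    expect_equal(s$nSeq, 1000)
    expect_equal(s$transform, "asinh")

    # spline at deviation 0 sits near the baseline-vs-baseline RDI level
    nullVals <- nullSample(cal)
    expect_equal(length(nullVals), 10 * 9 / 2)
    band <- 2 * .residualSdForTest(cal, 0)
    expect_lt(abs(predictRDI(cal, 0) - mean(nullVals)), band)
})

test_that("a scaled-down calibration on a 50-feature table stays monotone", {
    rs <- simulatePerturbedSet(defaultBaseline(50), sigmas = rep(0.5, 3),
        nSeq = 2000, nBaseline = 2, seed = 77)
    cal <- buildCalibration(rs, RDIParams(), nPerturb = 100,
        nBaseline = 5, seed = 77)
    expect_true(all(diff(cal@fitted) >= -1e-9))
    expect_gt(max(cal@fitted), min(cal@fitted))
})

test_that("rdiToFold inverts the forward spline and clamps at the edges", {
    cal <- .calFixture()
    # inverse-of-forward identity on the fitted interior
    for (d in c(0.5, 1, 2, 4, 6))
        expect_equal(as.numeric(rdiToFold(cal, predictRDI(cal, d))), d,
            tolerance = 1e-6)
    # at or below the null level: clamp to zero
    lowest <- rdiToFold(cal, predictRDI(cal, 0))
    expect_equal(as.numeric(lowest), 0)
    expect_equal(attr(lowest, "clamp"), "low")
    expect_equal(as.numeric(rdiToFold(cal, 0)), 0)
    # above the fitted range: clamp to the maximum with a warning
    expect_warning(high <- rdiToFold(cal, max(cal@fitted) * 2),
        "clamped")
    expect_equal(as.numeric(high), max(cal@grid))
    expect_equal(attr(high, "clamp"), "high")
})

test_that("rdiToFold rejects values from mismatched settings", {
    cal <- .calFixture()
    expect_error(
        rdiToFold(cal, 1, checkSettings = list(transform = "none")),
        "settings mismatch")
    expect_silent(
        rdiToFold(cal, predictRDI(cal, 1),
            checkSettings = list(transform = "asinh", nSeq = 1000)))
})

test_that("ladders carry increasing means and positive SDs", {
    cal <- .calFixture()
    lad <- makeLadder(cal, c(0, log2(1.2), log2(1.5)))
    e <- ladderEntries(lad)
    expect_equal(nrow(e), 3L)
    expect_true(all(diff(e$mean_rdi) > 0))
    expect_true(all(e$sd_rdi > 0))

    empty <- makeLadder(cal, numeric())
    expect_equal(nrow(ladderEntries(empty)), 0L)

    expect_error(makeLadder(cal, c(0, 9)), "above the fitted range")
    expect_error(makeLadder(cal, c(1, 0.5)), "strictly increasing")
})

test_that("ladder densities are Gaussian and integrate to one", {
    cal <- .calFixture()
    lad <- makeLadder(cal, c(0, 2))
    e <- ladderEntries(lad)
    grid <- seq(e$mean_rdi[1] - 6 * e$sd_rdi[1],
        e$mean_rdi[2] + 6 * e$sd_rdi[2], length.out = 4000)
    dens <- ladderDensity(lad, grid)
    expect_equal(dim(dens), c(4000L, 2L))
    # peak height 1/(sd * sqrt(2*pi))
    expect_equal(max(dens[, 1]), 1 / (e$sd_rdi[1] * sqrt(2 * pi)),
        tolerance = 1e-3)
    # trapezoid integral ~ 1
    h <- diff(grid[1:2])
    for (k in 1:2) {
        integral <- h * (sum(dens[, k]) - (dens[1, k] + dens[4000, k]) / 2)
        expect_equal(unname(integral), 1, tolerance = 1e-3)
    }
    # symmetry about the mean
    g2 <- seq(-3, 3, length.out = 11) * e$sd_rdi[1] + e$mean_rdi[1]
    d2 <- ladderDensity(lad, g2)[, 1]
    expect_equal(d2, rev(d2))
})

test_that("nullTailFraction follows the order statistics of the null", {
    cal <- .calFixture()
    nul <- nullSample(cal)
    n <- length(nul)
    expect_equal(nullTailFraction(cal, min(nul) - 10), 1)
    expect_equal(nullTailFraction(cal, max(nul) + 10), 1 / (n + 1))
    med <- median(nul)
    expect_equal(nullTailFraction(cal, med), 0.5, tolerance = 0.15)
})

test_that("recovery bias stays small across depths and feature counts", {
    set.seed(91)
    for (cfg in list(c(500, 20), c(500, 50), c(2000, 20))) {
        nSeq <- cfg[1]; nf <- cfg[2]
        p <- defaultBaseline(nf)
        tab <- simulatePerturbedSet(p, sigmas = rep(0.4, 3), nSeq = nSeq,
            nBaseline = 2, seed = 91 + nf)
        cal <- buildCalibration(tab, RDIParams(), nPerturb = 150,
            nBaseline = 15, seed = 92 + nSeq)
        pB <- baselineFromCounts(tab)
        for (d in c(0.5, 1, 2, 4)) {
            ests <- replicate(50, {
                pfc <- perturbProbabilities(pB,
                    perturbationAtDeviation(pB, d))
                m <- cbind(drawRepertoire(pfc, nSeq),
                           vapply(1:4, function(i) drawRepertoire(pB, nSeq),
                                  integer(nf)))
                colnames(m) <- c("pert", paste0("b", 1:4))
                v <- rdiValues(calcRDI(t(m)))
                suppressWarnings(
                    as.numeric(rdiToFold(cal, mean(v["pert", -1]))))
            })
            expect_lt(abs(mean(ests) - d), 0.25 * d,
                label = sprintf("bias at nSeq=%d nf=%d d=%g", nSeq, nf, d))
        }
    }
})

test_that("calibration models survive a JSON round trip", {
    cal <- .calFixture()
    path <- tempfile(fileext = ".json")
    writeCalibration(cal, path)
    back <- readCalibration(path)
    expect_equal(back@grid, cal@grid)
    expect_equal(back@fitted, cal@fitted)
    expect_equal(nullSample(back), nullSample(cal))
    expect_equal(calibrationSettings(back)$nSeq,
        calibrationSettings(cal)$nSeq)
    for (d in c(0.5, 2))
        expect_equal(as.numeric(rdiToFold(back, predictRDI(back, d))), d,
            tolerance = 1e-6)
})
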