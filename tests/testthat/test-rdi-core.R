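test_that("subsampling draws without replacement from the pooled elements", {
    # full draw is the identity; empty draw is zero
    expect_equal(unname(subsampleCounts(c(3, 7), 10)), c(3L, 7L))
    expect_equal(unname(subsampleCounts(c(5, 0, 5), 0)), c(0L, 0L, 0L))
    expect_error(subsampleCounts(c(3, 7), 11), "exceeds")

    set.seed(402)
    draws <- replicate(10000, subsampleCounts(c(8, 2), 5)[1])
    expect_true(all(draws >= 3 & draws <= 5))      # support of Hyper(8,2,5)
    # hypergeometric mean m*K/N = 5*8/10 = 4; sd of the mean ~ 0.006
    expect_equal(mean(draws), 4, tolerance = 0.02)

    # each entry bounded by its original count, total exact
    set.seed(403)
    for (i in 1:20) {
        v <- rpois(8, 10)
        s <- subsampleCounts(v, 15)
        expect_equal(sum(s), 15L)
        expect_true(all(s <= v))
    }
})

test_that("normalization and transform follow their closed forms", {
    expect_equal(normalizeCounts(c(1, 1, 2), 500), c(125, 125, 250))
    expect_equal(normalizeCounts(c(500, 0), 500), c(500, 0))
    expect_equal(normalizeCounts(c(3, 3, 3), 300), c(100, 100, 100))
    expect_error(normalizeCounts(c(0, 0), 500), "non-positive")

    expect_equal(transformCounts(c(0, 0), "asinh"), c(0, 0))
    expect_equal(transformCounts(1, "asinh"), log(1 + sqrt(2)))
    expect_equal(transformCounts(c(5, 2), "none"), c(5, 2))
})

test_that("vector distance matches brute-force sums in both modes", {
    expect_equal(vectorDistance(c(250, 0, 250), c(0, 250, 250)),
        sqrt(2 * 250^2))
    expect_equal(vectorDistance(c(3, 4), c(0, 0), "rmsd"), 5 / sqrt(2))
    v <- c(1.5, 2.5, 9)
    expect_equal(vectorDistance(v, v), 0)
    expect_error(vectorDistance(1:3, 1:4), "equal length")

    set.seed(9)
    for (i in 1:10) {
        a <- runif(5) * 100
        b <- runif(5) * 100
        expect_equal(vectorDistance(a, b), sqrt(sum((a - b)^2)),
            tolerance = 1e-9)
        expect_equal(vectorDistance(a, b, "rmsd"),
            sqrt(sum((a - b)^2) / 5), tolerance = 1e-9)
        expect_equal(vectorDistance(a, b), vectorDistance(b, a))
    }
})

test_that("calcRDI reproduces closed-form values on degenerate tables", {
    # both repertoires concentrated on one shared feature: RDI is 0
    m <- rbind(a = c(20L, 0L), b = c(20L, 0L))
    colnames(m) <- c("V1", "V2")
    expect_equal(max(rdiValues(calcRDI(m, seed = 1))), 0)

    oh <- oneHotCounts()
    r <- calcRDI(oh, RDIParams(transform = "none"), seed = 1)
    expect_equal(rdiValues(r)[1, 2], sqrt(2) * 500, tolerance = 1e-9)
    r2 <- calcRDI(oh, RDIParams(), seed = 1)
    expect_equal(rdiValues(r2)[1, 2], sqrt(2) * asinh(500),
        tolerance = 1e-9)
    # rmsd mode divides by sqrt(k)
    r3 <- calcRDI(oh, RDIParams(transform = "none", distanceMode = "rmsd"),
        seed = 1)
    expect_equal(rdiValues(r3)[1, 2], sqrt(2) * 500 / sqrt(2),
        tolerance = 1e-9)
})

test_that("calcRDI equals the hand-composed pipeline for one iteration", {
    set.seed(31)
    counts <- matrix(rpois(3 * 6, 30) + 1L, nrow = 3,
        dimnames = list(paste0("r", 1:3), paste0("V", 1:6)))
    params <- RDIParams(nIterations = 1, subsampleSize = 50)
    got <- rdiValues(calcRDI(counts, params, seed = 99))

    # oracle: replay the identical RNG stream through the exported steps
    set.seed(99)
    sub <- apply(counts, 1, function(v) subsampleCounts(v, 50))  # 6 x 3
    prof <- apply(sub, 2, function(v)
        transformCounts(normalizeCounts(v, 500), "asinh"))
    want <- matrix(0, 3, 3, dimnames = list(rownames(counts),
        rownames(counts)))
    for (i in 1:3) for (j in 1:3) if (i != j)
        want[i, j] <- vectorDistance(prof[, i], prof[, j])
    expect_equal(got, want, tolerance = 1e-9)
})

test_that("RDI matrices are symmetric, non-negative and seed-deterministic", {
    set.seed(77)
    counts <- matrix(rpois(4 * 10, 40) + 1L, nrow = 4,
        dimnames = list(paste0("r", 1:4), paste0("V", 1:10)))
    params <- RDIParams(nIterations = 20)
    a <- calcRDI(counts, params, seed = 5)
    b <- calcRDI(counts, params, seed = 5)
    expect_identical(rdiValues(a), rdiValues(b))
    v <- rdiValues(a)
    expect_true(all(v >= 0))
    expect_equal(v, t(v))
    expect_equal(diag(v), setNames(rep(0, 4), rownames(counts)))
    expect_equal(resolvedSubsampleSize(a), min(rowSums(counts)))

    # a seeded call must not disturb the caller's RNG stream
    set.seed(123); before <- rnorm(1)
    set.seed(123); invisible(calcRDI(counts, params, seed = 5))
    expect_identical(rnorm(1), before)
})

test_that("calcRDI rejects degenerate input", {
    m <- rbind(a = c(0L, 0L), b = c(5L, 5L))
    colnames(m) <- c("V1", "V2")
    expect_error(calcRDI(m), "a")
    m2 <- rbind(a = c(3L, 2L), b = c(5L, 5L))
    colnames(m2) <- c("V1", "V2")
    expect_error(calcRDI(m2, RDIParams(subsampleSize = 8)), "smallest")
    expect_error(calcRDI(m2[1, , drop = FALSE]), "at least 2")
})

test_that("shannonEntropy matches closed forms", {
    expect_equal(shannonEntropy(c(250, 250)), 1)
    expect_equal(shannonEntropy(c(10, 0, 0)), 0)
    expect_equal(shannonEntropy(c(1, 1, 1, 1)), 2)
    expect_equal(shannonEntropy(rep(3, 8)), 3)
    expect_error(shannonEntropy(c(0, 0)), "all-zero")
})

test_that("RDI matrices round-trip through CSV plus sidecar", {
    oh <- oneHotCounts()
    r <- calcRDI(oh, RDIParams(transform = "none", nIterations = 5),
        seed = 3)
    path <- tempfile(fileext = ".csv")
    writeRDIMatrix(r, path)
    expect_true(file.exists(paste0(path, ".json")))
    back <- readRDIMatrix(path)
    expect_equal(rdiValues(back), rdiValues(r))
    expect_equal(resolvedSubsampleSize(back), resolvedSubsampleSize(r))
    expect_equal(rdiParams(back)@transform, "none")
})
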