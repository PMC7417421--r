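mkIndices <- function(absP1, p2, ltr, tP1 = 20, tP2 = 40) {
    new("RecurrenceIndices", ltr = ltr, absP1 = absP1, p2 = p2,
        tP1 = tP1, tP2 = tP2,
        normP1 = if (ltr > 0) absP1 / ltr else NA_real_,
        normP2 = if (ltr > 0) p2 / ltr else NA_real_,
        nBlocks = 1L, nDegenerate = 0L)
}

test_that("index distance is the sum of absolute differences", {
    a <- mkIndices(0.3, 0.2, 0.06)
    b <- mkIndices(0.1, 0.2, 0.06)
    expect_equal(indexDistance(a, a), 0)
    expect_equal(indexDistance(a, b), 0.2)
    expect_equal(indexDistance(a, b), indexDistance(b, a))
    bad <- mkIndices(NA_real_, 0.2, 0.06)
    expect_error(indexDistance(a, bad), "finite")
})

test_that("a single-cell grid returns that cell", {
    set.seed(30)
    target <- subjectIndices(simulateAA(modelParams(nSamples = 2000L)))
    g <- fitGrid(dValues = 8, vValues = 0.3, fafOffsets = 0, nModels = 3L)
    fit <- fitSubject(target, fAF = 6.5, grid = g, nSamples = 1000L,
                      seed = 4L)
    expect_equal(fit@bestD, 8)
    expect_equal(fit@bestV, 0.3)
    expect_equal(fit@bestOffset, 0)
    expect_identical(dim(fit@scoreSurface), c(1L, 1L))
})

test_that("score surfaces are reproducible and grow monotonically", {
    set.seed(31)
    target <- subjectIndices(simulateAA(modelParams(nSamples = 2000L)))
    g <- fitGrid(dValues = c(7, 9), vValues = c(0.2, 0.3),
                 fafOffsets = 0, nModels = 3L)
    f1 <- fitSubject(target, fAF = 6.5, grid = g, nSamples = 1000L,
                     seed = 11L)
    f2 <- fitSubject(target, fAF = 6.5, grid = g, nSamples = 1000L,
                     seed = 11L)
    expect_identical(f1@scoreSurface, f2@scoreSurface)

    # widening the grid never worsens the best score (cell streams are
    # keyed by parameter values, so old cells rescore identically)
    wide <- fitGrid(dValues = c(5, 7, 9), vValues = c(0.2, 0.25, 0.3),
                    fafOffsets = 0, nModels = 3L)
    f3 <- fitSubject(target, fAF = 6.5, grid = wide, nSamples = 1000L,
                     seed = 11L)
    expect_lte(min(f3@scoreSurface, na.rm = TRUE),
               min(f1@scoreSurface, na.rm = TRUE))
    expect_equal(f3@scoreSurface[c("7", "9"), c("0.2", "0.3")],
                 f1@scoreSurface)
})

test_that("a noise-free target is recovered exactly", {
    # v = 0 collapses the model to a deterministic loop; with v = 0 in the
    # grid the fitted rate must be 0
    set.seed(32)
    target <- subjectIndices(simulateAA(modelParams(v = 0,
                                                    nSamples = 2000L)))
    g <- fitGrid(dValues = 8, vValues = c(0, 0.2, 0.4), fafOffsets = 0,
                 nModels = 4L)
    fit <- fitSubject(target, fAF = 6.5, grid = g, nSamples = 2000L,
                      seed = 5L)
    expect_equal(fit@bestV, 0)
})

test_that("more models per cell stabilise the score", {
    set.seed(33)
    target <- subjectIndices(simulateAA(modelParams(nSamples = 2000L)))
    scoreAt <- function(nModels, seed) {
        g <- fitGrid(dValues = 8, vValues = 0.3, fafOffsets = 0,
                     nModels = nModels)
        min(fitSubject(target, fAF = 6.5, grid = g, nSamples = 1000L,
                       seed = seed)@scoreSurface)
    }
    few <- vapply(1:8, function(s) scoreAt(3L, s), numeric(1))
    many <- vapply(1:8, function(s) scoreAt(24L, s), numeric(1))
    expect_lt(var(many), var(few))
})
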