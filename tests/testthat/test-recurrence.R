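test_that("blocks partition the sample axis into 2M-column pieces", {
    x <- matrix(rnorm(2 * 15360), 2)
    expect_length(partitionBlocks(x, M = 500), 15L)
    expect_true(all(vapply(partitionBlocks(x, M = 500), ncol, 0L) == 1000L))

    expect_length(partitionBlocks(matrix(1, 2, 1000), M = 500), 1L)
    expect_error(partitionBlocks(matrix(1, 2, 999), M = 500),
                 "too short")
    # trailing remainder discarded
    expect_length(partitionBlocks(matrix(1, 2, 1999), M = 500), 1L)
})

test_that("recurrence matrix is the cosine similarity at increasing lags", {
    # orthogonal / antiphase spatial vectors at known positions
    rot <- function(th) c(cos(th), sin(th))
    block <- sapply(seq(0, 5) * pi / 2, rot)  # 2 x 6, quarter turns
    R <- recurrenceMatrix(block)
    expect_equal(dim(R@values), c(3L, 3L))
    expect_equal(R@values[, 1L], rep(1, 3))          # lag 0
    expect_equal(R@values[1L, 2L], 0, tolerance = 1e-12)
    expect_equal(R@values[1L, 3L], -1, tolerance = 1e-12)

    # quadrature pair: R[i, j] = cos(omega (j - 1)) for every i
    b <- aaData(quadratureSet(8, 256, 200))
    R2 <- recurrenceMatrix(b)
    om <- 2 * pi * 8 / 256
    for (i in c(1L, 50L, 100L))
        expect_equal(R2@values[i, ], cos(om * (0:99)), tolerance = 1e-9)

    expect_error(recurrenceMatrix(cbind(c(0, 0), diag(2), c(1, 1))),
                 "degenerate sample vector")
})

test_that("recurrence signal equals brute-force per-lag cosine means", {
    set.seed(42)
    for (rep in 1:5) {
        block <- matrix(rnorm(3 * 40), 3)
        r <- recurrenceSignal(block)@r
        expect_equal(r, bruteRecurrence(block), tolerance = 1e-12)
        expect_equal(r, colMeans(recurrenceMatrix(block)@values),
                     tolerance = 1e-12)
        expect_equal(r[1], 1)
        expect_true(all(abs(r) <= 1 + 1e-9))
    }
})

test_that("quadrature tone yields the closed-form cosine recurrence", {
    r <- recurrenceSignals(quadratureSet(8, 256, 2000), M = 500)[[1]]@r
    expect_equal(r, cos(2 * pi * 8 * (0:499) / 256), tolerance = 1e-9)
    expect_equal(r[16 + 1], -1, tolerance = 1e-9)
    expect_equal(r[32 + 1], 1, tolerance = 1e-9)
})

test_that("recurrence is invariant to positive per-column rescaling", {
    set.seed(7)
    block <- matrix(rnorm(4 * 60), 4)
    scl <- runif(60, 0.1, 10)
    scaled <- block * rep(scl, each = 4)
    expect_equal(recurrenceMatrix(block)@values,
                 recurrenceMatrix(scaled)@values, tolerance = 1e-12)
    expect_equal(recurrenceSignal(block)@r, recurrenceSignal(scaled)@r,
                 tolerance = 1e-12)
})

test_that("short-term peaks find first minimum then first maximum", {
    # pure tone: t_P1 at half a period, t_P2 at a full period
    r <- cos(2 * pi * 8 * (0:499) / 256)
    pk <- shortTermPeaks(r)
    expect_true(pk$ok)
    expect_identical(pk$tP1, 16L)
    expect_identical(pk$tP2, 32L)
    expect_equal(pk$absP1, 1)
    expect_equal(pk$p2, 1)

    # strictly decreasing signal has no qualifying extrema
    expect_false(shortTermPeaks(seq(1, 0, length.out = 100))$ok)

    # plateaus resolve to their first lag
    rp <- c(1, 0.5, -0.2, -0.2, -0.2, 0.4, 0.9, 0.9, 0.3, 0.1)
    pk2 <- shortTermPeaks(rp)
    expect_identical(pk2$tP1, 2L)
    expect_identical(pk2$tP2, 6L)
    expect_equal(pk2$absP1, 0.2)
    expect_equal(pk2$p2, 0.9)
})

test_that("LTR averages absolute recurrence over the lag band and blocks", {
    expect_equal(ltrFromBlocks(list(rep(0.2, 501))), 0.2)
    expect_equal(ltrFromBlocks(list(rep(-0.3, 501))), 0.3)
    expect_equal(ltrFromBlocks(list(rep(0.2, 501), rep(0.4, 501))), 0.3)
    # many periods inside the band: mean |cos| approaches 2/pi
    r <- cos(2 * pi * 8 * (0:500) / 256)
    expect_equal(ltrFromBlocks(list(r)), 2 / pi, tolerance = 0.01)
    expect_error(ltrFromBlocks(list(rep(0.2, 450))), "too short")
})

test_that("subject indices aggregate blocks and normalise by LTR", {
    # identical blocks: subject indices equal block indices
    r <- cos(2 * pi * 8 * (0:499) / 256) * exp(-(0:499) / 800)
    rs <- new("RecurrenceSignal", r = r / r[1], blockIndex = 1L)
    idx1 <- subjectIndices(list(rs))
    idx2 <- subjectIndices(list(rs, rs, rs))
    for (s in c("ltr", "absP1", "p2", "tP1", "tP2", "normP1", "normP2"))
        expect_equal(slot(idx1, s), slot(idx2, s))
    pk <- shortTermPeaks(r)
    expect_equal(idx1@absP1, pk$absP1)
    expect_equal(idx1@normP1, idx1@absP1 / idx1@ltr)
    expect_equal(idx1@normP2, idx1@p2 / idx1@ltr)

    # degenerate blocks are excluded but error only when all are
    flat <- new("RecurrenceSignal",
                r = c(1, seq(0.9, 0.5, length.out = 500)), blockIndex = 2L)
    mixed <- subjectIndices(list(rs, flat))
    expect_identical(mixed@nDegenerate, 1L)
    expect_equal(mixed@absP1, idx1@absP1)
    expect_error(subjectIndices(list(flat)), "no indices computable")
})

test_that("recurrence properties hold on random multichannel signals", {
    set.seed(11)
    for (rep in 1:5) {
        x <- AASignalSet(matrix(rnorm(3 * 80), 3), fs = 100)
        r <- recurrenceSignals(x, M = 40)[[1]]@r
        expect_equal(r[1], 1)
        expect_true(all(abs(r) <= 1 + 1e-9))
    }
})

test_that("lead-map compression preserves recurrence exactly", {
    set.seed(13)
    src <- pseudoAA(modelParams(intrinsicDim = 5L, nLeads = 40L,
                                nSamples = 1200L))
    A <- randomLeadMap(40L, 5L)
    full <- recurrenceSignal(aaData(mapToLeads(src, 40L, leadMap = A)))
    comp <- recurrenceSignal(compressLeads(src, A))
    expect_equal(full@r, comp@r, tolerance = 1e-12)
})

test_that("faster phase wandering weakens long-term recurrence", {
    # median LTR over seeds is non-increasing in the rate v
    set.seed(17)
    vGrid <- seq(0.16, 0.32, by = 0.02)
    med <- vapply(vGrid, function(v) {
        ltrs <- vapply(1:40, function(s) {
            src <- pseudoAA(modelParams(d = 8, v = v, fAF = 6.5,
                                        nSamples = 8000L))
            x <- compressLeads(src, randomLeadMap(184L, 15L))
            subjectIndices(recurrenceSignals(x, M = 500))@ltr
        }, numeric(1L))
        median(ltrs)
    }, numeric(1L))
    expect_true(all(diff(med) <= 0))
})
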