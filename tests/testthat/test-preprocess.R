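tone <- function(f, fs = 256, N = 2048, amp = 1, dc = 0) {
    n <- 0:(N - 1)
    AASignalSet(rbind(amp * sin(2 * pi * f * n / fs) + dc,
                      amp * cos(2 * pi * f * n / fs) + dc), fs = fs)
}

# RMS of the central part of each lead (edge transients trimmed)
coreRms <- function(x, trim = 256L) {
    d <- aaData(x)[, (trim + 1L):(ncol(aaData(x)) - trim), drop = FALSE]
    sqrt(mean(d^2))
}

test_that("band-pass keeps the AF band and removes DC and drift", {
    # in-band 50 Hz tone preserved within (doubled) passband ripple
    x <- tone(50)
    expect_equal(coreRms(bandpassAA(x)) / coreRms(x), 1, tolerance = 0.15)
    # DC offset removed (central region, away from edge transients)
    xdc <- tone(8, dc = 5)
    expect_lt(abs(mean(aaData(bandpassAA(xdc))[, 257:1792])), 0.01)
    flat <- AASignalSet(matrix(5, 2, 2048), fs = 256)
    expect_lt(abs(mean(aaData(bandpassAA(flat)))), 0.01)
    # 0.2 Hz drift attenuated by more than 20 dB
    drift <- tone(0.2, N = 8192)
    expect_lt(coreRms(bandpassAA(drift), trim = 1024L) /
              coreRms(drift, trim = 1024L), 0.1)
    expect_error(bandpassAA(AASignalSet(matrix(1:20, 2), fs = 150)),
                 "sampling rate")
})

test_that("notch removes the power line and spares the AF band", {
    x50 <- tone(50)
    expect_lt(coreRms(notchAA(x50)) / coreRms(x50), 0.1)  # > 20 dB
    x65 <- tone(6.5)
    expect_equal(coreRms(notchAA(x65)) / coreRms(x65), 1,
                 tolerance = 0.01)
    # mixed tones: the 50 Hz component goes, the 6.5 Hz one stays
    mix <- AASignalSet(aaData(x50) + aaData(x65), fs = 256)
    res <- notchAA(mix)
    expect_equal(coreRms(res) / coreRms(x65), 1, tolerance = 0.05)
})

test_that("high-pass removes sub-AF residuals", {
    x1 <- tone(1, N = 8192)
    expect_lt(coreRms(highpassAA(x1), trim = 1024L) /
              coreRms(x1, trim = 1024L), 0.1)
    x65 <- tone(6.5)
    expect_equal(coreRms(highpassAA(x65)) / coreRms(x65), 1,
                 tolerance = 0.15)
    zero <- AASignalSet(matrix(0, 2, 1000), fs = 256)
    expect_equal(aaData(highpassAA(zero)),
                 matrix(0, 2, 1000), ignore_attr = TRUE)
})

test_that("the filter chain is zero-phase on in-band tones", {
    x <- tone(8, N = 4096)
    for (f in list(bandpassAA, notchAA, highpassAA, preprocessAA)) {
        y <- f(x)
        a <- aaData(x)[1, 1025:3072]
        b <- aaData(y)[1, 1025:3072]
        cc <- stats::ccf(a, b, lag.max = 20, plot = FALSE)
        expect_equal(as.vector(cc$lag)[which.max(cc$acf)], 0)
    }
})

test_that("dominant frequency finds tones on the Welch grid", {
    x <- tone(6, N = 2048)
    est <- dominantFrequency(x)
    expect_equal(est@fAF, 6, tolerance = 0.13)
    expect_false(est@edgeFlag)
    expect_true(est@reliable)
    expect_equal(est@perLeadF, rep(6, 2), tolerance = 0.13)

    # invariant to per-lead amplitude scaling
    scaled <- AASignalSet(aaData(x) * c(0.05, 40), fs = 256)
    expect_equal(dominantFrequency(scaled)@perLeadF, est@perLeadF)

    # out-of-band tone pushes the peak to a band edge
    expect_true(dominantFrequency(tone(1.5, N = 4096))@edgeFlag)
    expect_error(dominantFrequency(tone(6, N = 512)), "too short")
})

test_that("dominant frequency tracks the model and flags noise", {
    set.seed(21)
    ests <- replicate(5, {
        x <- simulateAA(modelParams(v = 0.16, fAF = 6.5,
                                    nSamples = 7680L, nLeads = 30L))
        dominantFrequency(x)@fAF
    })
    expect_true(all(abs(ests - 6.5) <= 0.5))

    noise <- AASignalSet(matrix(rnorm(4 * 7680), 4), fs = 256)
    expect_false(dominantFrequency(noise)@reliable)
})
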