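# Shared fixtures, built in code.

# Quadrature multichannel cosine: channel k is cos(2 pi f n / fs + (k-1) pi/2)
# so consecutive channels are 90 degrees apart; for ell = 2 this is the
# classic (cos, sin) pair whose spatial vectors rotate uniformly.
quadratureSet <- function(f, fs = 256, N = 2000, ell = 2L) {
    n <- 0:(N - 1L)
    AASignalSet(t(sapply(seq_len(ell), function(k)
        cos(2 * pi * f * n / fs + (k - 1) * pi / 2))), fs = fs)
}

# Brute-force recurrence signal: per-lag mean of pairwise cosine
# similarities, computed with explicit loops. Oracle for the matrix path.
bruteRecurrence <- function(block) {
    M <- ncol(block) %/% 2L
    cosang <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    vapply(0:(M - 1L), function(p)
        mean(vapply(seq_len(M), function(i)
            cosang(block[, i], block[, i + p]), numeric(1L))),
        numeric(1L))
}

# Brute-force knee: enumerate all distances to the origin of a scaled
# flat-top spectrum with r nonzero equal values out of K.
bruteFlatKnee <- function(K, r) {
    y <- c(rep(K, r), rep(0, K - r))
    which.min(sqrt(seq_len(K)^2 + y^2)) - 1L
}
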