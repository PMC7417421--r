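#' Bounded Gaussian random walk
#'
#' Generates the phase-modulation process of the pseudo-AA model: a random
#' walk s(n) = s(n-1) + Delta(n) with Delta ~ N(0, v^2), constrained to
#' |s(n)| <= d by redrawing the increment until the bound holds. s(0) = 0.
#' The bound d controls the range of the phase excursion and v its rate of
#' variation. d = 0 or v = 0 yield the all-zero walk.
#'
#' @param n walk length in samples.
#' @param d bound in radians (nonnegative).
#' @param v standard deviation of the increment in radians (nonnegative).
#'
#' @return Numeric vector s(0..n-1) with |s| <= d throughout.
#'
#' @examples
#' set.seed(1)
#' s <- boundedRandomWalk(1000, d = 8, v = 0.3)
#' max(abs(s)) <= 8
#' @export
boundedRandomWalk <- function(n, d, v) {
    if (d < 0 || v < 0)
        stop("'d' and 'v' must be nonnegative")
    .boundedWalkCpp(as.integer(n), as.numeric(d), as.numeric(v))
}

#' Construct model parameters for the pseudo-AA generator
#'
#' Defaults reproduce the simulation conditions used throughout: cohort
#' median range d = 8 and rate v = 0.30, dominant frequency 6.5 Hz, 256 Hz
#' sampling, 15 intrinsic channels (the median long-scale effective dimension
#' observed on patients) mapped to 184 body-surface leads, and 60 s of
#' signal.
#'
#' @param d phase bound in radians.
#' @param v per-sample phase-increment standard deviation in radians.
#' @param fAF dominant frequency in Hz.
#' @param fs sampling rate in Hz.
#' @param intrinsicDim number of intrinsic channels.
#' @param nLeads number of surface leads.
#' @param nSamples number of samples (default 60 s at `fs`).
#' @param sharedWalk if TRUE a single walk drives all channels (planar-loop
#'   alternative); default FALSE (independent walks, loops span the space
#'   differently).
#' @param seed optional integer seed consumed by [simulateAA()].
#'
#' @return A [ModelParams-class].
#' @export
modelParams <- function(d = 8, v = 0.30, fAF = 6.5, fs = 256,
                        intrinsicDim = 15L, nLeads = 184L,
                        nSamples = round(60 * fs), sharedWalk = FALSE,
                        seed = NA_integer_) {
    new("ModelParams", d = as.numeric(d), v = as.numeric(v),
        fAF = as.numeric(fAF), fs = as.numeric(fs),
        intrinsicDim = as.integer(intrinsicDim), nLeads = as.integer(nLeads),
        nSamples = as.integer(nSamples), sharedWalk = isTRUE(sharedWalk),
        seed = as.integer(seed))
}

#' Intrinsic pseudo-AA signal
#'
#' Generates the intrinsic-dimensional pseudo-AA matrix: channel k
#' (k = 1..intrinsicDim) is cos(2 pi fAF / fs * n + s_k(n) + k / 2) for
#' n = 0..N-1, where s_k is a bounded random walk (see
#' [boundedRandomWalk()]). The fixed offsets k/2 (radians) stagger the
#' channels so that, with no randomness, the trajectory is a closed
#' propagation loop in intrinsic space; independent walks make the loops span
#' the space differently over time, emulating spatially uncoordinated AA
#' propagation.
#'
#' @param params a [ModelParams-class]. The `seed` slot is ignored here; use
#'   [simulateAA()] for seeded end-to-end generation.
#'
#' @return Numeric intrinsicDim x nSamples matrix with entries in [-1, 1].
#'
#' @examples
#' set.seed(1)
#' m <- pseudoAA(modelParams(intrinsicDim = 3, nSamples = 512))
#' dim(m)
#' @export
pseudoAA <- function(params) {
    stopifnot(is(params, "ModelParams"))
    N <- params@nSamples
    ell <- params@intrinsicDim
    n <- 0:(N - 1L)
    base <- 2 * pi * params@fAF / params@fs * n
    shared <- if (params@sharedWalk)
        boundedRandomWalk(N, params@d, params@v) else NULL
    out <- matrix(0, nrow = ell, ncol = N)
    for (k in seq_len(ell)) {
        s <- if (is.null(shared)) boundedRandomWalk(N, params@d, params@v)
             else shared
        out[k, ] <- cos(base + s + k / 2)
    }
    out
}

#' Random linear lead map
#'
#' Draws an nLeads x intrinsicDim matrix with i.i.d. standard-normal entries,
#' regenerating in the (measure-zero) event that it is column-rank
#' deficient. One fresh map is drawn per simulated subject.
#'
#' @param nLeads number of output leads.
#' @param intrinsicDim number of intrinsic channels.
#' @return An nLeads x intrinsicDim numeric matrix of full column rank.
#' @export
randomLeadMap <- function(nLeads, intrinsicDim) {
    if (nLeads < intrinsicDim)
        stop("'nLeads' must be at least 'intrinsicDim'")
    repeat {
        A <- matrix(rnorm(nLeads * intrinsicDim), nrow = nLeads)
        if (qr(A)$rank == intrinsicDim) return(A)
    }
}

#' Map an intrinsic signal to surface leads
#'
#' Applies a linear lead map to an intrinsic-dimensional signal, emulating
#' how a low-dimensional atrial source projects onto a dense body-surface
#' electrode array. The output rank cannot exceed the intrinsic dimension.
#'
#' @param source intrinsicDim x N numeric matrix.
#' @param nLeads number of surface leads (default 184).
#' @param fs sampling rate in Hz recorded in the result.
#' @param leadMap optional explicit map (nLeads x intrinsicDim); drawn with
#'   [randomLeadMap()] when NULL.
#'
#' @return An [AASignalSet-class] of nLeads leads.
#' @export
mapToLeads <- function(source, nLeads = 184L, fs = 256, leadMap = NULL) {
    source <- as.matrix(source)
    if (is.null(leadMap))
        leadMap <- randomLeadMap(nLeads, nrow(source))
    if (ncol(leadMap) != nrow(source))
        stop("'leadMap' columns must match the intrinsic dimension")
    AASignalSet(leadMap %*% source, fs = fs,
                leadIds = paste0("S", seq_len(nrow(leadMap))))
}

#' Completely random control process
#'
#' Generates i.i.d. standard-normal samples in an intrinsic-dimensional space
#' and maps them to surface leads. This control has no temporal structure at
#' all, so its effective dimension equals the intrinsic dimension at every
#' segment length: it isolates the effect of segment length from the effect
#' of signal dynamics in SVAAP analyses.
#'
#' @param intrinsicDim dimension of the noise process (default 15).
#' @param nLeads number of surface leads (default 184).
#' @param nSamples number of samples.
#' @param fs sampling rate in Hz (default 256).
#'
#' @return An [AASignalSet-class].
#' @export
randomControl <- function(intrinsicDim = 15L, nLeads = 184L,
                          nSamples = round(60 * fs), fs = 256) {
    src <- matrix(rnorm(intrinsicDim * nSamples), nrow = intrinsicDim)
    mapToLeads(src, nLeads = nLeads, fs = fs)
}

#' Exact lead-map compression for cosine-similarity analyses
#'
#' For a lead map A and intrinsic signal S, the cosine of the angle between
#' any two columns of A S depends on A only through its Gram matrix t(A) A.
#' Writing t(A) A = t(U) U (Cholesky), the compressed signal U S — with only
#' intrinsicDim rows — therefore has exactly the same column-wise cosine
#' similarities, hence exactly the same recurrence matrices, recurrence
#' signals and indices, as the full surface recording. This makes large
#' recurrence Monte-Carlo studies over many random lead maps cheap. Note the
#' compression does not preserve SVAAP, whose spectrum scaling depends on the
#' lead count.
#'
#' @param source intrinsicDim x N numeric matrix.
#' @param leadMap nLeads x intrinsicDim matrix (e.g. [randomLeadMap()]).
#' @return An intrinsicDim x N matrix equivalent to `leadMap %*% source` for
#'   all cosine-similarity analyses.
#' @export
compressLeads <- function(source, leadMap) {
    source <- as.matrix(source)
    if (ncol(leadMap) != nrow(source))
        stop("'leadMap' columns must match the intrinsic dimension")
    chol(crossprod(leadMap)) %*% source
}

#' Simulate a surface pseudo-AA recording
#'
#' End-to-end generator: intrinsic pseudo-AA signal ([pseudoAA()]) mapped
#' through a fresh random lead map ([mapToLeads()]). When the `seed` slot of
#' `params` is not NA the RNG is seeded first, making the output fully
#' reproducible from the parameter object alone.
#'
#' @param params a [ModelParams-class].
#' @param leadMap optional explicit lead map; a fresh random map is drawn
#'   when NULL.
#'
#' @return An [AASignalSet-class] of `params@nLeads` leads.
#'
#' @examples
#' x <- simulateAA(modelParams(nSamples = 2560, nLeads = 32, seed = 7L))
#' x
#' @export
simulateAA <- function(params, leadMap = NULL) {
    stopifnot(is(params, "ModelParams"))
    if (!is.na(params@seed))
        set.seed(params@seed)
    src <- pseudoAA(params)
    mapToLeads(src, nLeads = params@nLeads, fs = params@fs,
               leadMap = leadMap)
}
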