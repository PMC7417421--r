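---
title: "Methods: recurrence and spatial-variability analysis of atrial activity"
author: "aadyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recurrence and spatial-variability analysis of atrial activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aadyn)
```

## The problem

During persistent atrial fibrillation (AF) the atria no longer activate as a
single coherent wave: fibrillatory (f-) waves on the body surface reflect
disorganised, time-varying atrial activity (AA). How disorganised that
propagation is — the "substrate complexity" — matters clinically, e.g. for
anticipating AF recurrence after electrical cardioversion, but single-lead
ECG descriptors capture it poorly. `aadyn` implements a framework that works
on dense multichannel recordings (body surface potential maps, BSPM; 184
leads in the motivating setting) and separates the *short-term* (one AF
cycle) from the *long-term* (seconds) recurrent behaviour of the spatial AA
patterns.

Throughout, a recording is an `AASignalSet`: a leads × samples matrix
\(X\) whose column \(\mathbf x(n)\) is the spatial AA vector at sample
\(n\), plus a sampling rate (256 Hz in all defaults).

## Multi-variable recurrence signals and their indices

Within a block of \(2M\) consecutive samples (default \(M = 500\), i.e.
about 4 s at 256 Hz) the similarity of the spatial patterns at lag
\(p\) is measured by the cosine of the angle between the column vectors,

\[
R_{i,j} = \frac{\mathbf x(i)^{\mathsf T}\,\mathbf x(i+j-1)}
               {\lVert\mathbf x(i)\rVert_2\,\lVert\mathbf x(i+j-1)\rVert_2},
\qquad i, j = 1,\dots,M ,
\]

so column \(j\) holds lag \(p = j-1\). Normalising by the column norms makes
the analysis sensitive only to the *shape* of the spatial profile, not its
amplitude: rescaling any column of \(X\) by a positive constant leaves
everything unchanged (this invariance is asserted in the test suite). The
per-lag column mean of \(R\) is the multi-variable recurrence signal
\(r(p)\), a spatial autocorrelation with \(r(0)=1\) and \(|r(p)|\le 1\).
Consecutive non-overlapping blocks capture the piecewise-stationary nature
of AF propagation; trailing samples that do not fill a block are discarded.

From the block-wise curves, `subjectIndices()` extracts:

* **LTR** — long-term recurrence: the mean of \(|r(p)|\) over the lag band
  150–450 (where the curve envelope has plateaued), averaged over blocks;
* **|P1|, t\_P1** — absolute value and lag of the first strict local
  minimum at \(p \ge 1\) (≈ half an AF cycle);
* **P2, t\_P2** — value and lag of the first strict local maximum after
  t\_P1 (≈ one AF cycle);
* **P̃1 = |P1|/LTR, P̃2 = P2/LTR** — normalised peaks, which remove the
  influence of the overall substrate complexity on the short-term indices.

Design choices where the procedure is genuinely open:

* per-block peaks are averaged across blocks with the arithmetic mean,
  mirroring the explicit definition of LTR (the alternative — extracting
  peaks from a block-averaged curve — is *not* used; see "Model fitting"
  below for why averaging curves is harmful);
* peak detection uses strict local extrema with no smoothing and no
  prominence threshold; plateaus resolve to their first lag. This is the
  simplest deterministic rule and keeps t\_P1/t\_P2 exact for pure tones
  (t\_P1 = round(Fs/2f), t\_P2 = round(Fs/f));
* blocks with no qualifying extremum (e.g. monotone decay) are excluded
  from the peak averages, counted in `nDegenerate`, but still contribute to
  LTR, whose definition does not require peaks;
* \(r(0)=1\) is enforced within 1e-9; values are clipped to \([-1,1]\)
  against floating-point overshoot.

## SVAAP: spatial variability of AA propagation

For a segment of the recording, the singular values
\(\sigma_1 \ge \dots \ge \sigma_K\) (with \(K = \min(\text{leads},
\text{samples})\)) are scaled by \(K/\sigma_1\) and plotted against their
index. The effective dimension is read off at the knee of this spectrum:
the point closest to the origin marks the first negligible singular value,
and SVAAP is its index minus one — analogous to choosing the optimal
operating point of an ROC curve. The scaling puts both axes in the same
units, which is what makes the Euclidean distance meaningful.

Two time scales are used: **l-SVAAP** on non-overlapping 5-s segments, and
**s-SVAAP** on segments of \(q = \mathrm{round}(F_s/f_{AF})\) samples —
about one AF cycle, adapting the short scale to each subject. Both are
averaged over segments (the aggregation is stated for the short scale in
the original description; the mean is applied to both for symmetry).

Numerical choices:

* the scale factor uses \(K = \min(\ell, T)\), the number of singular
  values the segment actually has, not always the lead count \(\ell\): for
  5-s segments of a 184-lead recording \(K = \ell = 184\), but a one-cycle
  segment (\(q \approx 39 < 184\)) has only \(q\) singular values, and
  scaling those by \(\ell/\sigma_1\) would put the two axes on different
  ranges and break the distance geometry. A `scaleCount = "leads"` override
  is available;
* singular values below \(10^{-10}\sigma_1\) are set to exactly zero, so
  that rank-deficient synthetic segments produce clean flat-bottom spectra;
* ties in the distance minimisation resolve to the smallest index, and a
  knee at the first point (fully flat spectrum) yields the degenerate
  value 0;
* \(q = \mathrm{round}(F_s/f_{AF})\) (nearest integer; no rounding rule is
  inherited, and round() keeps the segment closest to one nominal cycle).

## The phenomenological generator

`pseudoAA()` generates intrinsic channel \(k = 1,\dots,\ell\) as

\[
m_k(n) = \cos\!\Big(2\pi \tfrac{f_{AF}}{F_s}\,n + s_k(n) + k/2\Big),
\]

where each \(s_k\) is a Gaussian random walk with per-step standard
deviation \(v\) (radians), confined to \([-d, d]\): increments are redrawn
until the bound holds (truncation — not clipping or reflection — which is
the natural reading of a constraint imposed on an otherwise Gaussian
step). \(s(0) = 0\), symmetric within the admissible range. The parameter
\(d\) controls the *range* of the phase excursions and \(v\) their *rate*;
the fixed offsets \(k/2\) rad stagger the channels so that the
deterministic limit (\(d = 0\) or \(v = 0\)) is a closed propagation loop
in \(\ell\)-dimensional space. With independent walks per channel (the
default) the loops wander through the space — emulating spatially
uncoordinated propagation; `sharedWalk = TRUE` gives the contrasting planar
alternative in which one walk modulates all channels.

The intrinsic signal is mapped to the surface by a random
\(\text{nLeads} \times \ell\) matrix with i.i.d. standard-normal entries
(one fresh map per simulated subject; regenerated in the measure-zero event
of rank deficiency). The control process (`randomControl()`) replaces the
model by i.i.d. standard-normal samples in \(\ell\) dimensions, mapped the
same way: it has no temporal structure, so its effective dimension equals
\(\ell\) at every segment length, isolating segment-length effects from
dynamics.

Defaults are the study conditions of the motivating analyses: \(d = 8\),
\(v = 0.30\) (cohort-median fitted values), \(f_{AF} = 6.5\) Hz,
\(F_s = 256\) Hz, \(\ell = 15\) (the median long-scale effective dimension
observed on patients), 184 leads, 60 s.

What the generator does *not* emulate: it is phenomenological, not
mechanistic — a single phase-modulated oscillation, with no tissue
electrophysiology, rotors, wavelets, ventricular residuals, electrode
noise, or lead geometry. Passing tests on this generator therefore
demonstrate the internal consistency of the measures under controlled
spatial dimensionality and phase dynamics, not their clinical performance
on real recordings.

### An exact computational shortcut

Cosine similarities between columns of \(A S\) depend on the lead map
\(A\) only through its Gram matrix \(A^{\mathsf T} A = U^{\mathsf T} U\)
(Cholesky), so `compressLeads()` replaces the 184-row mapped recording by
the \(\ell\)-row signal \(U S\) with *identical* recurrence matrices,
signals and indices (verified to 1e-12 in the tests). Recurrence
Monte-Carlo studies over many random maps use this path. SVAAP is not
preserved by the compression (its scaling depends on the lead count), so
SVAAP analyses always use the full mapped recording.

## Pre-filtering and dominant frequency

The standard chain is a 1–100 Hz 3rd-order Chebyshev type-I band-pass, a
50 Hz 2nd-order IIR notch, and a 3 Hz 3rd-order Chebyshev type-I
high-pass, each applied forward–backward (zero phase, so peak lags are not
displaced). Filter type and 0.5 dB passband ripple are package choices;
the band-pass is also applied zero-phase for consistency even though
zero-phase is only essential for the filters applied after any upstream
ventricular-activity removal. Each lead is extended by odd reflection
(up to 3 s) before `filtfilt` so start-up transients decay in the padding.
Inputs are assumed to be AA-only; QRST cancellation is out of scope.

The dominant frequency is estimated per lead as the Welch-periodogram
maximum (4-s Hamming windows, 50% overlap — a package choice, the spectral
estimator being otherwise unspecified) within 3–12 Hz, and averaged over
leads. Estimates are flagged when the peak sits on a band edge, or when the
peak-to-median in-band power ratio falls below 3 (no well-expressed
oscillation, e.g. broadband noise).

## Model fitting

`fitSubject()` fits \((d, v)\) by exhaustive grid search (defaults:
\(d \in \{6,\dots,14\}\), \(v \in \{0.16, 0.18, \dots, 0.32\}\)): for each
cell, `nModels` (default 40) realisations are simulated — fresh walks and a
fresh lead map each — and scored against the target by
\(|\Delta|P_1|| + |\Delta P_2| + |\Delta \mathrm{LTR}|\). The dominant
frequency is treated as a nuisance parameter: each cell's score is the
minimum over offsets \(\{-1, -0.5, 0, +0.5, +1\}\) Hz around the subject's
estimate. Ties resolve toward smaller \(d\), then smaller \(v\). Per-cell
seeds are derived deterministically from the master seed and the cell's
*parameter values*, so a score surface is exactly reproducible and
enlarging the grid rescores existing cells identically.

The simulated side is aggregated exactly like the observed side: per-block
peaks averaged over blocks (pooled across the `nModels` realisations) and
LTR as the mean over blocks of the band-mean \(|r(p)|\). The alternative —
extracting indices from the model-averaged \(\hat r(p)\) curve — was
implemented and rejected: block curves have independent phases in the
150–450 lag band, so curve averaging collapses the plateau
(\(|\overline{r}| \ll \overline{|r|}\); about 0.009 vs 0.036 at
\(d=8, v=0.30\)), which deflates the simulated LTR relative to the target's
and biases the fitted \(d\) low by one to two grid steps. Symmetric
aggregation removes that bias.

A related subtlety governs the recovery harness
(`recoveryExperiment()`): the walks start at \(s(0)=0\), so the first
block of every realisation is less phase-dispersed than the stationary
regime reached after roughly \((d/v)^2\) samples (~700 at the defaults,
i.e. most of one block). Target and model realisations must therefore use
the same duration, so that early-block transients contribute equally to
both sides of the score; fitting 60-s targets with 4-s model realisations
reintroduces a low-\(d\) bias.

Identifiability is asymmetric: \(v\) is recovered essentially exactly
(one grid step), while \(d\) — whose effect on the indices per unit grid
step is comparable to the sampling noise of a single 60-s subject — is
recovered to within about one step. The recovery harness reports the full
per-trial table so this asymmetry is visible rather than hidden in an
aggregate.

## Association utility

`univariateAssociation()` standardises an index (z-score — the scale being
otherwise unspecified, per-SD slopes make indices comparable), fits a
maximum-likelihood logistic regression against a binary outcome, and
reports the slope, Wald p-value and AUC of the fitted probabilities. Under
(quasi-)separation the estimates are refitted with Firth's bias-reduced
likelihood and flagged; a constant index short-circuits to slope 0 and
AUC 0.5. `multivariableAssociation()` fits all indices jointly, flags
strongly correlated pairs (|r| > 0.8), and deliberately performs no
variable selection.

## Problem sizes used by the test suite

The packaged checks run the simulation studies at sizes chosen for a
single-CPU desktop: 50 control runs and 50 model runs of 60 s for the
segment-scale analyses, 100 runs at the default parameters for the
short-scale dimension, a 9 × 9 \((d, v)\) grid with 5 runs per cell at
each of 5, 6.5 and 8 Hz for the direction of the index–LTR relation, and
20 recovery trials with 40 models per cell on a reduced
5 × 3 grid with matched 60-s durations. Monte-Carlo
tolerances in the tests correspond to these sizes.

## Known limitations

* Input is delimited text (plus in-memory matrices); physiological binary
  formats are not read directly.
* The generator's single-oscillator structure cannot produce harmonically
  rich or multi-focal AA; conclusions about real BSPM data require real
  recordings.
* The knee rule is the only effective-rank estimator provided (by design);
  entropy- or broken-stick-based estimators are out of scope.
* \(d\) is weakly identified by the index triple; fitted \(d\) values
  should be interpreted with their one-step uncertainty in mind.
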