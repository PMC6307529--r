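---
title: "Methods: EEG diffusion embeddings, windowed mutual information, and PVS asymmetry"
author: "ptebio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG diffusion embeddings, windowed mutual information, and PVS asymmetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptebio)
```

# Scope

`ptebio` implements an analysis battery for biomarker discovery in
post-traumatic epileptogenesis studies, where long-term multichannel EEG and
MRI-derived perivascular-space (PVS) markings are collected from the same
cohorts. Three signal-analysis tools operate on EEG recordings — short-time
Fourier spectrograms, windowed mutual information between channel pairs, and
an unsupervised diffusion-component embedding that flags epileptiform
windows — and one statistical battery operates on per-subject PVS marker
tables. Synthetic generators for both data types provide ground truth so
that every stage is testable without patient data.

All EEG data live in an `EEGRecording`: a channels-by-samples matrix in
microvolts with a sampling rate (200 samples/second in all defaults) and a
time origin. Time is measured in seconds, samples are 0-based, and every
interval is half-open `[start, end)`, which keeps the arithmetic of
50%-overlapping windows unambiguous.

# Spectral analysis

`stftSpectrogram()` applies the short-time Fourier transform to the raw,
unfiltered signal of one channel. The default analysis window is 1 s with a
periodic Hann taper and 50% overlap; all three are configurable. Squared
magnitudes are scaled to a one-sided power spectral density in µV²/Hz:
interior bins carry the doubled negative-frequency energy and the scaling
divides by `fs · sum(w²)` for taper `w`. This normalisation is chosen
because it makes the Parseval property exactly testable: with a rectangular
taper the density integrated over frequency equals the signal variance, and
the test suite asserts this within 5% on white noise.

`bandPowerSeries()` integrates the density over a frequency band with the
trapezoid rule, per frame; `thresholdEvents()` scans any per-frame series
for maximal runs above a threshold, discarding runs shorter than a minimum
duration. Together they quantify band-limited activity over time; nothing
here claims to be a detector of high-frequency oscillations.

# Windowed mutual information

Dependence between two channels is estimated per consecutive,
non-overlapping window (default 30 s) with a plug-in histogram estimator:
equal-width bins spanning each window's observed range (16 per axis by
default), mutual information in bits over non-empty cells. The estimator is
deterministic and dependency-free; its positive bias is approximately
`(B − 1)²/(2 n ln 2)` bits for `B` bins and `n` samples — about 0.03 bits at
the defaults — which is irrelevant for the intended use, the *trend* of MI
over windows, because the bias is common to all windows. A constant input
yields exactly 0. `miTrend()` reports the least-squares slope per window
plus the Spearman rank correlation and p-value of MI against window index;
rank statistics are preferred because the rise of inter-channel coupling
toward a seizure need not be linear. Trailing partial windows are dropped;
windows never overlap, so successive MI values are estimated from disjoint
data.

# The diffusion-component embedding

The embedding pipeline (`runUDCA()`) turns a multichannel recording into a
3-D point cloud, one point per analysis window, in which epileptiform
windows appear as outliers.

**Segmentation.** The signal matrix is cut into submatrices of
`windowSize` samples (default 400, i.e. 2 s at 200 samples/second —
long enough to estimate a channel covariance, short enough that a spike
dominates its window) overlapped by exactly half a window; the trailing
remainder is dropped. A report-only cross-correlation QC
(`qcCrossCorrelation()`) summarises, per channel pair, the median over
segments of the maximal absolute normalized cross-correlation over lags up
to `maxLag` (default 32 samples); nothing is ever dropped automatically.

**Metric.** Each segment contributes its time-based channel covariance
matrix, pseudo-inverted by SVD with singular values below
`svdTol · σ_max` zeroed (`svdTol` default 1e-8); a flat segment yields the
zero matrix and contributes zero distance, with a warning. The distance
between segments i and j is the covariance-weighted quadratic form

$$d_{ij} = \frac{1}{w}\sum_t \delta_t^\top
  \frac{\Sigma_i^{+} + \Sigma_j^{+}}{2} \delta_t,$$

where `δ_t` is the per-sample channel difference. Averaging over the
window's samples puts `d` on the scale of a single-sample quadratic form:
for two segments differing by a constant per-channel offset the expression
reduces exactly to the offset's quadratic form (an offset of (3, 4) under an
identity inverse covariance gives d = 25). Averaging the two segments'
pseudo-inverses is the symmetrised local-covariance form of the
Mahalanobis metric used for signal denoising; a pooled covariance is a
possible alternative and deliberately not the default, because local
covariances make the metric approximately invariant to slow gain and
coupling changes.

**Kernel.** Affinities are `A = exp(−d/(4 k_e))` with `k_e = 10`, applied
to the full pairwise distance matrix (the kernel needs to be square for the
spectral step; the consecutive-segment distances are also computed and kept
for inspection). With whitened data the typical pairwise distance is about
twice the channel count, so at five channels `d/(4k_e) ≈ 0.25` and the
kernel is well away from both the all-ones and the identity regime.

**Two-stage normalisation.** The operator construction divides the kernel
elementwise by the square root of its row sums on both sides and squares
the result, then repeats the same normalisation and squaring once more:

```
j1 = rowSums(A);  A1 = A / sqrt(j1 j1ᵀ);  W1 = A1 A1
j2 = rowSums(W1); A2 = W1 / sqrt(j2 j2ᵀ); W2 = A2 A2
```

As printed in the source method the first-stage row sums are defined via
the matrix they normalise, which is circular; the construction above is the
standard diffusion-maps resolution and has the advantage that the leading
eigenpair is analytically known: `sqrt(j2)` is a fixed point of `A2`, so
`W2` has eigenvalue 1 with the point-cloud vector (below) constant, and the
whole spectrum lies in [0, 1] because `A2` is similar to a row-stochastic
matrix. Both facts are asserted in the tests at 1e-8/1e-10 tolerances.
Eigenvectors are sorted by descending eigenvalue, with the notational
convention that *eigenvalues* and *eigenvectors* are always named
explicitly (the printed source swaps the symbols between equations).
Point-cloud (diffusion) coordinates are `V_clds = diag(1/sqrt(j2)) · V`.

**Nyström extension.** Held-out windows receive coordinates by pushing
their raw affinity row through the same two normalisation stages, making
the resulting row stochastic (dividing by its sum ω), multiplying by the
point-cloud eigenvectors, and dividing by the square root of each
eigenvalue. Because the point-cloud vectors are right eigenvectors of the
row-stochastic stage-two operator with eigenvalues `sqrt(λ_k)`, extending a
training window reproduces its in-sample coordinates exactly up to
numerical error; the tests require 1e-6 relative agreement. Column 1 of the
extension is the trivial constant; columns 2 and 3 are the extensions for
the two largest non-trivial eigenvalues.

**Embedding selection.** All `C(m−1, 3)` triples of eigenvector indices
≥ 2 are candidate embeddings (the first eigenvector is the constant and is
excluded); the selected embedding maximises the spread — the mean Euclidean
distance of embedded points from their centre of mass — with ties broken to
the lexicographically smallest triple for determinism.

A design choice was genuinely open here: which coordinates enter the
candidate embeddings. Using the raw point-cloud columns proved degenerate
under this operator: two rounds of squaring compress the spectrum so hard
that trailing eigenvalues sit orders of magnitude below the leading
non-trivial one, their eigenvectors are near-degenerate and localise on
single windows, and the `1/sqrt(j2)` scaling then hands them macroscopic
spread, so the max-spread rule selects what is effectively noise. The
package therefore evaluates candidates in eigenvalue-weighted diffusion
coordinates `λ_k φ_k` — the coordinates in which Euclidean distance is the
diffusion distance, the standard convention in the diffusion-maps
literature this method extends. With the weighting the selection is stable
and the flagged outliers track injected spikes; the selected coordinates
returned in the result are on this weighted scale. A consequence worth
noting: on structureless recordings the ratio of the selected spread to the
median candidate spread reflects the eigenvalue gaps rather than staying
near 1, so "no structure" is instead recognisable by the absence of
dominant outlier scores.

**Outlier scoring.** Scores are Euclidean distances from the embedding's
centre of mass. The `mad` rule flags scores above
`median + param · MAD` (scaled MAD, `stats::mad`); the `quantile` rule
flags exactly the top `param` fraction (count `ceiling(param · n)`, with an
epsilon guard against floating-point spill). Flags map back to window
start times. The pipeline contains no randomness: identical inputs give
bitwise-identical results.

# Synthetic data

`genEEG()` emulates the statistical skeleton of long-term clinical and
experimental EEG:

- **Background**: 1/f^a noise (a = 1 by default) at 20 µV RMS, generated by
  spectral shaping of white Gaussian noise.
- **Epileptiform transients**: spike-and-slow-wave templates — a sharp
  half-sine of 70 ms and 300 µV peak (clinically typical values) followed by
  an opposite-polarity slow wave three times as long at 40% amplitude —
  added to all channels with ±2 samples of jitter and per-channel gain in
  [0.8, 1.2], at 4 per minute by default, or at explicit peak times. Ground
  truth returns the peak times.
- **Coupling toward seizure**: channels mix an independent background with a
  shared latent 1/f signal; the shared-variance fraction ramps linearly
  from `couplingRamp[1]` to `couplingRamp[2]` at the seizure onset. A
  seizure is *optional*: by default no onset is configured and the ramp is
  flat at zero, so a default recording is interictal (spikes, no seizure);
  analyses of preseizure coupling configure, e.g.,
  `couplingRamp = c(0, 0.8), seizureOnsetS = 300`.

A single integer seed fans out into fixed per-component substreams
(background, latent signal, spike times, jitter), so enabling spikes never
perturbs the background draws — fixtures stay stable as configurations
vary.

What the generator does **not** emulate: artifacts (movement, electrode
pops, line noise), nonstationary background rhythms, realistic spatial
topographies or volume conduction, and seizure morphology itself. Passing
tests therefore demonstrate correctness of the algorithms under controlled
conditions, not clinical detection performance.

`genPvsCohort()` emulates a TBI-vs-control MRI cohort: 15 + 6 subjects,
total PVS count per subject drawn from Normal(78, 30) floored at 10,
per-subject asymmetry index drawn from a Beta distribution whose mean is
the group target (0.17 TBI-like, 0.04 control-like; concentration 20, which
gives SDs of about 0.08 and 0.04), and the hemisphere split derived
*deterministically* from the drawn AI (`nMajor = round(total(1+AI)/2)`) — a
binomial split would fold sampling noise into the measured AI and bias
small-AI groups upward. Calibers are Normal(1.35, 0.24) mm truncated to the
reliable [0.5, 3) mm marking range by resampling, with the minor side's
mean lowered by `0.5 · AI` mm, so that higher asymmetry goes with a larger
inter-hemispheric caliber difference, the smaller calibers sitting on the
PVS-poor side. Ages are uniform on 18–65. Note that a subject with an odd
total count cannot have AI = 0, so the measured control-group mean sits
slightly above its target — a floor effect of counting, not a bug.

# PVS asymmetry statistics

Per subject, the hemispheric ratios are `HR_h = count_h / total`, with
`HR_minor`/`HR_major` the smaller/larger value (both 0.5 on an exact tie)
and the asymmetry index `AI = HR_major − HR_minor ∈ [0, 1]`. In
`subjectAsymmetry()` the AI is computed in the count-exact form
`|right − left| / total`: the two are mathematically identical, but the
subtraction of rounded ratios can land a 60/40 split a few ulps *below*
the high-asymmetry boundary, and the boundary is inclusive — AI ≥ 0.2 is
graded `high`, which corresponds to one hemisphere holding more than 60% of
all PVSs. Between 0.1 and 0.2 the grade is `intermediate`; this band is a
package convention (only the 0.2 threshold has an established definition)
and both thresholds are parameters.

Caliber statistics are per-hemisphere means and the absolute difference
`|C_diff| = |C_right − C_left|`; the magnitude is used because the
asymmetry-correlation analysis needs a sign-free quantity. Group
comparisons use the classical equal-variance Student's t-test (a Welch
variant sits behind a flag), correlations are Pearson with t-based
p-values, and within-subject caliber differences between hemispheres use a
two-sample t-test per subject. `tTestFromSummary()` computes the
equal-variance t from printed group summaries (mean, SD, n); on summaries
of the scale reported for cohorts like this (77 ± 48 vs 80 ± 15 at
n = 15/6) it gives |t| < 1, i.e. no group difference — the tests assert
exactly this, and no attempt is made to reproduce any particular published
p-value from summary statistics alone.

`cohortReport()` assembles the full battery on any cohort: per-subject
rows, group mean ± SD of totals, HR ranges and minor/major means, group
mean AI with its t-test, caliber means with their t-test, the AI vs
|C_diff| correlation, the age vs total-count correlation, high/intermediate
asymmetry counts, and per-subject caliber tests. Subjects with zero
in-range markers are excluded with an explicit report; group tests with
fewer than two subjects per group are omitted rather than fabricated.

# Numerical conventions and degenerate inputs

- Caliber bounds are half-open: 0.5 mm is kept, 3.0 mm excluded; markers
  outside the range are dropped at load with a count in the load report.
- Ties in embedding selection break to the lexicographically smallest
  index triple; the quantile outlier rule breaks score ties by window
  order. Both keep the pipeline deterministic.
- Flat (zero-variance) segments: zero pseudo-inverse, zero distance,
  warning. Zero-variance vectors in correlations: `NA` with a message. A
  subject with an empty hemisphere: `|C_diff|` is `NA`-marked with a
  message.
- EDF output is 16-bit; each channel is scaled into the full digital range
  from its own extrema as written into the 8-character header fields, so
  the round-trip error is at most half a digital step of the channel range.

# Problem sizes

The shipped tests and the acceptance script run the pipeline at desk
scale, chosen to exercise every code path while staying light: 300-second,
5-channel recordings at 200 samples/second for spike detection (299
windows of 2 s); 100 simulations of 300 s for each arm of the MI-trend
property; 50 simulated cohorts of 21 subjects for the asymmetry parameter
recovery; kernels up to 25 × 25 for the spectral invariants. These sizes
are package choices; every routine accepts arbitrarily longer inputs.

# Known limitations

- The embedding pipeline's O(n²) pairwise metric makes very long
  recordings expensive; the intended use is on windows of minutes, or via
  the Nyström extension after decomposing a training stretch.
- The MI estimator is the plug-in histogram form only; estimator choice is
  recorded in the profile so k-NN estimators can be added without breaking
  the container.
- The cross-correlation QC is report-only; no operational rule for
  excluding channels is defined.
- Semi-supervised variants of the embedding and any claim about seizure
  *prediction* performance on clinical data are out of scope.
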