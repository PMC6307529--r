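# ptebio

Analytic toolkit for biomarker discovery in post-traumatic epileptogenesis:
unsupervised detection of epileptiform EEG windows by a diffusion-component
embedding, windowed mutual information between EEG channels, short-time
Fourier spectrograms, and hemispheric-asymmetry statistics for MRI-derived
perivascular-space (PVS) marker tables. It is written for researchers who
work with long-term multichannel EEG (clinical ICU or experimental
recordings, around 200 samples/second) and with manually marked PVS tables
from T2-weighted MRI, and who need every analysis step reproducible and
testable against synthetic ground truth.

## The methods at the core

**Diffusion-component embedding of EEG.** A recording is cut into
50%-overlapping windows of `w` samples. Each window gets its channel
covariance `Σ_i` (pseudo-inverted via SVD), and windows are compared with a
symmetrised Mahalanobis quadratic form

    d_ij = (1/w) Σ_t δ_tᵀ [(Σ_i⁺ + Σ_j⁺)/2] δ_t ,

which whitens out slow gain and coupling changes. A Gaussian affinity kernel
`A = exp(−d / (4 k_e))` (`k_e = 10`) is normalised in two stages (divide by
√row-sums on both sides, square; repeat) and eigendecomposed; point-cloud
coordinates are the eigenvectors scaled by `1/√(row sums)`. All triples of
eigenvectors ≥ 2 form candidate 3-D embeddings, evaluated in
eigenvalue-weighted diffusion coordinates; the one with maximal spread
(mean distance to the centre of mass) is selected, and windows far from the
centre of mass are flagged as epileptiform candidates — by a robust
median + MAD rule or a top-quantile rule. Out-of-sample windows get
coordinates by a Nyström extension that is exact on in-sample windows.

**Windowed mutual information.** For a channel pair, MI in bits is
estimated per consecutive non-overlapping 30-s window with an equal-width
histogram plug-in estimator (16 bins/axis); `miTrend()` quantifies whether
coupling rises toward a seizure (slope, Spearman rank correlation,
p-value).

**PVS asymmetry.** For each subject with hemisphere PVS counts, the
hemispheric ratios are `HR_h = count_h / total`; the asymmetry index

    AI = HR_major − HR_minor ∈ [0, 1],   AI ≥ 0.2 ⇒ high asymmetry

(0.2 means one hemisphere holds more than 60% of all PVSs). Per-hemisphere
mean calibers give `|C_diff| = |C_right − C_left|`. `cohortReport()`
computes the full battery: group mean ± SD of totals, HR ranges, group mean
AI with a Student's t-test, caliber statistics, AI vs |C_diff| and age vs
count Pearson correlations, and per-subject hemisphere caliber tests.

Synthetic generators (`genEEG()`, `genPvsCohort()`) produce both data types
with known ground truth: 1/f background with injected spike-and-slow-wave
transients and an optional coupling ramp toward seizure onset; PVS cohorts
with controllable group-mean asymmetry and a caliber–asymmetry coupling.

## Worked example

```r
library(ptebio)

# --- EEG: recover injected epileptiform spikes ---------------------------
sim <- genEEG(eegSimConfig(durationS = 120,
                           spikeTimesS = c(14.2, 33.7, 61.0, 88.4, 103.9),
                           seed = 42))
sim$recording
#> EEGRecording: 5 channel(s) x 24000 samples @ 200 Hz
#>   time span [0, 120) s
#>   channels: C1, C2, C3, C4, C5

res <- runUDCA(sim$recording, udcaConfig(outlierRule = "quantile",
                                         outlierParam = 0.1))
res
#> UDCAResult: 119 windows, 8 retained eigenpairs
#>   selected embedding (2, 3, 4), spread 1.126e-05
#>   flagged windows: 12 of 119
res@windowStartsS[outlierFlags(res)]
#> [1]  13  14  32  33  59  60  61  87  88 102 103 104
```

The flagged 2-second windows bracket exactly the five injected spike times
(14.2, 33.7, 61.0, 88.4, 103.9 s) — each spike lands in the two overlapping
windows that contain it.

```r
# --- PVS: cohort asymmetry statistics ------------------------------------
cohort <- genPvsCohort(pvsSimConfig(seed = 42))   # 15 TBI + 6 control
rep <- cohortReport(cohort)
rep$groups[, c("group", "n", "total_mean", "total_sd", "ai_mean", "n_high")]
#>     group  n total_mean total_sd ai_mean n_high
#> 1     TBI 15       69.5     33.2  0.1901      8
#> 2 control  6       98.8     45.4  0.0151      0
rep$aiTest[c("t", "pValue")]      # t = 4.66, p = 0.00017
rep$aiVsCdiff[c("r", "pValue")]   # r = 0.57, p = 0.007
```

The simulated TBI-like group shows a markedly higher mean asymmetry index
than the control-like group (0.19 vs 0.02, with 8 subjects above the high
threshold), the group difference is detected by the t-test, and subjects
with more asymmetric PVS distributions have larger inter-hemispheric
caliber differences — the relationships the generator encodes as ground
truth.

A command-line entry point wraps the same functions
(`inst/scripts/ptebio`): subcommands `simulate`, `spectrogram`, `mi`,
`udca`, `pvs`, each writing its outputs atomically together with a JSON run
manifest (command, config, input digests, version, timestamp, seed).

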