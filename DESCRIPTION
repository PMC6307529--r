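Package: ptebio
Title: EEG and Perivascular-Space Biomarker Analysis for Post-Traumatic
    Epileptogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analytic toolkit for biomarker discovery in post-traumatic
    epilepsy studies. Provides an unsupervised diffusion-component
    embedding of multichannel EEG built on a Mahalanobis-metric affinity
    kernel over 50%-overlapping windows, with Nystrom out-of-sample
    extension, automatic embedding selection by point-cloud spread, and
    outlier scoring to flag epileptiform windows; sliding-window mutual
    information between channel pairs with trend statistics; short-time
    Fourier spectrograms with one-sided power spectral density scaling
    and band-threshold event quantification; per-subject perivascular
    space (PVS) hemispheric ratios, asymmetry index and caliber
    statistics with cohort-level tests; synthetic EEG and PVS cohort
    generators with ground truth; readers and writers for EDF and
    plain-text fixtures; and a command-line entry point.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'edf.R'
    'signal-io.R'
    'pvs-io.R'
    'spectral.R'
    'mutual-info.R'
    'udca.R'
    'pvs-asymmetry.R'
    'synthetic-eeg.R'
    'synthetic-pvs.R'
    'cli.R'
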