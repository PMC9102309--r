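Package: wpdcca
Title: Motion-Artifact Correction for Single-Channel EEG and fNIRS by
    Wavelet Packet Decomposition and Canonical Correlation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Removes motion artifacts from single-channel EEG and fNIRS
    recordings with two related methods: a single-stage wavelet packet
    decomposition (WPD) that splits the record into 2^j frequency-ordered
    sub-band components and discards the artifact-bearing ones, and a
    two-stage WPD-CCA method that feeds the sub-band components to a
    canonical-correlation blind source separation against a neighbor-sum
    surrogate and discards maximally autocorrelated artifact sources.
    Includes the preprocessing chain (anti-aliased downsampling, power-line
    notch filtering with harmonics, polynomial baseline-drift correction),
    ground-truth-guided and ground-truth-free component selection rules,
    the delta-SNR and percentage-artifact-reduction (eta) evaluation
    metrics, and a seedable generator of paired clean/corrupted recordings
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
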