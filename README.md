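# wpdcca

Motion-artifact correction for **single-channel EEG and fNIRS** recordings
in R, built around two related methods:

* **WPD** (single-stage): decompose the record with a level-`j` wavelet
  packet transform into `2^j` equal-width, frequency-ordered sub-band
  component signals, discard the artifact-bearing components, and sum the
  rest.
* **WPD-CCA** (two-stage): feed the `2^j` sub-band signals, as a
  multichannel matrix, to a canonical-correlation blind source separation
  against a surrogate built from neighboring samples
  (`y_t = x_{t-1} + x_{t+1}`, or the classical lag-one delay); zero the
  artifact sources, re-mix through the inverse un-mixing matrix, and
  collapse the channels back to one signal.

Artifact components are identified either by **ground-truth-guided greedy
rejection** — remove a component only if doing so raises the Pearson
correlation between the reconstruction and a simultaneously recorded
artifact-free reference channel — or, without any reference, by discarding
the lowest-frequency **approximation sub-band**, where motion artifacts
concentrate.

Performance is scored by the SNR improvement
`ΔSNR = 10 log10(var(ref − corrupted) / var(ref − cleaned))` (dB) and the
percentage reduction in motion artifacts
`η = 100 (1 − (ρ_clean − ρ_after) / (ρ_clean − ρ_before))`, with the
idealized form taking `ρ_clean = 1`.

The package also ships the full preprocessing chain (anti-aliased
downsampling 2048→256 Hz, 50 Hz Butterworth notch with harmonics,
polynomial baseline-drift correction), CSV/JSON I/O, and a seedable
generator of paired clean/corrupted recordings that emulates the
two-channel benchmark protocol (540 s records, artifact bursts of 10-25 s
every 2 min), so the whole pipeline is testable without any external data.

## Worked example

```r
library(wpdcca)

cfg  <- synth_config("EEG", seed = 7)     # 540 s @ 2048 Hz, bursts every 120 s
pair <- generate_paired(cfg)
pair
#> <paired_recording> EEG, 1105920 samples @ 2048 Hz, 4 artifact epoch(s)

fit <- denoise(pair, method = "wpd", wavelet = "db1",
               selection = "approx-drop")
fit
#> Motion-artifact correction: WPD(db1) level=4 selection=approx-drop [single-stage]
#>   138240 samples @ 256 Hz (EEG)
#>   components removed: {1}
#>   rho before/after  : 0.3076 / 0.7130
#>   delta SNR         : 12.85 dB
#>   eta               : 58.55 %
```

The record was downsampled to 256 Hz, notch-filtered and detrended, then
split into 16 sub-bands (`j = 4`); dropping the approximation sub-band
(component 1, the 0-8 Hz band where the planted low-frequency artifact
lives) raises the correlation with the reference channel from 0.31 to
0.71, a 12.85 dB SNR improvement and a 58.6% artifact reduction — without
ever consulting the reference. The two-stage variant on the same pair:

```r
fit2 <- denoise(pair, method = "wpd-cca", wavelet = "db1",
                cca_surrogate = "delay")
fit2
#> Motion-artifact correction: WPD-CCA(db1) level=4 selection=ground-truth [two-stage]
#>   138240 samples @ 256 Hz (EEG)
#>   components removed: {1, 2}
#>   rho before/after  : 0.3076 / 0.7054
#>   delta SNR         : 12.72 dB
#>   eta               : 57.45 %
```

`fitted(fit)` returns the cleaned samples, `residuals(fit)` the removed
artifact estimate, `plot(fit)` a reference/corrupted/cleaned panel, and
`run_batch()` applies one configuration across many records with mean ± SD
summaries. A thin command-line wrapper for the same operations lives at
`inst/cli/wpdcca` (`generate`, `denoise`, `evaluate`, `batch`).

See the vignette (`vignettes/motion-artifact-correction.Rmd`) for the
model, the numerical choices, and a candid discussion of when the
two-stage method can and cannot improve on the single-stage one.

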