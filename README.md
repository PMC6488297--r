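# somnocirc

Sleep architecture, EEG spectral power, and circadian wheel-running
analysis for rodent recordings.

Rodent sleep studies score EEG/EMG recordings into 4-s epochs of
wakefulness (W), NREM sleep (N) and REM sleep (R), and phenotype animals
through a standard battery: time in state by zeitgeber hour, bout
architecture, sleep-onset latency after sleep deprivation, normalized
NREM delta (0.5–4 Hz) power as the index of sleep pressure, and — for
circadian function — wheel-running actograms with chi-squared periodogram
period estimation under light:dark (LD) and constant-darkness (DD)
schedules. `somnocirc` packages that battery as tested, reusable R
functions, for sleep/circadian labs and for anyone re-analyzing
epoch-scored hypnograms, per-epoch spectra, or wheel-count series.

## What it computes

* **Hypnogram metrics** — validation from epoch CSVs, maximal-run bout
  segmentation, hourly time-in-state tables with invalid-hour exclusion,
  total sleep time per light/dark period, bout statistics by time block,
  latency to state (NREM ≥ 28 s, REM ≥ 16 s criteria), wake percentage.
* **EEG spectra** — Welch-averaged epoch spectra on the 0.781 Hz bin grid
  (200 Hz / 256-sample windows, bins 1–25 up to 19.5 Hz), band powers
  (delta/theta/alpha), state-specific mean spectra with artifact
  exclusion, percent-of-state-total-power normalization, and
  percent-of-baseline normalization against hours 9–12 of a baseline day.
* **Sleep-deprivation homeostasis** — per-subject reports (deprivation
  efficacy, recovery latencies, windowed time in state, hourly normalized
  delta timecourse) and gated group spectral comparisons with
  Benjamini–Hochberg correction, reporting contiguous significant Hz
  ranges.
* **Circadian wheel running** — Sokolove–Bushell chi-squared periodogram

      Qp(P) = K · Σ_h (M_h − M̄)² / [(1/N) Σ_i (x_i − M̄)²],   df = P − 1,

  with a pointwise χ²(0.95) significance line; activity onset/offset and
  alpha; weekly period/alpha/activity summaries; single- and
  double-plotted actograms.
* **Statistics** — Welch t-tests, BH adjustment, GCV penalized-spline
  smooths with 95% CIs, and CI-non-overlap intervals.
* **Synthetic data** — Markov hypnograms built from analytic stationary
  targets, sleep-deprivation protocols with configurable leak and
  onset-delay, template-based EEG spectra/signals with a delta-rebound
  knob, and entrained or free-running Poisson wheel series. Generators
  are pure functions of `(config, seed)` and carry ground truth, so every
  stage is validated by parameter recovery.

File formats: hypnogram/spectra/wheel CSV, ClockLab-style AWD import, a
minimal EDF codec for signals, YAML run configs with provenance hashes.

## Worked example

```r
library(somnocirc)

cfg     <- sleepSimConfig()                      # wild-type-like defaults
base    <- simulateHypnogram(cfg, seed = 1)
sdDay   <- applySleepDeprivation(base, cfg, seed = 2)
tmpl    <- eegTemplates()
report  <- runHomeostasis(
  list(hyp = base,  spec = simulateEEG(base,  tmpl, seed = 3)),
  list(hyp = sdDay, spec = simulateEEG(sdDay, tmpl, seed = 4)))
report
#> Homeostasis report (subject NA)
#>   SD efficacy: 97.07% wake
#>   NREM latency: 192 s   REM latency: 376 s
```

The deprivation window (hours 1–5) held the animal awake 97.07% of the
time (the configured 3% per-epoch leak), and after release at hour 6 the
first ≥ 28 s NREM bout began 192 s later, the first ≥ 16 s REM bout at
376 s. The report also carries time in state for the recovery windows and
the hourly NREM delta timecourse normalized to baseline hours 9–12 (first
recovery hour ≈ 139% with the default 1.4 rebound gain).

```r
ws <- simulateWheel(wheelSimConfig(days = 14, schedule = "LD"), seed = 7)
chiSquaredPeriodogram(ws, dayRange = c(8, 14))
#> Chi-squared periodogram: 49 candidates 20.00-28.00 h; peak 24.00 h (significant)
```

An entrained mouse's wheel running peaks at exactly 24.0 h; under
constant darkness with `tauH = 23.7` the peak moves to 23.67 h (one
10-min candidate step from the true period).

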