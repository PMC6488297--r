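---
title: "Sleep and circadian phenotyping with somnocirc: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep and circadian phenotyping with somnocirc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somnocirc)
```

# Overview

`somnocirc` implements the computational core of a rodent sleep and
circadian phenotyping study: hypnogram architecture metrics, epoch-based
EEG spectral analysis with two normalization schemes, a sleep-deprivation
homeostasis report, and wheel-running circadian analysis built around the
Sokolove–Bushell chi-squared periodogram. Because raw EEG and wheel
recordings of this kind are rarely deposited, the package ships a
first-class synthetic-data module whose generators carry analytic ground
truth; every analysis stage is validated by recovering known parameters
from simulated data.

# Hypnogram model and conventions

A hypnogram is a sequence of 4-s epochs scored `W` (wakefulness), `N`
(NREM sleep) or `R` (REM sleep), with per-epoch artifact and missing
flags. Conventions, fixed package-wide:

* **Zeitgeber time.** Hour 1 is the first hour after light onset; the
  light period is hours 1–12 and the dark period hours 13–24. All
  user-facing windows are closed hour ranges; internally epochs are
  0-based half-open ranges.
* **Artifacts vs missing.** Artifact epochs keep their scored state and
  count toward time-in-state, bout and latency computations; they are
  excluded only from spectral averaging. Missing (unrecorded) epochs
  invalidate their containing hour — an hour without a full 900 recorded
  epochs is flagged invalid and excluded downstream — but never the rest
  of the recording.
* **Bouts.** A bout is a maximal run of one state; a bout belongs to the
  time block containing its *start* epoch, which avoids double counting
  across block boundaries. The minimum bout length for architecture
  counts is one epoch (configurable); the duration criteria apply only to
  sleep-onset latency.
* **Sleep-onset latency.** Latency from a reference hour is the time to
  the *start* of the first run of at least 7 consecutive NREM epochs
  (≥ 28 s) or 4 consecutive REM epochs (≥ 16 s). Sub-threshold runs are
  skipped. REM latency is measured independently of whether NREM precedes
  the qualifying REM run. A recording that never reaches criterion
  returns an explicit "not reached" (`NA`), never a silent maximum.

# EEG spectral analysis

Spectra live on a fixed grid: sampling at 200 Hz, 256-sample transform
windows, hence a bin width of 200/256 = 0.78125 Hz (printed as 0.781) and
usable bins *k* = 1…25 spanning 0.78–19.53 Hz; DC is excluded. Within each
800-sample epoch, `epochPSD()` averages tapered 256-sample segments at 50%
overlap (Welch's method; hann taper by default). The scoring software that
produced the original spectra documents only an FFT at this resolution, so
taper and overlap are exposed in `spectralConfig()` rather than hard-coded;
the estimator is normalized so that power integrates to signal variance
(Parseval), which the tests verify on white noise. An on-bin sinusoid
concentrates entirely in its bin only for the untapered (boxcar) window —
the hann taper spreads ~⅓ of the power into the two adjacent bins — which
is why the concentration test runs with `taper = "boxcar"`.

Bands map to bins by center inclusion: delta 0.5–4 Hz → bins 1–5, theta
5–9 Hz → bins 7–11, alpha 10–15 Hz → bins 13–19. Spectra are carried in
linear power units of arbitrary scale; both normalization schemes cancel
the units:

1. **State total power.** A state's period-specific mean spectrum is
   expressed as a percentage of its own summed power over the same
   baseline period (light or dark), so it sums to exactly 100
   (`normalizeStateTotalPower()`).
2. **Baseline window.** Post-deprivation quantities are normalized to the
   last 4 h of the baseline light period (hours 9–12): hourly NREM delta
   power as a percentage of the baseline delta level
   (`deltaTimecourse()`), and per-bin recovery spectra as percentages of
   the corresponding baseline bins (`recoverySpectrumNormalized()`), with
   zero-power baseline bins flagged rather than dropped.

A numerical choice worth stating: the baseline delta level is the average
of the window's *hourly* NREM delta means, not the pooled epoch mean.
With unequal NREM epoch counts per hour the two differ slightly; the
hourly-mean definition makes the self-normalization identity exact (the
normalization window itself averages 100).

# Sleep-deprivation homeostasis

`runHomeostasis()` assembles, per subject, deprivation efficacy (percent
wakefulness over hours 1–5), NREM/REM onset latencies from release at
hour 6, time in state over the recovery windows (hours 6–7, 8–12, 11–12,
6–24), and the normalized hourly delta timecourse.

`compareGroupSpectra()` implements the gate-then-per-bin logic used for
group spectral contrasts: a test on total spectral power gates the per-bin
tests (with two groups the one-way gate is equivalent to a two-sample
test), and per-bin p-values receive Benjamini–Hochberg adjustment.
Contiguous significant bins are reported as Hz ranges; isolated bins as
one-bin ranges. The Welch (unequal-variance) t-form is the default
throughout because fractional degrees of freedom are the norm in this
literature; the pooled form is available behind a flag. Group contrasts
use the normalized 2-h window means (e.g. hours 6–7) rather than pooled
light-period hours.

# Circadian wheel-running analysis

Wheel revolutions are analyzed in 10-min bins. The chi-squared
periodogram evaluates candidate periods *P* restricted to integer bin
multiples (no sub-bin interpolation; default 20–28 h in 10-min steps).
For each candidate the series is truncated to *K* complete cycles
(*K* ≥ 2; candidates with fewer are skipped with a warning), folded to a
*K* × *P* array with column means *M\_h* and grand mean *M̄*, and

Qp = K · Σ\_h (M\_h − M̄)² / [ (1/N) · Σ\_i (x\_i − M̄)² ],  N = K·P.

Under the null Qp is referenced to a chi-square with *P* − 1 degrees of
freedom; the significance line is the pointwise 0.95 quantile (a
Bonferroni option over candidates exists but is off by default, matching
common practice). The peak is the candidate maximizing Qp minus the
significance line. Monte-Carlo tests confirm the pointwise exceedance
rate on white noise is ≈ 5% and that noiseless on-grid periods are
recovered exactly. Periods are reported to 0.1 h. Weeks whose peak fails
the significance line are reported with `periodSignificant = FALSE`, not
dropped — unstable runners are information, not missing data.

Activity onset/offset detection has no public reference definition (the
vendor defaults are proprietary), so the rule is fully parameterized and
stated: the day's threshold is 25% of its 90th-percentile bin count;
onset is the first above-threshold bin that starts a 60-min window with
mean above threshold, preceded by ≥ 4 h of sub-threshold bins (clipped at
the day boundary); offset is symmetric from the day's end. Alpha is
onset-to-offset; weekly activity is mean daily revolutions.

# The synthetic-data module

The generators are pure functions of `(config, seed)`; a master seed fans
out to per-subject streams through a fixed integer recurrence.

**Hypnograms** come from an epoch-level first-order Markov chain with
hour-dependent transition matrices over {W, N, R}, with REM reachable only
from NREM. Rather than tuning transition probabilities by hand, each
hour's matrix is constructed *analytically* from a target stationary
occupancy π and mean wake/REM bout durations, using flow balance; the
target π is therefore exact ground truth for time-in-state recovery. The
defaults encode the usual baseline architecture of a wild-type mouse:
π = (0.37, 0.52, 0.11) in the light period (63% total sleep time) and
π = (0.713, 0.235, 0.052) in the dark (≈ 29%), mean wake bouts of 90 s
(light) / 240 s (dark) and mean REM bouts of 60 s. A first-order chain
produces geometric (memoryless) bout lengths — adequate for testing the
analysis stages, but its first-passage times are near-exponential
(coefficient of variation ≈ 1), more dispersed than real sleep-onset
latencies. Two consequences are documented rather than hidden: simulated
latency distributions have heavier tails than real ones, and detecting a
2× onset-delay shift at 80% power needs ~50 subjects per group in the
Monte-Carlo power check (a pilot run gave Cohen's d ≈ 0.6; real cohorts
of 10 can succeed because real latencies are less dispersed). Other
deliberately unmodelled features of real data: semi-Markov dwell
structure, waveform morphology (spindles, transients), torpor, and
estrous effects. Passing recovery tests therefore show the *analysis* is
correct, not that the generator is a biophysical model.

**Sleep deprivation** forces hours 1–5 to wakefulness with independent
per-epoch sleep leaks (default probability 0.03, reproducing the 95–97%
efficacy typical of gentle handling) and re-simulates recovery from hour
6. Knobs: `onsetDelayGain` scales wake-bout durations post-release (a
sleep-onset deficit), `reboundDeltaGain`/`reboundTauH` shape the NREM
delta rebound applied by the EEG simulator as an hourly-stepped
exponential decay — exactly the configured gain in the first recovery
hour — and `postSdBroadbandGain` reproduces a transient broadband
(≥ 3.9 Hz) enhancement in the first two recovery hours.

**EEG spectra** are state templates (NREM: 1/f plus a delta bump; REM: a
theta peak; wake: broadband 1/f) under log-normal per-epoch and per-bin
multiplicative noise; signals, when requested, are synthesized by
random-phase spectral shaping so that `epochPSD()` recovers the template.

**Wheel counts** are Poisson around a daily active window: anchored at
dark onset under LD, drifting at the intrinsic period τ under DD, with a
weekly amplitude decay knob for unstable runners. Defaults (600
counts/bin over a 10-h alpha ≈ 36 000 revolutions/day) match a vigorous
wild-type runner.

# Statistical primitives

`welchT()` (Welch–Satterthwaite df), `bhAdjust()` (step-up FDR),
`smoothWithCI()` (penalized cubic regression spline, basis dimension 20,
smoothing chosen by generalized cross-validation, pointwise 95% CI from
the smoother's standard errors) and `ciNonoverlap()` (maximal grid
intervals where two 95% bands are disjoint — the significance convention
used for smoothed spectra). The basis dimension default of 20 tracks the
"smooth curve" behavior expected for 25-bin spectra without replicating
any specific external implementation. Repeated-measures ANOVA, sphericity
corrections and mixed-effects inference are deliberately out of scope:
the pipeline emits tidy per-subject tables that any statistics
environment can consume.

# Problem sizes used in validation

The shipped tests validate at these scales, chosen to make the checks
statistically meaningful at desk scale: oracle-equivalence comparisons on
1000 random small instances per primitive; periodogram calibration on
1000 white-noise series of 21 days; period recovery for τ ∈ {23.5, 23.7,
24.0} over 100 seeds each (±1 candidate step, ≥ 95% required); null
calibration of the group spectral comparison over 1000 replicates with
n = 5 per group; and cohorts of 8–20 simulated subjects for the
entrainment and efficacy checks.

# Worked example

```{r example, eval = FALSE}
cfg <- sleepSimConfig()
baseHyp <- simulateHypnogram(cfg, seed = 1)
sdHyp <- applySleepDeprivation(baseHyp, cfg, seed = 2)
tmpl <- eegTemplates()
baseSpec <- simulateEEG(baseHyp, tmpl, seed = 3)
sdSpec <- simulateEEG(sdHyp, tmpl, seed = 4)
report <- runHomeostasis(list(hyp = baseHyp, spec = baseSpec),
                         list(hyp = sdHyp, spec = sdSpec))
report

ws <- simulateWheel(wheelSimConfig(days = 35,
                                   schedule = c(rep("LD", 14),
                                                rep("DD", 21)),
                                   tauH = 23.7), seed = 5)
weeklySummary(ws)
plotActogram(ws)
```

# Known limitations

* The Markov sleep model has geometric bout-length tails and
  near-exponential onset latencies (see above).
* The onset/offset detector is a stated stand-in for proprietary vendor
  defaults; its parameters are exposed so it can be matched to any
  convention.
* The EDF codec covers plain continuous 16-bit EDF without annotation
  streams.
* Floating-point determinism of reproducibility guarantees holds within a
  fixed platform and BLAS.
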