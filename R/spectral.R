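#' Spectral estimation configuration
#'
#' Defines the epoch power-spectrum estimator: sampling rate, transform
#' window length (the bin width is `samplingRate / windowSamples`; the
#' defaults give 200/256 = 0.78125 Hz, conventionally printed as 0.781 Hz),
#' upper frequency cutoff, taper, and segment overlap. Usable bins are the
#' multiples of the bin width whose centers do not exceed `fMax` (k = 1..25
#' covering 0.78-19.53 Hz under the defaults; DC is excluded).
#'
#' @param samplingRate sampling rate in Hz.
#' @param windowSamples FFT window length in samples.
#' @param fMax upper frequency cutoff in Hz.
#' @param taper `"hann"`, `"hamming"` or `"boxcar"`.
#' @param overlapFraction fractional overlap between successive segments.
#' @return list with class `"SpectralConfig"`; includes `binWidthHz` and the
#'   `binHz` grid of usable bin centers.
#' @export
spectralConfig <- function(samplingRate = 200, windowSamples = 256,
                           fMax = 20, taper = c("hann", "hamming", "boxcar"),
                           overlapFraction = 0.5) {
  taper <- match.arg(taper)
  stopifnot(samplingRate > 0, windowSamples > 1,
            overlapFraction >= 0, overlapFraction < 1)
  bw <- samplingRate / windowSamples
  kMax <- min(floor(fMax / bw + 1e-9), windowSamples %/% 2)
  structure(list(samplingRate = samplingRate,
                 windowSamples = as.integer(windowSamples),
                 fMax = fMax, taper = taper,
                 overlapFraction = overlapFraction,
                 binWidthHz = bw,
                 binHz = (1:kMax) * bw),
            class = "SpectralConfig")
}

taperWindow <- function(n, taper) {
  t <- 0:(n - 1)
  switch(taper,
         hann = 0.5 - 0.5 * cos(2 * pi * t / (n - 1)),
         hamming = 0.54 - 0.46 * cos(2 * pi * t / (n - 1)),
         boxcar = rep(1, n))
}

#' Power spectrum of one EEG epoch
#'
#' Averaged modified periodogram (Welch) estimate for a single epoch:
#' the epoch is split into `windowSamples`-sample segments at the configured
#' overlap, each segment is demeaned, tapered and transformed, and the
#' one-sided power densities are averaged. The result is reported on the
#' usable bin grid (centers `k * binWidth`, truncated at `fMax`). With the
#' taper-power normalization used here, the power integrates to the signal
#' variance (Parseval) when `fMax` spans the full band.
#'
#' @param segment numeric vector of samples (one epoch, e.g. 800 samples of
#'   a 4-s epoch at 200 Hz). `NaN`/`NA` samples make the epoch an artifact:
#'   the function returns all-`NA` with attribute `artifact = TRUE`.
#' @param cfg a [spectralConfig()].
#' @return named numeric vector of power density per usable bin.
#' @export
epochPSD <- function(segment, cfg = spectralConfig()) {
  n <- cfg$windowSamples
  if (length(segment) < n)
    stop(sprintf("segment too short: %d samples, need at least %d",
                 length(segment), n))
  if (anyNA(segment) || any(is.nan(segment))) {
    out <- rep(NA_real_, length(cfg$binHz))
    names(out) <- sprintf("%.3f", cfg$binHz)
    attr(out, "artifact") <- TRUE
    return(out)
  }
  step <- max(1L, as.integer(round(n * (1 - cfg$overlapFraction))))
  starts <- seq.int(1L, length(segment) - n + 1L, by = step)
  w <- taperWindow(n, cfg$taper)
  U <- sum(w^2)
  acc <- numeric(n %/% 2)
  for (s in starts) {
    x <- segment[s:(s + n - 1L)]
    x <- (x - mean(x)) * w
    X <- stats::fft(x)
    p <- Mod(X[2:(n %/% 2 + 1L)])^2  # bins k = 1 .. n/2
    p <- 2 * p / (cfg$samplingRate * U)
    p[n %/% 2] <- p[n %/% 2] / 2     # no doubling at Nyquist
    acc <- acc + p
  }
  acc <- acc / length(starts)
  out <- acc[seq_along(cfg$binHz)]
  names(out) <- sprintf("%.3f", cfg$binHz)
  attr(out, "artifact") <- FALSE
  out
}

#' Construct a SpectralSeries
#'
#' @param power epochs x bins matrix of non-negative power values.
#' @param binHz bin center frequencies in Hz.
#' @param artifact per-epoch artifact flags (default all `FALSE`).
#' @return a [SpectralSeries-class].
#' @export
SpectralSeries <- function(power, binHz, artifact = NULL) {
  power <- as.matrix(power)
  if (is.null(artifact)) artifact <- rep(FALSE, nrow(power))
  new("SpectralSeries", power = power, binHz = as.numeric(binHz),
      artifact = as.logical(artifact))
}

#' @rdname nEpochs
#' @export
setMethod("nEpochs", "SpectralSeries", function(x) nrow(x@power))

#' @rdname isArtifact
#' @export
setMethod("isArtifact", "SpectralSeries", function(x) x@artifact)

#' Bin center frequencies of a SpectralSeries
#' @param x a [SpectralSeries-class].
#' @return numeric vector in Hz.
#' @export
binFrequencies <- function(x) x@binHz

#' Per-epoch power matrix of a SpectralSeries
#' @param x a [SpectralSeries-class].
#' @return epochs x bins numeric matrix.
#' @export
powerMatrix <- function(x) x@power

setMethod("show", "SpectralSeries", function(object) {
  cat(sprintf(
    "SpectralSeries: %d epochs x %d bins (%.3f-%.3f Hz), %d artifact epochs\n",
    nrow(object@power), ncol(object@power), min(object@binHz),
    max(object@binHz), sum(object@artifact)))
})

#' Per-epoch spectra from a continuous EEG signal
#'
#' Splits a continuous signal into epochs aligned with a hypnogram and runs
#' [epochPSD()] on each. Epochs containing `NaN` samples are auto-flagged
#' artifact (all-`NA` spectrum).
#'
#' @param signal numeric vector, `nEpochs(hyp) * epochLength(hyp) *
#'   samplingRate` samples.
#' @param hyp the paired [Hypnogram-class].
#' @param cfg a [spectralConfig()].
#' @return a [SpectralSeries-class].
#' @export
computeSpectralSeries <- function(signal, hyp, cfg = spectralConfig()) {
  spe <- as.integer(round(hyp@epochLengthS * cfg$samplingRate))
  need <- nEpochs(hyp) * spe
  if (length(signal) != need)
    stop(sprintf("signal has %d samples, expected %d", length(signal), need))
  n <- nEpochs(hyp)
  power <- matrix(NA_real_, n, length(cfg$binHz))
  artifact <- logical(n)
  for (i in seq_len(n)) {
    p <- epochPSD(signal[((i - 1L) * spe + 1L):(i * spe)], cfg)
    power[i, ] <- p
    artifact[i] <- isTRUE(attr(p, "artifact"))
  }
  SpectralSeries(power, cfg$binHz, artifact)
}

## ---- bands ----

#' Frequency band definition
#'
#' Maps a nominal band in Hz to spectral bins by bin-center inclusion:
#' member bins are those whose centers fall in `[loHz, hiHz]`. Under the
#' default 0.78125-Hz grid the conventional bands resolve to delta
#' (0.5-4 Hz) = bins 1-5, theta (5-9 Hz) = bins 7-11, alpha (10-15 Hz) =
#' bins 13-19.
#'
#' @param name band name.
#' @param loHz,hiHz band edges in Hz (closed interval).
#' @param binHz bin center grid.
#' @return list with class `"BandDefinition"` including `bins`, the member
#'   bin indices.
#' @export
bandDefinition <- function(name, loHz, hiHz,
                           binHz = spectralConfig()$binHz) {
  stopifnot(loHz < hiHz)
  bins <- which(binHz >= loHz - 1e-9 & binHz <= hiHz + 1e-9)
  if (!length(bins)) stop("band contains no bins")
  structure(list(name = name, loHz = loHz, hiHz = hiHz, bins = bins,
                 binHz = binHz[bins]),
            class = "BandDefinition")
}

#' Conventional EEG bands on a bin grid
#'
#' @param binHz bin center grid.
#' @return named list of [bandDefinition()]s: delta (0.5-4 Hz),
#'   theta (5-9 Hz), alpha (10-15 Hz).
#' @export
defaultBands <- function(binHz = spectralConfig()$binHz) {
  list(delta = bandDefinition("delta", 0.5, 4, binHz),
       theta = bandDefinition("theta", 5, 9, binHz),
       alpha = bandDefinition("alpha", 10, 15, binHz))
}

#' Band power of a spectrum
#'
#' @param spectrum numeric power vector on the band's bin grid.
#' @param band a [bandDefinition()].
#' @return sum of member-bin powers.
#' @export
bandPower <- function(spectrum, band) {
  sum(spectrum[band$bins])
}

## ---- aggregation & normalization ----

qualifyingEpochs <- function(spec, hyp, state, windowHours = NULL) {
  if (nEpochs(spec) != nEpochs(hyp))
    stop("spectral series and hypnogram have different epoch counts")
  ok <- !hyp@artifact & !spec@artifact & !hyp@missing &
    !is.na(hyp@states) & hyp@states == state
  if (!is.null(windowHours)) {
    inWin <- logical(nEpochs(hyp))
    inWin[ztHourEpochs(hyp, windowHours)] <- TRUE
    ok <- ok & inWin
  }
  which(ok)
}

#' State-specific mean spectrum
#'
#' Mean power spectrum over non-artifact, non-missing epochs of the given
#' state within an hour window. Artifact-flagged epochs (from either the
#' hypnogram or the spectral series) never contribute.
#'
#' @param spec a [SpectralSeries-class].
#' @param hyp the paired [Hypnogram-class].
#' @param state state code.
#' @param windowHours closed zeitgeber-hour range, or `NULL` for the whole
#'   recording.
#' @return list with `spectrum` (numeric vector; all-`NA` when no epoch
#'   qualifies) and `nEpochs` (count used).
#' @export
stateMeanSpectrum <- function(spec, hyp, state, windowHours = NULL) {
  idx <- qualifyingEpochs(spec, hyp, state, windowHours)
  if (!length(idx))
    return(list(spectrum = rep(NA_real_, ncol(spec@power)), nEpochs = 0L))
  list(spectrum = colMeans(spec@power[idx, , drop = FALSE]),
       nEpochs = length(idx))
}

#' Normalize a spectrum to a total-power reference
#'
#' Each bin is expressed as a percentage of the summed reference spectrum;
#' with the default `reference = spectrum` the output sums to exactly 100.
#'
#' @param spectrum numeric power vector.
#' @param reference numeric power vector whose sum is the denominator.
#' @return percent spectrum.
#' @export
normalizeSpectrum <- function(spectrum, reference = spectrum) {
  tot <- sum(reference)
  if (!is.finite(tot) || tot <= 0) stop("zero or invalid total power")
  100 * spectrum / tot
}

#' State-specific spectrum as percent of state total power
#'
#' The period-specific state mean spectrum expressed as a percentage of the
#' sum of that state's total power over the same baseline period (light
#' hours 1-12 or dark hours 13-24), so the output sums to 100.
#'
#' @param spec a [SpectralSeries-class].
#' @param hyp the paired [Hypnogram-class].
#' @param state state code.
#' @param period `"light"` or `"dark"` (or a two-element hour range).
#' @return percent spectrum summing to 100.
#' @export
normalizeStateTotalPower <- function(spec, hyp, state,
                                     period = c("light", "dark")) {
  hours <- resolvePeriod(if (is.character(period)) match.arg(period)
                         else period)
  m <- stateMeanSpectrum(spec, hyp, state, hours)
  if (m$nEpochs == 0L) stop("no qualifying epochs in period")
  normalizeSpectrum(m$spectrum)
}

#' Hourly NREM delta power normalized to a baseline window
#'
#' Per-hour mean NREM delta-band power expressed as a percentage of the
#' baseline delta level, defined as the average of the hourly NREM delta
#' means across the normalization window (default the last 4 h of the
#' baseline light period, hours 9-12), so the window itself averages
#' exactly 100. The baseline may come from
#' a different (same-subject) recording, e.g. the undisturbed day preceding
#' a sleep-deprivation day. Hours without qualifying NREM epochs yield `NA`.
#'
#' @param spec,hyp the recording to express hourly.
#' @param baselineSpec,baselineHyp the recording supplying the baseline
#'   window (defaults: the same recording).
#' @param band delta [bandDefinition()].
#' @param baselineWindow closed hour range of the normalization window.
#' @return data.frame with `hour`, `deltaPct`, `nEpochs`.
#' @export
deltaTimecourse <- function(spec, hyp, baselineSpec = spec,
                            baselineHyp = hyp,
                            band = defaultBands(binFrequencies(spec))$delta,
                            baselineWindow = c(9, 12)) {
  ## baseline = average of the window's hourly NREM delta means, so the
  ## normalization window itself averages exactly 100
  baseHourly <- vapply(baselineWindow[1L]:baselineWindow[2L], function(zt) {
    idx <- qualifyingEpochs(baselineSpec, baselineHyp, "N", c(zt, zt))
    if (!length(idx)) return(NA_real_)
    mean(rowSums(baselineSpec@power[idx, band$bins, drop = FALSE]))
  }, 0)
  if (all(is.na(baseHourly)))
    stop("no NREM epochs in the baseline normalization window")
  baseDelta <- mean(baseHourly, na.rm = TRUE)
  eph <- epochsPerHour(hyp)
  hourIdx <- (seq_len(nEpochs(hyp)) - 1L) %/% eph
  hours <- sort(unique(hourIdx))
  res <- lapply(hours, function(h) {
    zt <- hyp@ztStartHour + h
    idx <- qualifyingEpochs(spec, hyp, "N", c(zt, zt))
    val <- if (length(idx))
      100 * mean(rowSums(spec@power[idx, band$bins, drop = FALSE])) / baseDelta
    else NA_real_
    data.frame(hour = zt, deltaPct = val, nEpochs = length(idx))
  })
  do.call(rbind, res)
}

#' Recovery spectrum as percent of baseline, bin by bin
#'
#' Per-bin ratio (x100) of the window NREM mean spectrum on the
#' sleep-deprivation day to the baseline NREM mean spectrum from the
#' normalization window (default hours 9-12 of the baseline light period).
#' Bins with zero baseline power are flagged (returned `NA`, listed in the
#' `"flaggedBins"` attribute) rather than silently dropped.
#'
#' @param specSd,hypSd sleep-deprivation-day recording.
#' @param specBase,hypBase baseline recording (same subject).
#' @param windowHours closed hour range on the SD day (default hours 6-7,
#'   the first 2 h of recovery).
#' @param baselineWindow closed hour range on the baseline day.
#' @param state state whose spectra are compared (default `"N"`).
#' @return numeric percent-of-baseline vector per bin.
#' @export
recoverySpectrumNormalized <- function(specSd, hypSd, specBase, hypBase,
                                       windowHours = c(6, 7),
                                       baselineWindow = c(9, 12),
                                       state = "N") {
  sd <- stateMeanSpectrum(specSd, hypSd, state, windowHours)
  base <- stateMeanSpectrum(specBase, hypBase, state, baselineWindow)
  if (sd$nEpochs == 0L) stop("no qualifying epochs in the recovery window")
  if (base$nEpochs == 0L) stop("no qualifying epochs in the baseline window")
  zero <- which(!is.na(base$spectrum) & base$spectrum == 0)
  out <- 100 * sd$spectrum / base$spectrum
  if (length(zero)) {
    out[zero] <- NA_real_
    warning(sprintf("%d baseline bin(s) with zero power flagged", length(zero)))
  }
  attr(out, "flaggedBins") <- zero
  attr(out, "nEpochs") <- c(window = sd$nEpochs, baseline = base$nEpochs)
  out
}
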