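#' @import methods
NULL

STATE_CODES <- c("W", "N", "R")

#' Hypnogram: an epoch-scored vigilance-state sequence
#'
#' Container for an epoch-scored sleep recording. Each epoch (default 4 s)
#' carries one of the vigilance states `"W"` (wakefulness), `"N"` (NREM
#' sleep) or `"R"` (REM sleep), an artifact flag, and a missing flag for
#' unrecorded epochs (state `NA`). The recording is aligned to zeitgeber
#' time: `ztStartHour` is the zeitgeber hour of the first epoch, with hour 1
#' defined as the first hour after light onset.
#'
#' Artifact-flagged epochs keep their scored state and count toward
#' time-in-state, bout and latency computations; they are excluded only from
#' spectral averaging. Missing epochs invalidate their containing zeitgeber
#' hour but not the rest of the recording.
#'
#' @slot states character vector of state codes (`NA` where missing).
#' @slot artifact logical per-epoch artifact flag.
#' @slot missing logical per-epoch missing (unrecorded) flag.
#' @slot epochLengthS epoch duration in seconds (default 4).
#' @slot ztStartHour zeitgeber hour of the first epoch (hour 1 = first hour
#'   after light onset).
#'
#' @seealso [Hypnogram()], [validateHypnogram()], [segmentBouts()],
#'   [timeInStateHourly()]
#' @export
setClass("Hypnogram",
  slots = c(
    states = "character",
    artifact = "logical",
    missing = "logical",
    epochLengthS = "numeric",
    ztStartHour = "numeric"
  )
)

setValidity("Hypnogram", function(object) {
  n <- length(object@states)
  msgs <- character(0)
  if (n == 0L) msgs <- c(msgs, "hypnogram must contain at least one epoch")
  if (length(object@artifact) != n || length(object@missing) != n)
    msgs <- c(msgs, "artifact and missing flags must have one entry per epoch")
  if (length(object@epochLengthS) != 1L || !is.finite(object@epochLengthS) ||
      object@epochLengthS <= 0)
    msgs <- c(msgs, "epochLengthS must be a single positive number")
  if (length(object@ztStartHour) != 1L || !is.finite(object@ztStartHour))
    msgs <- c(msgs, "ztStartHour must be a single finite number")
  bad <- !is.na(object@states) & !(object@states %in% STATE_CODES)
  if (any(bad)) {
    msgs <- c(msgs, sprintf(
      "unknown state code '%s' at epoch %d (0-based)",
      object@states[which(bad)[1L]], which(bad)[1L] - 1L))
  }
  if (length(object@missing) == n &&
      any(is.na(object@states) & !object@missing))
    msgs <- c(msgs, "NA states are only allowed for epochs flagged missing")
  if (length(msgs)) msgs else TRUE
})

#' SpectralSeries: per-epoch EEG power spectra on a fixed bin grid
#'
#' Power spectra for every epoch of a paired [Hypnogram-class], on a fixed
#' grid of frequency-bin centers (default multiples of 200/256 = 0.78125 Hz,
#' truncated at 20 Hz). Power units are arbitrary but must be consistent
#' within a recording; all downstream normalizations cancel them. Carries
#' its own artifact mask (e.g. epochs auto-flagged for NaN samples), which is
#' OR-combined with the hypnogram's mask during aggregation.
#'
#' @slot power numeric matrix, epochs x bins, non-negative (NA for artifact
#'   epochs whose spectra could not be computed).
#' @slot binHz numeric vector of bin center frequencies in Hz.
#' @slot artifact logical per-epoch artifact flag.
#'
#' @seealso [computeSpectralSeries()], [stateMeanSpectrum()]
#' @export
setClass("SpectralSeries",
  slots = c(
    power = "matrix",
    binHz = "numeric",
    artifact = "logical"
  )
)

setValidity("SpectralSeries", function(object) {
  msgs <- character(0)
  if (ncol(object@power) != length(object@binHz))
    msgs <- c(msgs, "power must have one column per frequency bin")
  if (nrow(object@power) != length(object@artifact))
    msgs <- c(msgs, "artifact must have one entry per epoch")
  if (any(object@power < 0, na.rm = TRUE))
    msgs <- c(msgs, "power must be non-negative")
  if (is.unsorted(object@binHz, strictly = TRUE))
    msgs <- c(msgs, "binHz must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

#' WheelSeries: wheel-running counts in fixed-width time bins
#'
#' Wheel revolutions per 10-min bin (bin width configurable), with a per-day
#' lighting schedule (`"LD"` for a 12:12 light:dark day, `"DD"` for constant
#' darkness). Time 0 is lights-on of the first day; under LD, dark onset is
#' at hour 12 of each day.
#'
#' @slot counts numeric vector of non-negative counts, one per bin.
#' @slot binMin bin width in minutes (default 10).
#' @slot schedule character vector, one of `"LD"`/`"DD"` per day.
#' @slot t0Hour clock time (hours after lights-on of day 1) of the first bin.
#'
#' @seealso [simulateWheel()], [chiSquaredPeriodogram()], [buildActogram()]
#' @export
setClass("WheelSeries",
  slots = c(
    counts = "numeric",
    binMin = "numeric",
    schedule = "character",
    t0Hour = "numeric"
  )
)

setValidity("WheelSeries", function(object) {
  msgs <- character(0)
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msgs <- c(msgs, "counts must be finite and non-negative")
  if (length(object@binMin) != 1L || object@binMin <= 0)
    msgs <- c(msgs, "binMin must be a single positive number")
  bpd <- 24 * 60 / object@binMin
  if (length(object@counts) %% bpd != 0)
    msgs <- c(msgs, "counts must cover whole days")
  else if (length(object@schedule) != length(object@counts) / bpd)
    msgs <- c(msgs, "schedule must have one entry per day")
  if (!all(object@schedule %in% c("LD", "DD")))
    msgs <- c(msgs, "schedule entries must be 'LD' or 'DD'")
  if (length(msgs)) msgs else TRUE
})

#' PeriodogramResult: chi-squared periodogram of an activity series
#'
#' Result of the Sokolove-Bushell chi-squared periodogram: the Qp statistic
#' over a grid of candidate periods (integer multiples of the bin width),
#' the per-candidate chi-square 0.05 significance line, and the peak period
#' (the candidate maximizing Qp minus the significance line).
#'
#' @slot periodsH candidate periods in hours.
#' @slot qp Qp statistic per candidate.
#' @slot df chi-square degrees of freedom per candidate (bins per period - 1).
#' @slot sigLine chi-square 0.95 quantile per candidate.
#' @slot peakPeriodH peak period in hours.
#' @slot peakSignificant whether Qp at the peak exceeds the significance line.
#'
#' @seealso [chiSquaredPeriodogram()]
#' @export
setClass("PeriodogramResult",
  slots = c(
    periodsH = "numeric",
    qp = "numeric",
    df = "numeric",
    sigLine = "numeric",
    peakPeriodH = "numeric",
    peakSignificant = "logical"
  )
)

setValidity("PeriodogramResult", function(object) {
  msgs <- character(0)
  nc <- length(object@periodsH)
  if (length(object@qp) != nc || length(object@df) != nc ||
      length(object@sigLine) != nc)
    msgs <- c(msgs, "qp, df and sigLine must align with periodsH")
  if (any(object@qp < 0, na.rm = TRUE))
    msgs <- c(msgs, "Qp must be non-negative")
  if (length(object@peakPeriodH) == 1L && !is.na(object@peakPeriodH) &&
      (object@peakPeriodH < min(object@periodsH) - 1e-9 ||
       object@peakPeriodH > max(object@periodsH) + 1e-9))
    msgs <- c(msgs, "peak period must lie within the candidate range")
  if (length(msgs)) msgs else TRUE
})
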