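#' Number of epochs in a recording
#' @param x a [Hypnogram-class] or [SpectralSeries-class].
#' @return integer epoch count.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' Epoch state codes
#' @param x a [Hypnogram-class].
#' @return character vector of `"W"`/`"N"`/`"R"` (NA where missing).
#' @export
setGeneric("epochStates", function(x) standardGeneric("epochStates"))

#' Per-epoch artifact flags
#' @param x a [Hypnogram-class] or [SpectralSeries-class].
#' @return logical vector.
#' @export
setGeneric("isArtifact", function(x) standardGeneric("isArtifact"))

#' Per-epoch missing (unrecorded) flags
#' @param x a [Hypnogram-class].
#' @return logical vector.
#' @export
setGeneric("isMissing", function(x) standardGeneric("isMissing"))

#' Epoch length in seconds
#' @param x a [Hypnogram-class].
#' @return numeric scalar.
#' @export
setGeneric("epochLength", function(x) standardGeneric("epochLength"))

#' Zeitgeber hour of the first epoch
#' @param x a [Hypnogram-class].
#' @return numeric scalar (hour 1 = first hour after light onset).
#' @export
setGeneric("ztStart", function(x) standardGeneric("ztStart"))

#' Segment a hypnogram into bouts
#'
#' A bout is a maximal run of consecutive epochs in one state. Gaps of
#' missing epochs form their own runs with state `NA`, so the returned bouts
#' always tile the recording exactly.
#'
#' @param x a [Hypnogram-class].
#' @return data.frame with columns `state`, `startEpoch` (0-based),
#'   `nEpochs`, `durationS`.
#' @export
setGeneric("segmentBouts", function(x) standardGeneric("segmentBouts"))

#' Hourly time-in-state table
#'
#' Percent of recorded time per zeitgeber hour spent in each state. Hours
#' containing any missing epoch, or not fully covered by the recording, are
#' flagged invalid and should be excluded downstream.
#'
#' @param x a [Hypnogram-class].
#' @return data.frame with columns `hour`, `pctW`, `pctN`, `pctR`,
#'   `nEpochs`, `valid`.
#' @export
setGeneric("timeInStateHourly", function(x) standardGeneric("timeInStateHourly"))

#' Total sleep time over a period
#'
#' Percent of recorded time spent asleep (NREM + REM) over a zeitgeber-hour
#' period, computed over the period's valid hours.
#'
#' @param x a [Hypnogram-class].
#' @param period `"light"` (hours 1-12), `"dark"` (hours 13-24), or a
#'   two-element closed hour range.
#' @return percent (0-100).
#' @export
setGeneric("totalSleepTime", function(x, period = "light")
  standardGeneric("totalSleepTime"))

#' Bout counts and mean durations by time block
#'
#' Splits the 24-h day into equal blocks (default 6 h) and summarizes bout
#' number and mean bout duration per state per block. A bout is assigned to
#' the block containing its start epoch, so bouts spanning block boundaries
#' are counted once.
#'
#' @param x a [Hypnogram-class].
#' @param blockHours block width in hours; must divide 24.
#' @param minEpochs minimum bout length (epochs) to include; default 1.
#' @return data.frame with columns `block`, `hourFrom`, `hourTo`, `state`,
#'   `nBouts`, `meanDurationS`.
#' @export
setGeneric("boutStatsByBlock", function(x, blockHours = 6, minEpochs = 1L)
  standardGeneric("boutStatsByBlock"))

#' Latency from a reference time to sleep onset
#'
#' Seconds elapsed from the start of zeitgeber hour `t0Hour` to the start of
#' the first run of at least the criterion number of consecutive epochs of
#' the target state. Runs shorter than the criterion are skipped. The
#' defaults encode the usual onset criteria: NREM bout >= 28 s (7 epochs of
#' 4 s) and REM bout >= 16 s (4 epochs).
#'
#' @param x a [Hypnogram-class].
#' @param t0Hour zeitgeber hour at which the clock starts.
#' @param state target state, `"N"` or `"R"`.
#' @param criteria a [latencyCriteria()] list.
#' @return latency in seconds, or `NA` with attribute `reached = FALSE` if
#'   no qualifying run occurs before the end of the recording.
#' @export
setGeneric("latencyToState",
  function(x, t0Hour, state = c("N", "R"), criteria = latencyCriteria())
    standardGeneric("latencyToState"))

#' Percent wakefulness over an hour window
#'
#' @param x a [Hypnogram-class].
#' @param windowHours closed zeitgeber-hour range, e.g. `c(1, 5)`.
#' @return percent of recorded epochs in the window scored `"W"`.
#' @export
setGeneric("wakePercentage", function(x, windowHours)
  standardGeneric("wakePercentage"))

#' Chi-squared periodogram (Sokolove-Bushell)
#'
#' @param x a [WheelSeries-class] (or numeric vector of counts).
#' @param pMinH,pMaxH candidate period range in hours.
#' @param alpha pointwise significance level for the chi-square line.
#' @param dayRange optional two-element day range (1-based, inclusive) to
#'   restrict the analysis to.
#' @return a [PeriodogramResult-class].
#' @export
setGeneric("chiSquaredPeriodogram",
  function(x, pMinH = 20, pMaxH = 28, alpha = 0.05, dayRange = NULL)
    standardGeneric("chiSquaredPeriodogram"))

#' Build an actogram matrix
#'
#' @param x a [WheelSeries-class].
#' @param doublePlotted if `TRUE`, row r is the concatenation of day r and
#'   day r+1 (the conventional double-plotted actogram); the final row pads
#'   the absent next day with `NA`.
#' @param moduloH row length in hours (default 24).
#' @return numeric matrix, days x bins (or days x 2*bins if double-plotted).
#' @export
setGeneric("buildActogram",
  function(x, doublePlotted = FALSE, moduloH = 24)
    standardGeneric("buildActogram"))
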