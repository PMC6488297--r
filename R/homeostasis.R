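#' Protocol hour windows for a sleep-deprivation experiment
#'
#' The standard window layout, in closed zeitgeber-hour ranges: enforced
#' wakefulness over hours 1-5, full recovery hours 6-24, first two recovery
#' hours 6-7, remaining light-period recovery hours 8-12, end of the light
#' period hours 11-12, and the baseline normalization window hours 9-12
#' (the last 4 h of the baseline light period).
#'
#' @param sd,recoveryFull,recoveryFirst closed hour ranges.
#' @param recoveryRestLight,lightEnd,baselineNorm closed hour ranges.
#' @return list with class `"ProtocolWindows"`.
#' @export
protocolWindows <- function(sd = c(1, 5), recoveryFull = c(6, 24),
                            recoveryFirst = c(6, 7),
                            recoveryRestLight = c(8, 12),
                            lightEnd = c(11, 12),
                            baselineNorm = c(9, 12)) {
  win <- list(sd = sd, recoveryFull = recoveryFull,
              recoveryFirst = recoveryFirst,
              recoveryRestLight = recoveryRestLight,
              lightEnd = lightEnd, baselineNorm = baselineNorm)
  for (w in win) stopifnot(length(w) == 2L, w[1L] <= w[2L],
                           w[1L] >= 1, w[2L] <= 24)
  structure(win, class = "ProtocolWindows")
}

timeInStateWindow <- function(hyp, windowHours) {
  idx <- ztHourEpochs(hyp, windowHours)
  st <- hyp@states[idx]
  st <- st[!is.na(st)]
  if (!length(st)) stop("window contains no recorded epochs")
  vapply(STATE_CODES, function(s) 100 * sum(st == s) / length(st), 0)
}

#' Single-subject sleep-deprivation homeostasis report
#'
#' Assembles, from the core hypnogram and spectral operations, the standard
#' homeostasis read-outs for one subject: deprivation efficacy (percent
#' wakefulness during the enforced-wake window), NREM and REM sleep-onset
#' latencies from release into recovery, percent time in each state over
#' the recovery windows, and the hourly NREM delta-power timecourse
#' normalized to the baseline-day normalization window. An unreached
#' latency is carried as `NA` (never imputed).
#'
#' @param baseline list with elements `hyp` ([Hypnogram-class]) and `spec`
#'   ([SpectralSeries-class]) for the undisturbed baseline day.
#' @param sdDay same-structured list for the sleep-deprivation day.
#' @param windows a [protocolWindows()].
#' @param criteria a [latencyCriteria()].
#' @param subject optional subject label.
#' @return list with class `"HomeostasisReport"`.
#' @export
runHomeostasis <- function(baseline, sdDay, windows = protocolWindows(),
                           criteria = latencyCriteria(), subject = NA) {
  stopifnot(is(baseline$hyp, "Hypnogram"), is(sdDay$hyp, "Hypnogram"))
  t0 <- windows$recoveryFull[1L]
  nLat <- latencyToState(sdDay$hyp, t0, "N", criteria)
  rLat <- latencyToState(sdDay$hyp, t0, "R", criteria)
  winNames <- c("recoveryFirst", "recoveryRestLight", "lightEnd",
                "recoveryFull")
  tis <- do.call(rbind, lapply(winNames, function(w) {
    pct <- timeInStateWindow(sdDay$hyp, windows[[w]])
    data.frame(window = w, hourFrom = windows[[w]][1L],
               hourTo = windows[[w]][2L],
               pctW = pct["W"], pctN = pct["N"], pctR = pct["R"],
               row.names = NULL)
  }))
  delta <- if (!is.null(baseline$spec) && !is.null(sdDay$spec))
    deltaTimecourse(sdDay$spec, sdDay$hyp, baseline$spec, baseline$hyp,
                    baselineWindow = windows$baselineNorm)
  else NULL
  structure(list(
    subject = subject,
    sdWakePercent = wakePercentage(sdDay$hyp, windows$sd),
    nremLatencyS = as.numeric(nLat),
    nremLatencyReached = isTRUE(attr(nLat, "reached")),
    remLatencyS = as.numeric(rLat),
    remLatencyReached = isTRUE(attr(rLat, "reached")),
    timeInState = tis,
    deltaTimecourse = delta,
    windows = windows, criteria = criteria
  ), class = "HomeostasisReport")
}

#' @export
print.HomeostasisReport <- function(x, ...) {
  cat(sprintf("Homeostasis report (subject %s)\n", x$subject))
  cat(sprintf("  SD efficacy: %.2f%% wake\n", x$sdWakePercent))
  cat(sprintf("  NREM latency: %s   REM latency: %s\n",
              if (x$nremLatencyReached) sprintf("%.0f s", x$nremLatencyS)
              else "not reached",
              if (x$remLatencyReached) sprintf("%.0f s", x$remLatencyS)
              else "not reached"))
  invisible(x)
}

#' Tidy table of per-subject homeostasis metrics
#'
#' @param reports list of [runHomeostasis()] results.
#' @return data.frame, one row per subject x metric.
#' @export
homeostasisTable <- function(reports) {
  do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    subj <- if (is.na(r$subject)) i else r$subject
    base <- data.frame(
      subject = subj,
      metric = c("sdWakePercent", "nremLatencyS", "remLatencyS"),
      value = c(r$sdWakePercent, r$nremLatencyS, r$remLatencyS))
    tis <- do.call(rbind, lapply(seq_len(nrow(r$timeInState)), function(j) {
      row <- r$timeInState[j, ]
      data.frame(subject = subj,
                 metric = paste0(row$window, c(".pctW", ".pctN", ".pctR")),
                 value = c(row$pctW, row$pctN, row$pctR))
    }))
    rbind(base, tis)
  }))
}

#' Group comparison of percent-of-baseline spectra
#'
#' Gate-then-per-bin logic: first a two-sample test on total spectral power
#' (with two groups this is the one-way comparison specialized to k = 2);
#' only if the gate is significant are the individual frequency bins
#' compared, with Benjamini-Hochberg adjustment. Contiguous significant
#' bins are reported as Hz ranges (isolated bins as one-bin ranges).
#'
#' @param groupA,groupB numeric matrices, subjects x bins (>= 2 subjects
#'   each), e.g. rows of [recoverySpectrumNormalized()] values.
#' @param binHz bin center frequencies.
#' @param alpha significance level for the gate and the BH-adjusted bins.
#' @param varEqual passed to [welchT()].
#' @return list with `gate` (a `TestResult`), `gated` (logical), `perBin`
#'   (data.frame with per-bin t, p and BH-adjusted p; `NULL` when the gate
#'   is not significant), and `ranges` (data.frame of significant Hz
#'   ranges, zero rows when none).
#' @export
compareGroupSpectra <- function(groupA, groupB,
                                binHz = spectralConfig()$binHz,
                                alpha = 0.05, varEqual = FALSE) {
  groupA <- as.matrix(groupA); groupB <- as.matrix(groupB)
  if (nrow(groupA) < 2 || nrow(groupB) < 2)
    stop("need at least two subjects per group")
  if (ncol(groupA) != length(binHz) || ncol(groupB) != length(binHz))
    stop("spectra do not match the bin grid")
  gate <- welchT(rowSums(groupA), rowSums(groupB), varEqual = varEqual)
  gated <- gate$pValue < alpha
  emptyRanges <- data.frame(fromBin = integer(0), toBin = integer(0),
                            loHz = numeric(0), hiHz = numeric(0))
  if (!gated)
    return(list(gate = gate, gated = FALSE, perBin = NULL,
                ranges = emptyRanges))
  tests <- lapply(seq_along(binHz), function(k)
    welchT(groupA[, k], groupB[, k], varEqual = varEqual))
  perBin <- data.frame(
    bin = seq_along(binHz), binHz = binHz,
    t = vapply(tests, `[[`, 0, "statistic"),
    df = vapply(tests, `[[`, 0, "df"),
    p = vapply(tests, `[[`, 0, "pValue"))
  perBin$pAdj <- bhAdjust(perBin$p)
  sig <- perBin$pAdj < alpha
  runs <- runsToIntervals(sig, binHz)
  ranges <- if (nrow(runs)) data.frame(fromBin = runs$fromIdx,
                                       toBin = runs$toIdx,
                                       loHz = round(runs$from, 1),
                                       hiHz = round(runs$to, 1))
  else emptyRanges
  list(gate = gate, gated = TRUE, perBin = perBin, ranges = ranges)
}
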