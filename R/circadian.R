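#' Construct a WheelSeries
#'
#' @param counts numeric vector of wheel revolutions per bin.
#' @param binMin bin width in minutes (default 10).
#' @param schedule per-day lighting schedule, `"LD"` or `"DD"`; recycled to
#'   the number of days if length 1.
#' @param t0Hour clock time of the first bin, in hours after lights-on of
#'   day 1 (default 0).
#' @return a [WheelSeries-class].
#' @export
WheelSeries <- function(counts, binMin = 10, schedule = "LD", t0Hour = 0) {
  bpd <- 24 * 60 / binMin
  nDays <- length(counts) / bpd
  if (length(schedule) == 1L) schedule <- rep(schedule, ceiling(nDays))
  new("WheelSeries", counts = as.numeric(counts), binMin = binMin,
      schedule = schedule, t0Hour = t0Hour)
}

binsPerDay <- function(x) as.integer(24 * 60 / x@binMin)

#' Number of whole days in a WheelSeries
#' @param x a [WheelSeries-class].
#' @return integer day count.
#' @export
nDays <- function(x) length(x@counts) %/% binsPerDay(x)

#' Counts of a WheelSeries
#' @param x a [WheelSeries-class].
#' @return numeric vector.
#' @export
wheelCounts <- function(x) x@counts

#' Lighting schedule of a WheelSeries
#' @param x a [WheelSeries-class].
#' @return character vector, one entry per day.
#' @export
lightSchedule <- function(x) x@schedule

setMethod("show", "WheelSeries", function(object) {
  bpd <- binsPerDay(object)
  cat(sprintf(
    "WheelSeries: %d days x %d bins of %g min (%d LD, %d DD), %.0f total rev\n",
    length(object@counts) %/% bpd, bpd, object@binMin,
    sum(object@schedule == "LD"), sum(object@schedule == "DD"),
    sum(object@counts)))
})

## ---- chi-squared periodogram ----

## Core statistic on a plain numeric vector; candidate periods in bins.
qpStatistic <- function(counts, pBins) {
  nTot <- length(counts)
  vapply(pBins, function(P) {
    K <- nTot %/% P
    if (K < 2L) return(NA_real_)
    N <- K * P
    x <- counts[seq_len(N)]
    gm <- mean(x)
    denom <- sum((x - gm)^2) / N
    if (denom == 0) stop("constant series: zero variance")
    Mh <- .rowMeans(matrix(x, nrow = P), P, K)
    K * sum((Mh - gm)^2) / denom
  }, 0)
}

#' @rdname chiSquaredPeriodogram
#' @export
setMethod("chiSquaredPeriodogram", "WheelSeries",
          function(x, pMinH = 20, pMaxH = 28, alpha = 0.05, dayRange = NULL) {
  counts <- x@counts
  bpd <- binsPerDay(x)
  if (!is.null(dayRange)) {
    stopifnot(length(dayRange) == 2L, dayRange[1L] >= 1)
    counts <- counts[((dayRange[1L] - 1L) * bpd + 1L):(dayRange[2L] * bpd)]
  }
  chiSquaredPeriodogramCounts(counts, binMin = x@binMin, pMinH = pMinH,
                              pMaxH = pMaxH, alpha = alpha)
})

#' @rdname chiSquaredPeriodogram
#' @export
setMethod("chiSquaredPeriodogram", "numeric",
          function(x, pMinH = 20, pMaxH = 28, alpha = 0.05, dayRange = NULL) {
  chiSquaredPeriodogramCounts(x, binMin = 10, pMinH = pMinH, pMaxH = pMaxH,
                              alpha = alpha)
})

chiSquaredPeriodogramCounts <- function(counts, binMin, pMinH, pMaxH, alpha) {
  binsPerHour <- 60 / binMin
  pBins <- seq.int(ceiling(pMinH * binsPerHour), floor(pMaxH * binsPerHour))
  if (length(counts) < 7 * 24 * binsPerHour)
    stop("need at least 7 days of data")
  qp <- qpStatistic(counts, pBins)
  skipped <- is.na(qp)
  if (any(skipped))
    warning(sprintf("%d candidate period(s) skipped (fewer than 2 cycles)",
                    sum(skipped)))
  df <- pBins - 1
  sig <- stats::qchisq(1 - alpha, df)
  score <- qp - sig
  peakIdx <- which.max(score)  # NA scores never win
  peakH <- pBins[peakIdx] / binsPerHour
  new("PeriodogramResult",
      periodsH = pBins / binsPerHour, qp = qp, df = df, sigLine = sig,
      peakPeriodH = peakH,
      peakSignificant = isTRUE(qp[peakIdx] > sig[peakIdx]))
}

#' Peak period of a periodogram
#' @param x a [PeriodogramResult-class].
#' @return peak period in hours.
#' @export
peakPeriod <- function(x) x@peakPeriodH

#' Whether the periodogram peak clears the significance line
#' @param x a [PeriodogramResult-class].
#' @return logical.
#' @export
peakSignificant <- function(x) x@peakSignificant

#' Periodogram as a data.frame
#' @param x a [PeriodogramResult-class].
#' @return data.frame with `periodH`, `qp`, `df`, `sigLine`.
#' @export
periodogramTable <- function(x) {
  data.frame(periodH = x@periodsH, qp = x@qp, df = x@df, sigLine = x@sigLine)
}

setMethod("show", "PeriodogramResult", function(object) {
  cat(sprintf(
    "Chi-squared periodogram: %d candidates %.2f-%.2f h; peak %.2f h (%s)\n",
    length(object@periodsH), min(object@periodsH), max(object@periodsH),
    object@peakPeriodH,
    if (object@peakSignificant) "significant" else "not significant"))
})

## ---- onset / offset ----

#' Activity onset and offset for one day
#'
#' Threshold-based detector (the conventional ClockLab-style defaults are
#' proprietary, so the rule is fully parameterized): the day's activity
#' threshold is `thresholdFrac` times the day's 90th-percentile bin count;
#' onset is the start of the first `windowMin`-minute window whose mean
#' exceeds the threshold after at least `quietHours` hours of sub-threshold
#' bins; offset is detected symmetrically from the day's end. Quiet spans
#' are clipped at the day boundary.
#'
#' @param x a [WheelSeries-class].
#' @param day 1-based day index.
#' @param windowMin detection window length in minutes (default 60).
#' @param quietHours required quiet span in hours (default 4).
#' @param thresholdFrac threshold as a fraction of the day's 90th-percentile
#'   bin count (default 0.25).
#' @param quantileProb quantile defining the day's activity scale.
#' @return list with `onsetH`, `offsetH`, `alphaH` (hours from the day's
#'   start; all `NA` when no qualifying window exists, e.g. a zero-activity
#'   day).
#' @export
detectOnsetOffset <- function(x, day, windowMin = 60, quietHours = 4,
                              thresholdFrac = 0.25, quantileProb = 0.9) {
  bpd <- binsPerDay(x)
  stopifnot(day >= 1, day <= nDays(x))
  v <- x@counts[((day - 1L) * bpd + 1L):(day * bpd)]
  if (mean(is.finite(v)) < 0.5)
    return(list(onsetH = NA_real_, offsetH = NA_real_, alphaH = NA_real_))
  theta <- thresholdFrac * stats::quantile(v, quantileProb, names = FALSE)
  if (theta <= 0)
    return(list(onsetH = NA_real_, offsetH = NA_real_, alphaH = NA_real_))
  w <- max(1L, as.integer(round(windowMin / x@binMin)))
  q <- as.integer(round(quietHours * 60 / x@binMin))
  below <- v < theta
  ## onset candidates: above-threshold bins that start a sustained window
  starts <- which(!below[seq_len(bpd - w + 1L)])
  onsetBin <- NA_integer_
  for (t in starts) {
    if (mean(v[t:(t + w - 1L)]) <= theta) next
    pre <- below[max(1L, t - q):(t - 1L)]
    if (t == 1L || all(pre)) { onsetBin <- t; break }
  }
  ## offset: last above-threshold bin ending a sustained window, then quiet
  ends <- which(!below); ends <- ends[ends >= w]
  offsetBin <- NA_integer_
  for (t in rev(ends)) {
    if (mean(v[(t - w + 1L):t]) <= theta) next
    post <- below[(t + 1L):min(bpd, t + q)]
    if (t == bpd || all(post)) { offsetBin <- t; break }
  }
  if (is.na(onsetBin) || is.na(offsetBin) || offsetBin <= onsetBin)
    return(list(onsetH = NA_real_, offsetH = NA_real_, alphaH = NA_real_))
  onsetH <- (onsetBin - 1L) * x@binMin / 60
  offsetH <- offsetBin * x@binMin / 60
  list(onsetH = onsetH, offsetH = offsetH, alphaH = offsetH - onsetH)
}

## ---- weekly summaries ----

#' Per-week circadian metrics
#'
#' For each analysis week: period from the week's chi-squared periodogram
#' (reported to 0.1 h with a significance flag; weeks whose peak does not
#' clear the significance line are reported, not dropped), alpha as the mean
#' daily onset-to-offset span, and activity as mean daily revolutions.
#'
#' @param x a [WheelSeries-class].
#' @param weeks named list of day-index vectors; default: consecutive
#'   7-day weeks labeled by their lighting schedule (`"LD Week k"` /
#'   `"DD Week k"`).
#' @param ... onset/offset parameters passed to [detectOnsetOffset()].
#' @return data.frame with `week`, `schedule`, `periodH`,
#'   `periodSignificant`, `alphaH`, `activityRevPerDay`.
#' @export
weeklySummary <- function(x, weeks = NULL, ...) {
  bpd <- binsPerDay(x)
  if (is.null(weeks)) weeks <- protocolWeeks(x)
  res <- lapply(names(weeks), function(nm) {
    days <- weeks[[nm]]
    pg <- chiSquaredPeriodogram(x, dayRange = range(days))
    daily <- vapply(days, function(d) {
      oo <- detectOnsetOffset(x, d, ...)
      c(alpha = oo$alphaH,
        rev = sum(x@counts[((d - 1L) * bpd + 1L):(d * bpd)]))
    }, c(alpha = 0, rev = 0))
    data.frame(week = nm,
               schedule = x@schedule[days[1L]],
               periodH = round(peakPeriod(pg), 1),
               periodSignificant = peakSignificant(pg),
               alphaH = mean(daily["alpha", ], na.rm = TRUE),
               activityRevPerDay = mean(daily["rev", ]))
  })
  do.call(rbind, res)
}

#' Default week layout of a recording
#'
#' Splits the recording into consecutive 7-day weeks and labels them
#' `"LD Week k"` / `"DD Week k"`, numbering LD and DD weeks separately in
#' the order they occur (the usual entrainment-then-free-run protocol).
#'
#' @param x a [WheelSeries-class].
#' @return named list of day-index vectors.
#' @export
protocolWeeks <- function(x) {
  nd <- nDays(x)
  nWeeks <- nd %/% 7L
  weeks <- list()
  cnt <- c(LD = 0L, DD = 0L)
  for (w in seq_len(nWeeks)) {
    days <- ((w - 1L) * 7L + 1L):(w * 7L)
    sched <- x@schedule[days[1L]]
    cnt[sched] <- cnt[sched] + 1L
    weeks[[sprintf("%s Week %d", sched, cnt[sched])]] <- days
  }
  weeks
}

## ---- actogram ----

#' @rdname buildActogram
#' @export
setMethod("buildActogram", "WheelSeries",
          function(x, doublePlotted = FALSE, moduloH = 24) {
  rowBins <- as.integer(round(moduloH * 60 / x@binMin))
  nRows <- length(x@counts) %/% rowBins
  m <- matrix(x@counts[seq_len(nRows * rowBins)], nrow = nRows,
              byrow = TRUE)
  if (doublePlotted) {
    nxt <- rbind(m[-1L, , drop = FALSE],
                 matrix(NA_real_, 1L, rowBins))
    m <- cbind(m, nxt)
  }
  rownames(m) <- paste0("day", seq_len(nRows))
  m
})

#' Plot an actogram
#'
#' Day-by-day raster of activity counts drawn with [graphics::image()]
#' (days top to bottom, conventionally double-plotted).
#'
#' @param x a [WheelSeries-class].
#' @param doublePlotted draw each row as day r followed by day r+1.
#' @param main plot title.
#' @return the plotted matrix, invisibly.
#' @export
plotActogram <- function(x, doublePlotted = TRUE, main = "Actogram") {
  m <- buildActogram(x, doublePlotted = doublePlotted)
  nr <- nrow(m)
  hours <- seq(0, ncol(m) * x@binMin / 60, length.out = ncol(m))
  graphics::image(x = hours, y = seq_len(nr), z = t(m[nr:1, , drop = FALSE]),
                  col = grDevices::gray.colors(64, start = 1, end = 0),
                  xlab = "time (h)", ylab = "day", yaxt = "n", main = main)
  graphics::axis(2, at = seq_len(nr), labels = rev(seq_len(nr)), las = 1)
  invisible(m)
}
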