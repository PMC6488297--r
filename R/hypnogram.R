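#' Construct a Hypnogram
#'
#' @param states character vector of state codes `"W"`, `"N"`, `"R"`
#'   (`NA` allowed only where `missing` is `TRUE`).
#' @param epochLengthS epoch duration in seconds.
#' @param artifact logical per-epoch artifact flags (default all `FALSE`).
#' @param missing logical per-epoch missing flags (default: `is.na(states)`).
#' @param ztStartHour zeitgeber hour of the first epoch; hour 1 is the first
#'   hour after light onset.
#' @return a [Hypnogram-class].
#' @examples
#' hyp <- Hypnogram(rep(c("W", "N"), each = 450))
#' totalSleepTime(hyp, c(1, 1))
#' @export
Hypnogram <- function(states, epochLengthS = 4, artifact = NULL,
                      missing = NULL, ztStartHour = 1) {
  states <- as.character(states)
  if (is.null(missing)) missing <- is.na(states)
  if (is.null(artifact)) artifact <- rep(FALSE, length(states))
  new("Hypnogram", states = states, artifact = as.logical(artifact),
      missing = as.logical(missing), epochLengthS = epochLengthS,
      ztStartHour = ztStartHour)
}

#' Validate an epoch table into a Hypnogram
#'
#' Takes a raw epoch table (as read from a hypnogram CSV: one row per
#' recorded epoch) and returns a validated [Hypnogram-class]. Absent epoch
#' indices become missing epochs; their containing hour will be flagged
#' invalid by [timeInStateHourly()]. Unknown state codes and non-monotone
#' epoch indices are hard errors naming the offending epoch.
#'
#' @param raw data.frame with columns `epoch_index` (0-based integers),
#'   `state`, and optionally `zt_seconds` and `artifact` (0/1).
#' @param epochLengthS epoch duration in seconds.
#' @return a [Hypnogram-class]; attribute `"report"` carries per-state epoch
#'   counts and the number of missing epochs.
#' @export
validateHypnogram <- function(raw, epochLengthS = 4) {
  stopifnot(is.data.frame(raw))
  if (!all(c("epoch_index", "state") %in% names(raw)))
    stop("epoch table must have 'epoch_index' and 'state' columns")
  idx <- as.integer(raw$epoch_index)
  if (anyNA(idx)) stop("non-integer epoch_index")
  if (is.unsorted(idx, strictly = TRUE)) {
    bad <- which(diff(idx) <= 0)[1L]
    stop(sprintf("non-monotone epoch_index at row %d (epoch %d)",
                 bad + 1L, idx[bad + 1L]))
  }
  st <- as.character(raw$state)
  unknown <- which(!(st %in% STATE_CODES))
  if (length(unknown))
    stop(sprintf("unknown state code '%s' at epoch %d",
                 st[unknown[1L]], idx[unknown[1L]]))
  n <- max(idx) + 1L
  states <- rep(NA_character_, n)
  states[idx + 1L] <- st
  artifact <- rep(FALSE, n)
  if (!is.null(raw$artifact)) artifact[idx + 1L] <- as.logical(raw$artifact)
  ztStartHour <- 1
  if (!is.null(raw$zt_seconds)) {
    zt0 <- raw$zt_seconds[1L] - idx[1L] * epochLengthS
    ztStartHour <- zt0 / 3600 + 1
  }
  hyp <- Hypnogram(states, epochLengthS = epochLengthS, artifact = artifact,
                   ztStartHour = ztStartHour)
  counts <- vapply(STATE_CODES, function(s) sum(states == s, na.rm = TRUE), 0L)
  attr(hyp, "report") <- list(stateCounts = counts,
                              nMissing = sum(is.na(states)),
                              nArtifact = sum(artifact))
  hyp
}

## ---- accessors ----

#' @rdname nEpochs
#' @export
setMethod("nEpochs", "Hypnogram", function(x) length(x@states))

#' @rdname epochStates
#' @export
setMethod("epochStates", "Hypnogram", function(x) x@states)

#' @rdname isArtifact
#' @export
setMethod("isArtifact", "Hypnogram", function(x) x@artifact)

#' @rdname isMissing
#' @export
setMethod("isMissing", "Hypnogram", function(x) x@missing)

#' @rdname epochLength
#' @export
setMethod("epochLength", "Hypnogram", function(x) x@epochLengthS)

#' @rdname ztStart
#' @export
setMethod("ztStart", "Hypnogram", function(x) x@ztStartHour)

setMethod("show", "Hypnogram", function(object) {
  n <- nEpochs(object)
  cat(sprintf("Hypnogram: %d epochs of %g s (%.2f h), ZT start hour %g\n",
              n, object@epochLengthS, n * object@epochLengthS / 3600,
              object@ztStartHour))
  counts <- vapply(STATE_CODES, function(s)
    sum(object@states == s, na.rm = TRUE), 0L)
  cat(sprintf("  W: %d  N: %d  R: %d  missing: %d  artifact: %d\n",
              counts[1L], counts[2L], counts[3L],
              sum(object@missing), sum(object@artifact)))
})

## ---- internal hour/epoch bookkeeping ----

epochsPerHour <- function(hyp) {
  eph <- 3600 / hyp@epochLengthS
  if (abs(eph - round(eph)) > 1e-9)
    stop("epoch length must divide one hour")
  as.integer(round(eph))
}

## 1-based epoch indices covered by closed zeitgeber-hour range [lo, hi],
## clipped to the recording.
ztHourEpochs <- function(hyp, hours) {
  stopifnot(length(hours) == 2L, hours[1L] <= hours[2L])
  eph <- epochsPerHour(hyp)
  from <- round((hours[1L] - hyp@ztStartHour) * eph) + 1L
  to <- round((hours[2L] + 1 - hyp@ztStartHour) * eph)
  from <- max(1L, as.integer(from))
  to <- min(nEpochs(hyp), as.integer(to))
  if (from > to) integer(0) else seq.int(from, to)
}

resolvePeriod <- function(period) {
  if (is.character(period)) {
    switch(match.arg(period, c("light", "dark")),
           light = c(1, 12), dark = c(13, 24))
  } else {
    stopifnot(is.numeric(period), length(period) == 2L)
    period
  }
}

## ---- operations ----

#' @rdname segmentBouts
#' @export
setMethod("segmentBouts", "Hypnogram", function(x) {
  if (nEpochs(x) == 0L) stop("empty hypnogram")
  st <- x@states
  st[is.na(st)] <- ".."  # sentinel so missing gaps form their own runs
  r <- rle(st)
  starts <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  state <- ifelse(r$values == "..", NA_character_, r$values)
  data.frame(state = state, startEpoch = starts, nEpochs = r$lengths,
             durationS = r$lengths * x@epochLengthS,
             stringsAsFactors = FALSE)
})

#' @rdname timeInStateHourly
#' @export
setMethod("timeInStateHourly", "Hypnogram", function(x) {
  eph <- epochsPerHour(x)
  n <- nEpochs(x)
  hourIdx <- (seq_len(n) - 1L) %/% eph  # 0-based hour offset
  hours <- sort(unique(hourIdx))
  res <- lapply(hours, function(h) {
    sel <- hourIdx == h
    st <- x@states[sel]
    rec <- sum(!is.na(st))
    cnt <- vapply(STATE_CODES, function(s) sum(st == s, na.rm = TRUE), 0L)
    pct <- if (rec > 0) 100 * cnt / rec else rep(NA_real_, 3L)
    data.frame(hour = x@ztStartHour + h,
               pctW = pct[1L], pctN = pct[2L], pctR = pct[3L],
               nEpochs = rec,
               valid = rec == eph && !any(is.na(st)),
               row.names = NULL)
  })
  do.call(rbind, res)
})

#' @rdname totalSleepTime
#' @export
setMethod("totalSleepTime", "Hypnogram", function(x, period = "light") {
  hours <- resolvePeriod(period)
  tab <- timeInStateHourly(x)
  tab <- tab[tab$hour >= hours[1L] & tab$hour <= hours[2L] & tab$valid, ,
             drop = FALSE]
  if (nrow(tab) == 0L)
    stop("period contains no valid hours")
  eph <- epochsPerHour(x)
  idx <- unlist(lapply(tab$hour, function(h) ztHourEpochs(x, c(h, h))))
  st <- x@states[idx]
  100 * sum(st %in% c("N", "R")) / sum(!is.na(st))
})

#' @rdname boutStatsByBlock
#' @export
setMethod("boutStatsByBlock", "Hypnogram",
          function(x, blockHours = 6, minEpochs = 1L) {
  if (24 %% blockHours != 0) stop("blockHours must divide 24")
  eph <- epochsPerHour(x)
  bouts <- segmentBouts(x)
  bouts <- bouts[!is.na(bouts$state) & bouts$nEpochs >= minEpochs, ,
                 drop = FALSE]
  epb <- blockHours * eph
  bouts$block <- bouts$startEpoch %/% epb + 1L
  nBlocks <- ceiling(nEpochs(x) / epb)
  grid <- expand.grid(block = seq_len(nBlocks), state = STATE_CODES,
                      stringsAsFactors = FALSE)
  grid$hourFrom <- x@ztStartHour + (grid$block - 1L) * blockHours
  grid$hourTo <- grid$hourFrom + blockHours - 1
  grid$nBouts <- mapply(function(b, s)
    sum(bouts$block == b & bouts$state == s), grid$block, grid$state)
  grid$meanDurationS <- mapply(function(b, s) {
    d <- bouts$durationS[bouts$block == b & bouts$state == s]
    if (length(d)) mean(d) else NA_real_
  }, grid$block, grid$state)
  grid[order(grid$block, match(grid$state, STATE_CODES)),
       c("block", "hourFrom", "hourTo", "state", "nBouts", "meanDurationS")]
})

#' Sleep-onset latency criteria
#'
#' Minimum run lengths (in epochs) that a state run must reach to count as
#' sleep onset. With 4-s epochs the defaults encode a NREM bout of at least
#' 28 s (7 epochs) and a REM bout of at least 16 s (4 epochs).
#'
#' @param nremMinEpochs minimum consecutive NREM epochs (default 7).
#' @param remMinEpochs minimum consecutive REM epochs (default 4).
#' @return list with class `"LatencyCriteria"`.
#' @export
latencyCriteria <- function(nremMinEpochs = 7L, remMinEpochs = 4L) {
  stopifnot(nremMinEpochs >= 1, remMinEpochs >= 1)
  structure(list(nremMinEpochs = as.integer(nremMinEpochs),
                 remMinEpochs = as.integer(remMinEpochs)),
            class = "LatencyCriteria")
}

#' @rdname latencyToState
#' @export
setMethod("latencyToState", "Hypnogram",
          function(x, t0Hour, state = c("N", "R"),
                   criteria = latencyCriteria()) {
  state <- match.arg(state)
  minEp <- if (state == "N") criteria$nremMinEpochs else criteria$remMinEpochs
  eph <- epochsPerHour(x)
  start <- round((t0Hour - x@ztStartHour) * eph) + 1L
  if (start < 1L || start > nEpochs(x))
    stop("t0Hour outside the recording")
  st <- x@states[start:nEpochs(x)]
  st[is.na(st)] <- ".."
  r <- rle(st)
  offs <- cumsum(c(0L, r$lengths[-length(r$lengths)]))
  hit <- which(r$values == state & r$lengths >= minEp)
  if (!length(hit)) {
    out <- NA_real_
    attr(out, "reached") <- FALSE
    return(out)
  }
  out <- offs[hit[1L]] * x@epochLengthS
  attr(out, "reached") <- TRUE
  out
})

#' @rdname wakePercentage
#' @export
setMethod("wakePercentage", "Hypnogram", function(x, windowHours) {
  idx <- ztHourEpochs(x, windowHours)
  st <- x@states[idx]
  st <- st[!is.na(st)]
  if (!length(st)) stop("window contains no recorded epochs")
  100 * sum(st == "W") / length(st)
})
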