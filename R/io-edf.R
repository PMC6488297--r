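## Minimal EDF (European Data Format) codec: 16-bit integer samples with
## per-signal linear calibration, the polysomnography interchange standard.
## Covers plain continuous EDF (no annotations); written by hand because the
## format is fixed-width ASCII headers + int16 little-endian payload.

padField <- function(x, width) {
  x <- substr(as.character(x), 1L, width)
  formatC(x, width = -width, flag = " ")
}

#' Write signals to an EDF file
#'
#' @param signals list of channels, each a list with `label`,
#'   `samplingRate` (Hz) and `data` (numeric samples). All channels must
#'   span the same duration.
#' @param path file path.
#' @param recordDurS data-record duration in seconds; the total duration
#'   must be a whole number of records.
#' @param patient,recording free-text header fields.
#' @return `path`, invisibly.
#' @export
writeEdf <- function(signals, path, recordDurS = 1,
                     patient = "X", recording = "somnocirc") {
  ns <- length(signals)
  stopifnot(ns >= 1)
  spr <- vapply(signals, function(s)
    as.integer(round(s$samplingRate * recordDurS)), 0L)
  durS <- vapply(signals, function(s) length(s$data) / s$samplingRate, 0)
  if (max(durS) - min(durS) > 1e-9)
    stop("all channels must span the same duration")
  nRec <- durS[1L] / recordDurS
  if (abs(nRec - round(nRec)) > 1e-9)
    stop("signal duration must be a whole number of data records")
  nRec <- as.integer(round(nRec))
  fmt8 <- function(x) {
    s <- formatC(x, format = "g", digits = 6)
    if (nchar(s) > 8) s <- formatC(x, format = "e", digits = 1)
    if (nchar(s) > 8) s <- formatC(x, format = "e", digits = 0)
    s
  }
  physMin <- physMax <- numeric(ns)
  physMinS <- physMaxS <- character(ns)
  digData <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]]$data
    lo <- min(x); hi <- max(x)
    if (hi <= lo) { lo <- lo - 1; hi <- hi + 1 }
    # digitize against the header values as actually stored (8-char ASCII)
    physMinS[i] <- fmt8(lo); physMaxS[i] <- fmt8(hi)
    lo <- as.numeric(physMinS[i]); hi <- as.numeric(physMaxS[i])
    lo <- min(lo, min(x)); hi <- max(hi, max(x))
    physMinS[i] <- fmt8(lo); physMaxS[i] <- fmt8(hi)
    lo <- as.numeric(physMinS[i]); hi <- as.numeric(physMaxS[i])
    physMin[i] <- lo; physMax[i] <- hi
    digData[[i]] <- pmin(32767L, pmax(-32768L, as.integer(
      round((x - lo) / (hi - lo) * 65535 - 32768))))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, w) writeChar(padField(x, w), con, nchars = w,
                                 eos = NULL)
  wr("0", 8)
  wr(patient, 80); wr(recording, 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1L), 8)
  wr("", 44)
  wr(nRec, 8)
  wr(format(recordDurS), 8)
  wr(ns, 4)
  widths <- c(16, 80, 8, 8, 8, 8, 8, 80, 8, 32)
  fields <- list(
    vapply(signals, function(s) as.character(s$label), ""),
    rep("", ns), rep("uV", ns),
    physMinS, physMaxS,
    rep("-32768", ns), rep("32767", ns),
    rep("", ns), as.character(spr), rep("", ns))
  for (j in seq_along(fields))
    for (i in seq_len(ns)) wr(fields[[j]][i], widths[j])
  for (r in seq_len(nRec))
    for (i in seq_len(ns)) {
      sel <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(digData[[i]][sel], con, size = 2L, endian = "little")
    }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path file path.
#' @param expectedRate if given, a hard error is raised when any channel's
#'   sampling rate differs (guards a config/recording mismatch).
#' @return list with `signals` (each: `label`, `samplingRate`, `data` in
#'   physical units), `recordDurS`, `nRecords`.
#' @export
readEdf <- function(path, expectedRate = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF header: version")
  rd(80); rd(80); rd(8); rd(8)
  headerBytes <- suppressWarnings(as.integer(rd(8)))
  if (is.na(headerBytes)) stop("malformed EDF header: header bytes")
  rd(44)
  nRec <- suppressWarnings(as.integer(rd(8)))
  if (is.na(nRec) || nRec < 0) stop("malformed EDF header: record count")
  recDur <- suppressWarnings(as.numeric(rd(8)))
  if (is.na(recDur) || recDur <= 0)
    stop("malformed EDF header: record duration")
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1) stop("malformed EDF header: signal count")
  getF <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- getF(16); getF(80); getF(8)
  physMin <- as.numeric(getF(8)); physMax <- as.numeric(getF(8))
  digMin <- as.numeric(getF(8)); digMax <- as.numeric(getF(8))
  getF(80)
  spr <- as.integer(getF(8)); getF(32)
  if (anyNA(physMin) || anyNA(physMax))
    stop("malformed EDF header: physical min/max")
  if (anyNA(spr)) stop("malformed EDF header: samples per record")
  data <- lapply(seq_len(ns), function(i) numeric(nRec * spr[i]))
  for (r in seq_len(nRec))
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      data[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (d - digMin[i]) / (digMax[i] - digMin[i]) *
        (physMax[i] - physMin[i]) + physMin[i]
    }
  signals <- lapply(seq_len(ns), function(i) {
    sr <- spr[i] / recDur
    if (!is.null(expectedRate) && abs(sr - expectedRate) > 1e-9)
      stop(sprintf("channel '%s' sampled at %g Hz, expected %g Hz",
                   labels[i], sr, expectedRate))
    list(label = labels[i], samplingRate = sr, data = data[[i]])
  })
  list(signals = signals, recordDurS = recDur, nRecords = nRec)
}
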