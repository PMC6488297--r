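## CSV dialect throughout: comma separator, "." decimal, UTF-8, header row,
## ISO-8601 timestamps. Hour windows live in zeitgeber hours 1-24 in configs
## and are converted internally to 0-based half-open epoch ranges.

#' Read a hypnogram CSV
#'
#' Expected columns: `epoch_index` (0-based int), `zt_seconds` (float),
#' `state` (W|N|R), `artifact` (0|1). Missing epochs are encoded by absent
#' rows and come back flagged missing.
#'
#' @param path file path.
#' @param epochLengthS epoch duration in seconds.
#' @return a validated [Hypnogram-class].
#' @export
readHypnogramCsv <- function(path, epochLengthS = 4) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateHypnogram(raw, epochLengthS = epochLengthS)
}

#' Write a hypnogram CSV
#'
#' Missing epochs are written as absent rows, matching [readHypnogramCsv()].
#'
#' @param hyp a [Hypnogram-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeHypnogramCsv <- function(hyp, path) {
  idx <- which(!is.na(epochStates(hyp)))
  df <- data.frame(
    epoch_index = idx - 1L,
    zt_seconds = (ztStart(hyp) - 1) * 3600 + (idx - 1L) * epochLength(hyp),
    state = epochStates(hyp)[idx],
    artifact = as.integer(isArtifact(hyp)[idx]))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-epoch spectra from CSV
#'
#' Column layout: `epoch_index`, then one column per bin labeled by its
#' center frequency to 3 decimals (as written by [writeSpectraCsv()]).
#'
#' @param path file path.
#' @param nEpochs total epoch count of the paired hypnogram (rows absent
#'   from the file become all-`NA` artifact epochs); default: infer from
#'   the largest epoch index present.
#' @return a [SpectralSeries-class].
#' @export
readSpectraCsv <- function(path, nEpochs = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  idx <- as.integer(df$epoch_index)
  binHz <- as.numeric(setdiff(names(df), "epoch_index"))
  if (anyNA(binHz)) stop("bin columns must be labeled by center frequency")
  if (is.null(nEpochs)) nEpochs <- max(idx) + 1L
  power <- matrix(NA_real_, nEpochs, length(binHz))
  power[idx + 1L, ] <- as.matrix(df[, setdiff(names(df), "epoch_index")])
  artifact <- rep(FALSE, nEpochs)
  artifact[rowSums(is.na(power)) == length(binHz)] <- TRUE
  artifact[idx + 1L][rowSums(is.na(power[idx + 1L, , drop = FALSE])) > 0] <- TRUE
  SpectralSeries(power, binHz, artifact)
}

#' Write per-epoch spectra to CSV
#'
#' @param spec a [SpectralSeries-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeSpectraCsv <- function(spec, path) {
  df <- as.data.frame(powerMatrix(spec))
  names(df) <- sprintf("%.3f", binFrequencies(spec))
  df <- cbind(epoch_index = seq_len(nEpochs(spec)) - 1L, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read wheel counts from CSV
#'
#' Expected columns: `timestamp` (ISO-8601) and `counts`; bins must be
#' equally spaced. The lighting schedule is not stored in the CSV and is
#' supplied by the caller.
#'
#' @param path file path.
#' @param schedule per-day `"LD"`/`"DD"` (recycled if length 1).
#' @param t0Hour clock time of the first bin in hours after lights-on.
#' @return a [WheelSeries-class].
#' @export
readWheelCsv <- function(path, schedule = "LD", t0Hour = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ts <- as.POSIXct(df$timestamp, tz = "UTC",
                   format = "%Y-%m-%dT%H:%M:%S")
  if (anyNA(ts)) stop("timestamps must be ISO-8601 (YYYY-MM-DDTHH:MM:SS)")
  gaps <- diff(as.numeric(ts))
  if (length(gaps) && (max(gaps) - min(gaps)) > 1e-6)
    stop("bins must be equally spaced")
  binMin <- if (length(gaps)) gaps[1L] / 60 else 10
  WheelSeries(df$counts, binMin = binMin, schedule = schedule,
              t0Hour = t0Hour)
}

#' Write wheel counts to CSV
#'
#' @param ws a [WheelSeries-class].
#' @param path file path.
#' @param startTime POSIXct timestamp of the first bin.
#' @return `path`, invisibly.
#' @export
writeWheelCsv <- function(ws, path,
                          startTime = as.POSIXct("2000-01-01 00:00:00",
                                                 tz = "UTC")) {
  ts <- startTime + (seq_along(wheelCounts(ws)) - 1L) * ws@binMin * 60
  df <- data.frame(timestamp = format(ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
                   counts = wheelCounts(ws))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an AWD-style activity file
#'
#' Minimal ClockLab-style AWD dialect: a 7-line header (subject id, start
#' date, start time, bin length in minutes, age, serial, sex) followed by
#' one count per line at fixed bin width. The vendor's bin-length code
#' table is not public, so the fourth header line is interpreted directly
#' as minutes.
#'
#' @param path file path.
#' @param schedule per-day `"LD"`/`"DD"`.
#' @param t0Hour clock time of the first bin in hours after lights-on.
#' @return a [WheelSeries-class].
#' @export
readAWD <- function(path, schedule = "LD", t0Hour = 0) {
  lines <- readLines(path)
  if (length(lines) < 8) stop("AWD file too short")
  binMin <- as.numeric(lines[4L])
  if (!is.finite(binMin) || binMin <= 0)
    stop("AWD header line 4 must give the bin length in minutes")
  counts <- as.numeric(lines[-(1:7)])
  counts <- counts[!is.na(counts)]
  WheelSeries(counts, binMin = binMin, schedule = schedule, t0Hour = t0Hour)
}

#' Write an AWD-style activity file
#'
#' @param ws a [WheelSeries-class].
#' @param path file path.
#' @param id subject identifier for the header.
#' @return `path`, invisibly.
#' @export
writeAWD <- function(ws, path, id = "subject") {
  header <- c(id, "01-jan-2000", "00:00", format(ws@binMin), "0", "0", "M")
  writeLines(c(header, format(wheelCounts(ws), trim = TRUE)), path)
  invisible(path)
}

#' Write an actogram matrix to CSV
#'
#' @param m matrix from [buildActogram()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeActogramCsv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
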