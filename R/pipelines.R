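## Experiment-level drivers tying the stages together. These (plus the
## exported stage functions) are the package's operational surface; each
## writes tidy CSV/JSON outputs stamped with the configuration hash.

stampProvenance <- function(summary, cfg) {
  summary$configHash <- configHash(cfg)
  summary$package <- as.character(utils::packageVersion("somnocirc"))
  summary
}

#' Run the sleep-deprivation experiment analysis for a cohort
#'
#' Takes per-subject baseline and deprivation-day recordings, runs
#' [runHomeostasis()] on each, and writes the tidy per-subject metric table
#' (CSV) plus a JSON summary with group means +/- SEM and the configuration
#' hash.
#'
#' @param subjects named list; each element is
#'   `list(baseline = list(hyp, spec), sdDay = list(hyp, spec))`.
#' @param cfg a [runConfig()].
#' @param outDir output directory (default from `cfg`).
#' @return list with `reports`, `table`, and the output paths, invisibly.
#' @export
runSleepExperiment <- function(subjects, cfg = runConfig(),
                               outDir = cfg$outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  reports <- lapply(names(subjects), function(nm)
    runHomeostasis(subjects[[nm]]$baseline, subjects[[nm]]$sdDay,
                   windows = cfg$windows, criteria = cfg$criteria,
                   subject = nm))
  tab <- homeostasisTable(reports)
  csvPath <- file.path(outDir, "homeostasis_metrics.csv")
  utils::write.csv(tab, csvPath, row.names = FALSE, quote = FALSE)
  agg <- stats::aggregate(value ~ metric, tab, function(v)
    c(mean = mean(v, na.rm = TRUE),
      sem = stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))))
  summary <- stampProvenance(list(
    nSubjects = length(subjects),
    metrics = stats::setNames(
      lapply(seq_len(nrow(agg)), function(i) as.list(agg$value[i, ])),
      agg$metric)), cfg)
  jsonPath <- file.path(outDir, "homeostasis_summary.json")
  jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, digits = NA)
  invisible(list(reports = reports, table = tab,
                 paths = c(csv = csvPath, json = jsonPath)))
}

#' Run the wheel-running circadian analysis
#'
#' Weekly period/alpha/activity summary, full-series periodogram, and the
#' single-plot actogram matrix, written as tidy CSV plus a JSON summary
#' stamped with the configuration hash.
#'
#' @param ws a [WheelSeries-class].
#' @param cfg a [runConfig()].
#' @param outDir output directory (default from `cfg`).
#' @param id subject identifier used in file names.
#' @return list with `weekly`, `periodogram`, `actogram` and output paths,
#'   invisibly.
#' @export
runCircadianExperiment <- function(ws, cfg = runConfig(),
                                   outDir = cfg$outDir, id = "subject") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  weekly <- do.call(weeklySummary, c(list(ws), cfg$onsetOffset))
  pg <- chiSquaredPeriodogram(ws, pMinH = cfg$periodogram$pMinH,
                              pMaxH = cfg$periodogram$pMaxH,
                              alpha = cfg$periodogram$alpha)
  acto <- buildActogram(ws)
  paths <- c(
    weekly = file.path(outDir, sprintf("%s_weekly.csv", id)),
    periodogram = file.path(outDir, sprintf("%s_periodogram.csv", id)),
    actogram = file.path(outDir, sprintf("%s_actogram.csv", id)),
    json = file.path(outDir, sprintf("%s_circadian.json", id)))
  utils::write.csv(weekly, paths["weekly"], row.names = FALSE, quote = FALSE)
  utils::write.csv(periodogramTable(pg), paths["periodogram"],
                   row.names = FALSE, quote = FALSE)
  writeActogramCsv(acto, paths["actogram"])
  summary <- stampProvenance(list(
    id = id, nDays = nDays(ws),
    peakPeriodH = peakPeriod(pg),
    peakSignificant = peakSignificant(pg)), cfg)
  jsonlite::write_json(summary, paths["json"], auto_unbox = TRUE,
                       digits = NA)
  invisible(list(weekly = weekly, periodogram = pg, actogram = acto,
                 paths = paths))
}
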