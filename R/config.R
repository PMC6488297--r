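#' Run configuration
#'
#' A fully serializable bundle of every tunable the analysis stages take:
#' spectral estimator settings, protocol hour windows, latency criteria,
#' band definitions, periodogram candidate range, onset/offset detector
#' parameters, seeds and output directory. A run's configuration is embedded
#' verbatim (with its hash) in every output for provenance.
#'
#' @param spectral a [spectralConfig()].
#' @param windows a [protocolWindows()].
#' @param criteria a [latencyCriteria()].
#' @param bands named list of band edges in Hz.
#' @param periodogram list with `pMinH`, `pMaxH`, `alpha`.
#' @param onsetOffset list of [detectOnsetOffset()] parameters.
#' @param seed master seed.
#' @param outDir output directory.
#' @return list with class `"RunConfig"`.
#' @export
runConfig <- function(spectral = spectralConfig(),
                      windows = protocolWindows(),
                      criteria = latencyCriteria(),
                      bands = list(delta = c(0.5, 4), theta = c(5, 9),
                                   alpha = c(10, 15)),
                      periodogram = list(pMinH = 20, pMaxH = 28,
                                         alpha = 0.05),
                      onsetOffset = list(windowMin = 60, quietHours = 4,
                                         thresholdFrac = 0.25,
                                         quantileProb = 0.9),
                      seed = 1L, outDir = ".") {
  structure(list(spectral = spectral, windows = windows,
                 criteria = criteria, bands = bands,
                 periodogram = periodogram, onsetOffset = onsetOffset,
                 seed = seed, outDir = outDir),
            class = "RunConfig")
}

#' Read a run configuration from YAML
#'
#' Sections missing from the file fall back to the package defaults.
#' Hour windows are given in zeitgeber hours 1-24.
#'
#' @param path YAML file path.
#' @return a [runConfig()].
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  def <- runConfig()
  pick <- function(section, defaults) {
    got <- y[[section]]
    if (is.null(got)) return(defaults)
    for (nm in names(got)) defaults[[nm]] <- got[[nm]]
    defaults
  }
  spectralArgs <- y$spectral
  spectral <- if (is.null(spectralArgs)) def$spectral
  else do.call(spectralConfig,
               spectralArgs[intersect(names(spectralArgs),
                                      names(formals(spectralConfig)))])
  windows <- if (is.null(y$windows)) def$windows
  else do.call(protocolWindows, lapply(y$windows, unlist))
  criteria <- if (is.null(y$criteria)) def$criteria
  else do.call(latencyCriteria, y$criteria)
  runConfig(spectral = spectral, windows = windows, criteria = criteria,
            bands = pick("bands", def$bands),
            periodogram = pick("periodogram", def$periodogram),
            onsetOffset = pick("onsetOffset", def$onsetOffset),
            seed = if (is.null(y$seed)) def$seed else y$seed,
            outDir = if (is.null(y$outDir)) def$outDir else y$outDir)
}

## recursively drop S3 classes so configs serialize as plain lists
unclassDeep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclassDeep) else unclass(x)
}

#' Write a run configuration to YAML
#'
#' @param cfg a [runConfig()].
#' @param path YAML file path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(unclassDeep(cfg), path)
  invisible(path)
}

#' Deterministic hash of a configuration
#'
#' MD5 of the canonical JSON serialization; embedded in every output
#' artifact so a run can be matched to the configuration that produced it.
#'
#' @param cfg any serializable configuration object.
#' @return 32-character hex string.
#' @export
configHash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclassDeep(cfg), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
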