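## Run expr with a local RNG seed, restoring the caller's RNG state, so the
## generators are pure functions of (config, seed).
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Counter-based seed fan-out: subject/replicate streams derived from one
## master seed, kept below 2^31.
fanSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 69069 + i * 104729) %% 2147483629)
}

#' Sleep simulator configuration
#'
#' Configuration for the epoch-level Markov hypnogram generator. The chain
#' has hour-dependent transition matrices over states W/N/R constructed
#' analytically from target stationary occupancies and mean wake/REM bout
#' durations; REM is reachable only from NREM (physiological constraint
#' that also makes REM latency meaningful). The default occupancies target
#' the usual mouse baseline: ~63% total sleep time in the light period and
#' ~29% in the dark period.
#'
#' The genotype-style knobs modify the base matrices: `darkWakeGain` scales
#' the expected wake-bout duration in dark hours, `lateDarkBoutShortening`
#' divides sleep-bout durations in hours 19-24, `sdLeakProb` is the
#' per-epoch probability of a sleep intrusion during enforced wakefulness,
#' `onsetDelayGain` scales wake-bout durations immediately after sleep
#' deprivation for `onsetDelaySpanH` hours, and `reboundDeltaGain` /
#' `reboundTauH` shape the post-deprivation NREM delta rebound applied by
#' [simulateEEG()] (multiplier `1 + (gain-1) * exp(-(hour-6)/tau)` stepped
#' hourly, i.e. exactly `gain` in the first recovery hour).
#'
#' @param hours recording length in hours.
#' @param epochLengthS epoch duration in seconds.
#' @param lightHours closed zeitgeber-hour range of the light period.
#' @param piLight,piDark target stationary occupancy (W, N, R) for light
#'   and dark hours; each must sum to 1.
#' @param meanWakeBoutLightS,meanWakeBoutDarkS,meanRemBoutS mean bout
#'   durations (seconds) determining the wake and REM self-transitions.
#' @param darkWakeGain,lateDarkBoutShortening,sdLeakProb genotype/protocol
#'   knobs (see Details).
#' @param onsetDelayGain,onsetDelaySpanH,reboundDeltaGain,reboundTauH
#'   post-deprivation knobs (see Details).
#' @param postSdBroadbandGain multiplier applied to bins >= 3.9 Hz of NREM
#'   epochs during the first two recovery hours (see Details).
#' @param nSubjects default number of subjects generated per call.
#' @return list with class `"SleepSimConfig"`.
#' @export
sleepSimConfig <- function(hours = 24, epochLengthS = 4,
                           lightHours = c(1, 12),
                           piLight = c(W = 0.37, N = 0.52, R = 0.11),
                           piDark = c(W = 0.713, N = 0.235, R = 0.052),
                           meanWakeBoutLightS = 90,
                           meanWakeBoutDarkS = 240,
                           meanRemBoutS = 60,
                           darkWakeGain = 1,
                           lateDarkBoutShortening = 1,
                           sdLeakProb = 0.03,
                           onsetDelayGain = 1,
                           onsetDelaySpanH = 2,
                           reboundDeltaGain = 1.4,
                           reboundTauH = 6,
                           postSdBroadbandGain = 1,
                           nSubjects = 1L) {
  stopifnot(abs(sum(piLight) - 1) < 1e-9, abs(sum(piDark) - 1) < 1e-9,
            all(piLight > 0), all(piDark > 0),
            meanWakeBoutLightS > epochLengthS,
            meanWakeBoutDarkS > epochLengthS,
            meanRemBoutS > epochLengthS,
            darkWakeGain > 0, lateDarkBoutShortening > 0,
            sdLeakProb >= 0, sdLeakProb <= 1, onsetDelayGain > 0)
  structure(as.list(environment()), class = "SleepSimConfig")
}

## One transition matrix from target stationary pi and self-transitions.
## Flow balance: pi is exactly stationary for the returned matrix.
transitionFromStationary <- function(pi, pWW, pRR) {
  exitR <- pi[3L] * (1 - pRR)
  pNW <- (pi[1L] * (1 - pWW) - exitR) / pi[2L]
  pNR <- exitR / pi[2L]
  pNN <- 1 - pNW - pNR
  if (pNW < 0 || pNN <= 0)
    stop("infeasible stationary target: wake outflow smaller than REM outflow")
  m <- rbind(W = c(pWW, 1 - pWW, 0),
             N = c(pNW, pNN, pNR),
             R = c(1 - pRR, 0, pRR))
  colnames(m) <- STATE_CODES
  m
}

## Per-hour 3 x 3 x hours transition array implied by a config.
transitionMatrices <- function(cfg) {
  eps <- cfg$epochLengthS
  arr <- array(NA_real_, c(3, 3, cfg$hours),
               dimnames = list(STATE_CODES, STATE_CODES, NULL))
  for (h in seq_len(cfg$hours)) {
    zt <- (h - 1) %% 24 + 1
    light <- zt >= cfg$lightHours[1L] && zt <= cfg$lightHours[2L]
    pi <- if (light) cfg$piLight else cfg$piDark
    wakeBout <- if (light) cfg$meanWakeBoutLightS else cfg$meanWakeBoutDarkS
    if (!light && cfg$darkWakeGain != 1) wakeBout <- wakeBout * cfg$darkWakeGain
    pWW <- 1 - eps / wakeBout
    pRR <- 1 - eps / cfg$meanRemBoutS
    m <- transitionFromStationary(pi, pWW, pRR)
    if (zt >= 19 && zt <= 24 && cfg$lateDarkBoutShortening != 1) {
      s <- cfg$lateDarkBoutShortening  # divides mean sleep-bout durations
      m["N", ] <- c(m["N", "W"] * s, 1 - (1 - m["N", "N"]) * s,
                    m["N", "R"] * s)
      pRR2 <- 1 - (1 - pRR) * s
      m["R", ] <- c(1 - pRR2, 0, pRR2)
    }
    arr[, , h] <- m
  }
  arr
}

## Stationary distribution of a 3x3 row-stochastic matrix.
stationaryDistribution <- function(m) {
  e <- eigen(t(m))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), STATE_CODES)
}

## Vectorized Markov simulation: one column of states per subject.
simulateChain <- function(arr, nEpochs, epochsPerHr, nSubjects, initState) {
  cum1 <- apply(arr, 3, function(m) m[, 1L])           # 3 x hours
  cum2 <- apply(arr, 3, function(m) m[, 1L] + m[, 2L])
  out <- matrix(integer(0), nEpochs, nSubjects)
  state <- initState  # integer vector length nSubjects
  for (i in seq_len(nEpochs)) {
    h <- (i - 1L) %/% epochsPerHr + 1L
    u <- stats::runif(nSubjects)
    c1 <- cum1[state, h]
    c2 <- cum2[state, h]
    state <- 1L + (u > c1) + (u > c2)
    out[i, ] <- state
  }
  out
}

#' Simulate hypnograms from a Markov sleep model
#'
#' Epoch-level first-order Markov chain with hour-dependent transition
#' matrices (see [sleepSimConfig()]). The analytic stationary time-in-state
#' per hour implied by the matrices is attached as ground truth, making
#' every downstream estimate checkable by parameter recovery.
#'
#' @param cfg a [sleepSimConfig()].
#' @param seed integer seed; the generator is a pure function of
#'   `(cfg, seed)`.
#' @param nSubjects number of subjects (default from `cfg`).
#' @return a [Hypnogram-class] (or a list of them when `nSubjects > 1`);
#'   attribute `"groundTruth"` carries `piByHour` (hours x 3 stationary
#'   occupancies) and the transition array.
#' @export
simulateHypnogram <- function(cfg, seed, nSubjects = cfg$nSubjects) {
  stopifnot(inherits(cfg, "SleepSimConfig"))
  arr <- transitionMatrices(cfg)
  eph <- as.integer(3600 / cfg$epochLengthS)
  nEp <- cfg$hours * eph
  piByHour <- t(apply(arr, 3, stationaryDistribution))
  colnames(piByHour) <- STATE_CODES
  sim <- withSeed(seed, {
    init <- apply(stats::rmultinom(nSubjects, 1L, piByHour[1L, ]), 2,
                  which.max)
    simulateChain(arr, nEp, eph, nSubjects, as.integer(init))
  })
  gt <- list(piByHour = piByHour, transitions = arr)
  mk <- function(col) {
    hyp <- Hypnogram(STATE_CODES[col], epochLengthS = cfg$epochLengthS,
                     ztStartHour = 1)
    attr(hyp, "groundTruth") <- gt
    hyp
  }
  if (nSubjects == 1L) mk(sim[, 1L])
  else lapply(seq_len(nSubjects), function(j) mk(sim[, j]))
}

#' Apply an enforced-wakefulness (sleep deprivation) protocol
#'
#' Forces hours 1-5 to wakefulness except for independent per-epoch sleep
#' leaks (probability `cfg$sdLeakProb`, modelling the small efficacy gap of
#' gentle handling), then re-simulates the recovery phase from hour 6 so the
#' post-deprivation dynamics reflect the `onsetDelayGain` knob (wake-bout
#' durations scaled for `onsetDelaySpanH` hours after release).
#'
#' @param hyp a simulated [Hypnogram-class] covering at least hours 1-5.
#' @param cfg the [sleepSimConfig()] that generated it.
#' @param seed integer seed for the leak draws and the re-simulated recovery.
#' @param sdHours closed hour range of enforced wakefulness.
#' @return a [Hypnogram-class] with attribute `"sdInfo"` (deprivation window,
#'   leak probability, rebound parameters) used by [simulateEEG()] and
#'   [runHomeostasis()].
#' @export
applySleepDeprivation <- function(hyp, cfg, seed, sdHours = c(1, 5)) {
  eph <- epochsPerHour(hyp)
  sdIdx <- ztHourEpochs(hyp, sdHours)
  if (length(sdIdx) != (sdHours[2L] - sdHours[1L] + 1L) * eph)
    stop("deprivation window not fully inside the recording")
  states <- hyp@states
  arr <- transitionMatrices(cfg)
  span <- cfg$onsetDelaySpanH
  if (cfg$onsetDelayGain != 1 && span > 0) {
    for (h in seq_len(cfg$hours)) {
      zt <- h  # recording starts at hour 1
      if (zt > sdHours[2L] && zt <= sdHours[2L] + span) {
        pWW <- arr["W", "W", h]
        pWW2 <- 1 - (1 - pWW) / cfg$onsetDelayGain
        arr["W", , h] <- c(pWW2, arr["W", "N", h] / (1 - pWW) * (1 - pWW2), 0)
      }
    }
  }
  recStart <- max(sdIdx) + 1L
  nRec <- nEpochs(hyp) - recStart + 1L
  sim <- withSeed(seed, {
    leak <- stats::runif(length(sdIdx)) < cfg$sdLeakProb
    rec <- if (nRec > 0) {
      startHour <- (recStart - 1L) %/% eph  # 0-based hour offset
      subArr <- arr[, , (startHour + 1L):cfg$hours, drop = FALSE]
      simulateChain(subArr, nRec, eph, 1L, 1L)[, 1L]
    } else integer(0)
    list(leak = leak, rec = rec)
  })
  states[sdIdx] <- ifelse(sim$leak, "N", "W")
  if (nRec > 0) states[recStart:nEpochs(hyp)] <- STATE_CODES[sim$rec]
  out <- Hypnogram(states, epochLengthS = hyp@epochLengthS,
                   artifact = hyp@artifact, missing = hyp@missing,
                   ztStartHour = hyp@ztStartHour)
  attr(out, "groundTruth") <- attr(hyp, "groundTruth")
  attr(out, "sdInfo") <- list(sdHours = sdHours,
                              leakProb = cfg$sdLeakProb,
                              recoveryStartHour = sdHours[2L] + 1,
                              reboundDeltaGain = cfg$reboundDeltaGain,
                              reboundTauH = cfg$reboundTauH,
                              postSdBroadbandGain = cfg$postSdBroadbandGain)
  out
}

#' Simulate a cohort of sleep-deprivation-day hypnograms
#'
#' Generates deprivation-day recordings directly (no baseline day needed):
#' the enforced-wake window is wakefulness with independent per-epoch leaks
#' at `cfg$sdLeakProb`, and the recovery phase is simulated from release
#' with the `onsetDelayGain` knob applied, exactly as in
#' [applySleepDeprivation()]. All subjects run through the vectorized chain
#' engine, which makes large Monte-Carlo designs cheap.
#'
#' @param cfg a [sleepSimConfig()].
#' @param seed integer seed.
#' @param nSubjects number of subjects.
#' @param sdHours closed hour range of enforced wakefulness.
#' @return list of [Hypnogram-class] objects with `"sdInfo"` attributes
#'   (a single object when `nSubjects = 1`).
#' @export
simulateSleepDeprivedHypnograms <- function(cfg, seed,
                                            nSubjects = cfg$nSubjects,
                                            sdHours = c(1, 5)) {
  stopifnot(inherits(cfg, "SleepSimConfig"), cfg$hours > sdHours[2L],
            sdHours[1L] == 1)
  eph <- as.integer(3600 / cfg$epochLengthS)
  nSd <- (sdHours[2L] - sdHours[1L] + 1L) * eph
  nRec <- (cfg$hours - sdHours[2L]) * eph
  arr <- transitionMatrices(cfg)
  span <- cfg$onsetDelaySpanH
  if (cfg$onsetDelayGain != 1 && span > 0) {
    for (h in seq_len(cfg$hours)) {
      if (h > sdHours[2L] && h <= sdHours[2L] + span) {
        pWW <- arr["W", "W", h]
        pWW2 <- 1 - (1 - pWW) / cfg$onsetDelayGain
        arr["W", , h] <- c(pWW2, 1 - pWW2, 0)
      }
    }
  }
  sim <- withSeed(seed, {
    leak <- matrix(stats::runif(nSd * nSubjects) < cfg$sdLeakProb,
                   nSd, nSubjects)
    rec <- simulateChain(arr[, , (sdHours[2L] + 1L):cfg$hours,
                             drop = FALSE],
                         nRec, eph, nSubjects, rep(1L, nSubjects))
    list(leak = leak, rec = rec)
  })
  sdInfo <- list(sdHours = sdHours, leakProb = cfg$sdLeakProb,
                 recoveryStartHour = sdHours[2L] + 1,
                 reboundDeltaGain = cfg$reboundDeltaGain,
                 reboundTauH = cfg$reboundTauH,
                 postSdBroadbandGain = cfg$postSdBroadbandGain)
  mk <- function(j) {
    states <- c(ifelse(sim$leak[, j], "N", "W"), STATE_CODES[sim$rec[, j]])
    hyp <- Hypnogram(states, epochLengthS = cfg$epochLengthS,
                     ztStartHour = 1)
    attr(hyp, "sdInfo") <- sdInfo
    hyp
  }
  if (nSubjects == 1L) mk(1L) else lapply(seq_len(nSubjects), mk)
}

#' State-specific EEG spectral templates
#'
#' Per-state power-spectral templates on the standard bin grid: wakefulness
#' is broadband 1/f with modest low-frequency power, NREM adds a prominent
#' delta bump (argmax in 0.5-4 Hz), REM a theta peak (argmax in 5-9 Hz).
#' Units are arbitrary; every analysis normalization cancels them.
#'
#' @param binHz bin center grid.
#' @param epochSigma log-normal sigma of the per-epoch scalar power factor.
#' @param binSigma log-normal sigma of the per-bin multiplicative noise.
#' @return list with class `"EEGTemplateSet"`: `templates` (3 x bins matrix,
#'   rows W/N/R), `binHz`, `epochSigma`, `binSigma`.
#' @export
eegTemplates <- function(binHz = spectralConfig()$binHz,
                         epochSigma = 0.2, binSigma = 0.1) {
  f <- binHz
  w <- 1 / f^0.8 + 0.05
  n <- 2.5 / f + 1.6 * exp(-((f - 2) / 1.2)^2)
  r <- 0.6 / f + 1.2 * exp(-((f - 7) / 1.5)^2)
  tm <- rbind(W = w, N = n, R = r)
  colnames(tm) <- sprintf("%.3f", f)
  structure(list(templates = tm, binHz = f,
                 epochSigma = epochSigma, binSigma = binSigma),
            class = "EEGTemplateSet")
}

#' Simulate EEG spectra (or a signal) for a hypnogram
#'
#' For each recorded epoch, the power spectrum is the state's template
#' scaled by a log-normal per-epoch factor and per-bin multiplicative noise.
#' If the hypnogram carries an `"sdInfo"` attribute (from
#' [applySleepDeprivation()]), NREM epochs in the recovery phase receive the
#' configured delta rebound (delta bins multiplied by
#' `1 + (gain-1) * exp(-(hour - recoveryStart)/tau)`, stepped hourly) and,
#' during the first two recovery hours, the broadband (>= 3.9 Hz)
#' enhancement factor if one is configured.
#'
#' With `emit = "signal"` each epoch is synthesized as colored Gaussian
#' noise by spectral shaping with random phases (inverse FFT of the
#' template-shaped amplitude spectrum), suitable for [computeSpectralSeries()]
#' or EDF export.
#'
#' @param hyp a [Hypnogram-class].
#' @param templates an [eegTemplates()] set.
#' @param seed integer seed.
#' @param emit `"spectra"` (a [SpectralSeries-class]) or `"signal"` (numeric
#'   vector at `samplingRate`).
#' @param samplingRate sampling rate for signal synthesis.
#' @return a [SpectralSeries-class] or numeric signal vector.
#' @export
simulateEEG <- function(hyp, templates = eegTemplates(), seed,
                        emit = c("spectra", "signal"), samplingRate = 200) {
  emit <- match.arg(emit)
  tm <- templates$templates
  nb <- length(templates$binHz)
  if (ncol(tm) != nb) stop("template grid mismatch")
  n <- nEpochs(hyp)
  stateIdx <- match(hyp@states, STATE_CODES)
  reboundMul <- rep(1, n)
  broadMul <- rep(1, n)
  sdInfo <- attr(hyp, "sdInfo")
  if (!is.null(sdInfo)) {
    eph <- epochsPerHour(hyp)
    hourOf <- hyp@ztStartHour + (seq_len(n) - 1L) %/% eph
    rec <- sdInfo$recoveryStartHour
    g <- sdInfo$reboundDeltaGain
    isN <- !is.na(hyp@states) & hyp@states == "N"
    post <- hourOf >= rec
    reboundMul[isN & post] <-
      1 + (g - 1) * exp(-(hourOf[isN & post] - rec) / sdInfo$reboundTauH)
    if (!is.null(sdInfo$postSdBroadbandGain) &&
        sdInfo$postSdBroadbandGain != 1) {
      inWin <- hourOf >= rec & hourOf <= rec + 1
      broadMul[isN & inWin] <- sdInfo$postSdBroadbandGain
    }
  }
  deltaBins <- defaultBands(templates$binHz)$delta$bins
  broadBins <- which(templates$binHz >= 3.9)
  withSeed(seed, {
    epochFac <- exp(stats::rnorm(n, 0, templates$epochSigma))
    if (emit == "spectra") {
      power <- matrix(NA_real_, n, nb)
      ok <- which(!is.na(stateIdx))
      noise <- exp(matrix(stats::rnorm(length(ok) * nb, 0,
                                       templates$binSigma), length(ok), nb))
      base <- tm[stateIdx[ok], , drop = FALSE] * epochFac[ok] * noise
      base[, deltaBins] <- base[, deltaBins] * reboundMul[ok]
      base[, broadBins] <- base[, broadBins] * broadMul[ok]
      power[ok, ] <- base
      SpectralSeries(power, templates$binHz)
    } else {
      spe <- as.integer(round(hyp@epochLengthS * samplingRate))
      sig <- numeric(n * spe)
      for (i in seq_len(n)) {
        if (is.na(stateIdx[i])) next
        tgt <- tm[stateIdx[i], ] * epochFac[i]
        tgt[deltaBins] <- tgt[deltaBins] * reboundMul[i]
        tgt[broadBins] <- tgt[broadBins] * broadMul[i]
        sig[((i - 1L) * spe + 1L):(i * spe)] <-
          synthEpochSignal(tgt, templates$binHz, spe, samplingRate)
      }
      sig
    }
  })
}

## Colored-noise epoch via spectral shaping: random-phase inverse FFT whose
## one-sided PSD linearly interpolates the template over its band.
synthEpochSignal <- function(templatePSD, binHz, nSamples, fs) {
  df <- fs / nSamples
  freqs <- (1:(nSamples %/% 2 - 1L)) * df
  S <- stats::approx(binHz, templatePSD, xout = freqs, rule = 1)$y
  S[is.na(S)] <- 0
  amp <- sqrt(2 * S * df)
  phi <- stats::runif(length(freqs), 0, 2 * pi)
  Z <- complex(length.out = nSamples)
  Z[2:(nSamples %/% 2)] <- (nSamples * amp / 2) * exp(1i * phi)
  Z[nSamples:(nSamples %/% 2 + 2L)] <- Conj(Z[2:(nSamples %/% 2)])
  Re(stats::fft(Z, inverse = TRUE)) / nSamples
}

#' Wheel-running simulator configuration
#'
#' Activity is confined to a daily active window of length `alphaH` hours:
#' anchored to dark onset (hour 12) on LD days, drifting at the intrinsic
#' period `tauH` on DD days (each onset `tauH` hours after the previous).
#' Counts are Poisson with mean `meanCountsPerBin` inside the window and
#' `baselineRate` outside; in DD, active-window rates are multiplied by
#' `ddDecay` per completed DD week (amplitude decay of an unstable runner).
#'
#' @param days number of days.
#' @param schedule per-day `"LD"`/`"DD"` (recycled if length 1).
#' @param tauH intrinsic free-running period in hours (20-28).
#' @param alphaH active-phase duration in hours (< `tauH`).
#' @param meanCountsPerBin Poisson mean per 10-min bin inside the active
#'   window (default 600, i.e. ~36000 revolutions/day at alpha 10 h).
#' @param baselineRate Poisson mean outside the active window.
#' @param ddDecay weekly activity multiplier in DD (1 = stable).
#' @param binMin bin width in minutes.
#' @return list with class `"WheelSimConfig"`.
#' @export
wheelSimConfig <- function(days = 14, schedule = "LD", tauH = 24,
                           alphaH = 10, meanCountsPerBin = 600,
                           baselineRate = 2, ddDecay = 1, binMin = 10) {
  stopifnot(tauH >= 20, tauH <= 28, alphaH > 0, alphaH < tauH,
            meanCountsPerBin >= 0, baselineRate >= 0, ddDecay > 0)
  if (length(schedule) == 1L) schedule <- rep(schedule, days)
  stopifnot(length(schedule) == days, all(schedule %in% c("LD", "DD")))
  structure(as.list(environment()), class = "WheelSimConfig")
}

#' Simulate a wheel-running series
#'
#' @param cfg a [wheelSimConfig()].
#' @param seed integer seed.
#' @return a [WheelSeries-class]; attribute `"groundTruth"` records the
#'   active-window onsets and the configured period and alpha.
#' @export
simulateWheel <- function(cfg, seed) {
  stopifnot(inherits(cfg, "WheelSimConfig"))
  bpd <- as.integer(24 * 60 / cfg$binMin)
  nBins <- cfg$days * bpd
  binCenters <- (seq_len(nBins) - 0.5) * cfg$binMin / 60  # absolute hours
  onsets <- numeric(cfg$days)
  for (d in seq_len(cfg$days)) {
    onsets[d] <- if (cfg$schedule[d] == "LD" || d == 1L)
      (d - 1) * 24 + 12
    else onsets[d - 1L] + cfg$tauH
  }
  ddStart <- match("DD", cfg$schedule, nomatch = NA_integer_)
  rate <- rep(cfg$baselineRate, nBins)
  for (d in seq_len(cfg$days)) {
    act <- binCenters >= onsets[d] & binCenters < onsets[d] + cfg$alphaH
    lvl <- cfg$meanCountsPerBin
    if (!is.na(ddStart) && cfg$schedule[d] == "DD")
      lvl <- lvl * cfg$ddDecay^((d - ddStart) %/% 7L)
    rate[act] <- rate[act] + lvl
  }
  counts <- withSeed(seed, stats::rpois(nBins, rate))
  ws <- WheelSeries(counts, binMin = cfg$binMin, schedule = cfg$schedule)
  attr(ws, "groundTruth") <- list(onsetsH = onsets, tauH = cfg$tauH,
                                  alphaH = cfg$alphaH)
  ws
}
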