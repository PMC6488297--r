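test_that("generators are pure functions of (config, seed)", {
  cfg <- sleepSimConfig()
  h1 <- simulateHypnogram(cfg, seed = 7)
  h2 <- simulateHypnogram(cfg, seed = 7)
  expect_identical(epochStates(h1), epochStates(h2))
  expect_false(identical(epochStates(h1),
                         epochStates(simulateHypnogram(cfg, seed = 8))))
  w1 <- simulateWheel(wheelSimConfig(), seed = 3)
  w2 <- simulateWheel(wheelSimConfig(), seed = 3)
  expect_identical(wheelCounts(w1), wheelCounts(w2))
  tmpl <- eegTemplates()
  s1 <- simulateEEG(h1, tmpl, seed = 5)
  s2 <- simulateEEG(h1, tmpl, seed = 5)
  expect_identical(powerMatrix(s1), powerMatrix(s2))
  # the caller's RNG stream is untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(simulateHypnogram(cfg, seed = 9))
  expect_identical(rnorm(1), before)
})

test_that("transition matrices hit their stationary targets", {
  cfg <- sleepSimConfig()
  arr <- somnocirc:::transitionMatrices(cfg)
  for (h in c(1, 6, 12)) {
    expect_equal(unname(somnocirc:::stationaryDistribution(arr[, , h])),
                 unname(cfg$piLight), tolerance = 1e-9)
    expect_equal(rowSums(arr[, , h]), c(W = 1, N = 1, R = 1))
  }
  for (h in c(13, 20, 24))
    expect_equal(unname(somnocirc:::stationaryDistribution(arr[, , h])),
                 unname(cfg$piDark), tolerance = 1e-9)
  # REM reachable only from NREM
  expect_true(all(arr["W", "R", ] == 0))
  expect_true(all(arr["R", "N", ] == 0))
  expect_error(somnocirc:::transitionFromStationary(
    c(0.05, 0.05, 0.9), 0.99, 0.5), "infeasible")
})

test_that("an absorbing wake matrix yields an all-wake hypnogram", {
  cfg <- sleepSimConfig(piLight = c(W = 1 - 2e-9, N = 1e-9, R = 1e-9),
                        piDark = c(W = 1 - 2e-9, N = 1e-9, R = 1e-9),
                        meanWakeBoutLightS = 4e9, meanWakeBoutDarkS = 4e9)
  hyp <- simulateHypnogram(cfg, seed = 1)
  expect_true(all(epochStates(hyp) == "W"))
})

test_that("empirical light-period sleep matches the analytic target", {
  cfg <- sleepSimConfig()
  hyps <- simulateHypnogram(cfg, seed = 1234, nSubjects = 20)
  tst <- vapply(hyps, totalSleepTime, 0, period = "light")
  analytic <- 100 * (cfg$piLight[["N"]] + cfg$piLight[["R"]])
  expect_lt(abs(mean(tst) - analytic), 2)
  gt <- attr(hyps[[1]], "groundTruth")
  expect_equal(unname(gt$piByHour[1, ]), unname(cfg$piLight))
})

test_that("bout-shortening knob scales late-dark NREM bout durations", {
  # uniform day/night occupancy so blocks differ only through the knob
  base <- list(piLight = c(W = 0.4, N = 0.48, R = 0.12),
               piDark = c(W = 0.4, N = 0.48, R = 0.12),
               meanWakeBoutLightS = 120, meanWakeBoutDarkS = 120)
  cfg <- do.call(sleepSimConfig, c(base, list(lateDarkBoutShortening = 2)))
  ratios <- vapply(1:8, function(i) {
    hyp <- simulateHypnogram(cfg, seed = 400 + i)
    bs <- boutStatsByBlock(hyp)
    first <- bs$meanDurationS[bs$block == 1 & bs$state == "N"]
    last <- bs$meanDurationS[bs$block == 4 & bs$state == "N"]
    first / last
  }, 0)
  expect_lt(abs(mean(ratios) - 2), 0.4)
})

test_that("sleep deprivation forces wake with the configured leak", {
  cfg0 <- sleepSimConfig(sdLeakProb = 0)
  hyp <- simulateHypnogram(cfg0, seed = 20)
  sd0 <- applySleepDeprivation(hyp, cfg0, seed = 21)
  expect_equal(wakePercentage(sd0, c(1, 5)), 100)

  cfg3 <- sleepSimConfig(sdLeakProb = 0.03)
  wake <- vapply(1:10, function(i) {
    h <- simulateHypnogram(cfg3, seed = 500 + i)
    wakePercentage(applySleepDeprivation(h, cfg3, seed = 600 + i), c(1, 5))
  }, 0)
  expect_gt(mean(wake), 95)
  expect_lt(mean(wake), 99)
  # binomial oracle: mean leak 3%, so wake ~ 97% with SE ~ 0.08
  expect_lt(abs(mean(wake) - 97), 1)
})

test_that("cohort SD generator matches the single-subject path statistically", {
  cfg <- sleepSimConfig()
  cohort <- simulateSleepDeprivedHypnograms(cfg, seed = 700, nSubjects = 20)
  wakes <- vapply(cohort, wakePercentage, 0, windowHours = c(1, 5))
  expect_lt(abs(mean(wakes) - 97), 1)
  lat <- vapply(cohort, function(h)
    as.numeric(latencyToState(h, 6, "N")), 0)
  expect_true(all(is.finite(lat)))
  tis <- vapply(cohort, totalSleepTime, 0, period = c(6, 12))
  expect_gt(mean(tis), 50)  # recovery sleep present
})

test_that("EEG simulator recovers templates and the delta rebound", {
  tmpl <- eegTemplates()
  # zero template -> zero signal
  zt <- tmpl; zt$templates[] <- 0
  hyp <- Hypnogram(rep("N", 10))
  expect_true(all(simulateEEG(hyp, zt, seed = 1, emit = "signal") == 0))

  # state templates have their argmax in the expected bands
  expect_true(tmpl$binHz[which.max(tmpl$templates["N", ])] <= 4)
  peakR <- tmpl$binHz[which.max(tmpl$templates["R", ])]
  expect_true(peakR >= 5 && peakR <= 9)

  # rebound gain 1.4 -> first recovery hour reads ~140
  cfg <- sleepSimConfig(reboundDeltaGain = 1.4)
  firstHour <- vapply(1:10, function(i) {
    hypB <- simulateHypnogram(cfg, seed = 800 + i)
    hypS <- applySleepDeprivation(hypB, cfg, seed = 900 + i)
    specB <- simulateEEG(hypB, tmpl, seed = 1000 + i)
    specS <- simulateEEG(hypS, tmpl, seed = 1100 + i)
    dt <- deltaTimecourse(specS, hypS, specB, hypB)
    dt$deltaPct[dt$hour == 6]
  }, 0)
  expect_lt(abs(mean(firstHour) - 140), 10)
})

test_that("signal synthesis reproduces the target spectrum shape", {
  tmpl <- eegTemplates(epochSigma = 0, binSigma = 0)
  hyp <- Hypnogram(rep("N", 200))
  sig <- simulateEEG(hyp, tmpl, seed = 44, emit = "signal")
  spec <- computeSpectralSeries(sig, hyp)
  m <- stateMeanSpectrum(spec, hyp, "N")$spectrum
  tref <- tmpl$templates["N", ]
  cs <- sum(m * tref) / sqrt(sum(m^2) * sum(tref^2))
  expect_gt(cs, 0.9)
})

test_that("wheel simulator honors trivial and entrained configurations", {
  none <- simulateWheel(wheelSimConfig(meanCountsPerBin = 0,
                                       baselineRate = 0), seed = 1)
  expect_true(all(wheelCounts(none) == 0))
  ld <- simulateWheel(wheelSimConfig(days = 14, schedule = "LD"), seed = 2)
  expect_equal(peakPeriod(chiSquaredPeriodogram(ld)), 24.0)
  expect_error(wheelSimConfig(tauH = 19))
  expect_error(wheelSimConfig(alphaH = 25, tauH = 24))
})
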