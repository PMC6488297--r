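test_that("spectral grid follows from sampling rate and window length", {
  cfg <- spectralConfig()
  expect_equal(cfg$binWidthHz, 200 / 256)
  expect_equal(length(cfg$binHz), 25L)
  expect_equal(cfg$binHz, (1:25) * 0.78125)
})

test_that("band-to-bin mapping by center inclusion", {
  bands <- defaultBands()
  expect_equal(bands$delta$bins, 1:5)
  expect_equal(bands$theta$bins, 7:11)
  expect_equal(bands$alpha$bins, 13:19)
  flat <- rep(1, 25)
  expect_equal(bandPower(flat, bands$delta), 5)
  expect_equal(bandPower(rep(0, 25), bands$theta), 0)
  set.seed(9)
  for (i in 1:20) {
    sp <- runif(25)
    expect_lte(bandPower(sp, bands$delta) + bandPower(sp, bands$theta) +
                 bandPower(sp, bands$alpha), sum(sp) + 1e-12)
  }
})

test_that("epochPSD: zero input, Parseval on white noise, NaN flagging", {
  cfg <- spectralConfig()
  expect_true(all(epochPSD(rep(0, 800), cfg) == 0))

  cfgFull <- spectralConfig(fMax = 100)
  set.seed(11)
  tot <- 0
  nEp <- 300
  for (i in seq_len(nEp))
    tot <- tot + sum(epochPSD(rnorm(800), cfgFull)) * cfgFull$binWidthHz
  expect_equal(tot / nEp, 1, tolerance = 0.05)

  bad <- rnorm(800); bad[5] <- NaN
  p <- epochPSD(bad, cfg)
  expect_true(all(is.na(p)))
  expect_true(attr(p, "artifact"))
  expect_error(epochPSD(rnorm(100), cfg), "too short")
})

test_that("an on-bin sinusoid concentrates in its bin (untapered)", {
  cfg <- spectralConfig(taper = "boxcar")
  x <- sin(2 * pi * 5 * cfg$binWidthHz * (0:799) / 200)
  p <- epochPSD(x, cfg)
  expect_gte(p[5] / sum(p), 0.90)
  # direct DFT oracle on one 256-sample segment
  seg <- x[1:256] - mean(x[1:256])
  dft <- abs(fft(seg))^2
  expect_gte(dft[6] / sum(dft[2:129]), 0.90)
})

test_that("state mean spectra exclude artifacts and recover templates", {
  # identical spectra -> that spectrum
  hyp <- Hypnogram(rep("N", 100))
  sp <- matrix(rep(1:25, each = 100), 100, 25)
  ss <- SpectralSeries(sp, defaultGrid)
  m <- stateMeanSpectrum(ss, hyp, "N")
  expect_equal(m$spectrum, as.numeric(1:25))
  expect_equal(m$nEpochs, 100L)

  # artifact epochs with wild spectra never influence the mean
  art <- rep(c(TRUE, FALSE), 50)
  sp2 <- sp; sp2[art, ] <- sp2[art, ] * 1000
  hyp2 <- Hypnogram(rep("N", 100), artifact = art)
  ss2 <- SpectralSeries(sp2, defaultGrid)
  expect_equal(stateMeanSpectrum(ss2, hyp2, "N")$spectrum,
               as.numeric(1:25))
  expect_equal(stateMeanSpectrum(ss2, hyp2, "N")$nEpochs, 50L)

  # metamorphic: perturbing artifact epochs leaves aggregates bit-identical
  sp3 <- sp2; sp3[art, ] <- runif(sum(art) * 25)
  expect_identical(stateMeanSpectrum(SpectralSeries(sp3, defaultGrid),
                                     hyp2, "N")$spectrum,
                   stateMeanSpectrum(ss2, hyp2, "N")$spectrum)

  # zero qualifying epochs -> explicit empty result
  empty <- stateMeanSpectrum(ss, hyp, "R")
  expect_equal(empty$nEpochs, 0L)
  expect_true(all(is.na(empty$spectrum)))

  # template recovery from the simulator
  tmpl <- eegTemplates()
  hypN <- Hypnogram(rep("N", 600))
  specN <- simulateEEG(hypN, tmpl, seed = 21)
  mN <- stateMeanSpectrum(specN, hypN, "N")$spectrum
  cs <- sum(mN * tmpl$templates["N", ]) /
    sqrt(sum(mN^2) * sum(tmpl$templates["N", ]^2))
  expect_gt(cs, 0.99)
})

test_that("state-total-power normalization sums to 100", {
  hyp <- Hypnogram(rep(c("N", "W"), 12 * 450))
  set.seed(3)
  ss <- SpectralSeries(matrix(runif(nEpochs(hyp) * 25, 0.5, 2),
                              nEpochs(hyp), 25), defaultGrid)
  for (state in c("N", "W")) {
    ns <- normalizeStateTotalPower(ss, hyp, state, "light")
    expect_equal(sum(ns), 100, tolerance = 1e-9)
  }
  expect_equal(normalizeSpectrum(rep(2, 25)), rep(4, 25))
  expect_error(normalizeSpectrum(rep(0, 25)), "zero")

  # delta-enhanced template sits above 4%/bin in delta, below elsewhere
  tmpl <- eegTemplates()$templates["N", ]
  pct <- normalizeSpectrum(tmpl)
  expect_true(all(pct[1:5] > 4))
  expect_true(mean(pct[13:25] < 4) == 1)
})

test_that("delta timecourse self-normalizes its baseline window to 100", {
  hyp <- Hypnogram(rep(rep(c("N", "W"), each = 450), 12))
  set.seed(4)
  ss <- SpectralSeries(matrix(rexp(nEpochs(hyp) * 25), ncol = 25),
                       defaultGrid)
  dt <- deltaTimecourse(ss, hyp)
  expect_equal(mean(dt$deltaPct[dt$hour %in% 9:12]), 100, tolerance = 1e-9)

  # hour at exactly 1.5x baseline mean reads 150
  base <- mean(rowSums(
    powerMatrix(ss)[somnocirc:::qualifyingEpochs(ss, hyp, "N", c(9, 12)),
                    1:5, drop = FALSE]))
  p2 <- powerMatrix(ss)
  idx1 <- somnocirc:::qualifyingEpochs(ss, hyp, "N", c(1, 1))
  p2[idx1, 1:5] <- 1.5 * base / 5  # each delta bin -> epoch delta = 1.5x base
  ss2 <- SpectralSeries(p2, defaultGrid)
  dt2 <- deltaTimecourse(ss2, hyp, baselineSpec = ss, baselineHyp = hyp)
  expect_equal(dt2$deltaPct[1], 150, tolerance = 1e-9)

  # hours without NREM yield NA; missing baseline NREM errors
  hypW <- Hypnogram(c(rep("W", 900), rep("N", 11 * 900)))
  dt3 <- deltaTimecourse(ss, hypW, baselineSpec = ss, baselineHyp = hyp)
  expect_true(is.na(dt3$deltaPct[1]))
  expect_error(deltaTimecourse(ss, hyp, baselineSpec = ss,
                               baselineHyp = Hypnogram(rep("W", 12 * 900))),
               "no NREM")
})

test_that("recovery spectra normalize bin-by-bin against baseline", {
  hyp <- Hypnogram(rep("N", 12 * 900))
  set.seed(6)
  base <- matrix(rep(runif(25, 1, 2), each = nEpochs(hyp)),
                 nEpochs(hyp), 25)
  ssB <- SpectralSeries(base, defaultGrid)
  expect_equal(as.numeric(recoverySpectrumNormalized(ssB, hyp, ssB, hyp,
                                                     windowHours = c(6, 7))),
               rep(100, 25))

  doubled <- base; doubled[, 5:25] <- 2 * doubled[, 5:25]
  ssD <- SpectralSeries(doubled, defaultGrid)
  r <- recoverySpectrumNormalized(ssD, hyp, ssB, hyp, windowHours = c(6, 7))
  expect_equal(unname(r[5:25]), rep(200, 21))
  expect_equal(unname(r[1:4]), rep(100, 4))

  # zero baseline bins are flagged, not dropped
  z <- base; z[, 3] <- 0
  expect_warning(
    rz <- recoverySpectrumNormalized(ssB, hyp, SpectralSeries(z, defaultGrid),
                                     hyp, windowHours = c(6, 7)),
    "flagged")
  expect_true(is.na(rz[3]))
  expect_equal(attr(rz, "flaggedBins"), 3L)
})

test_that("simulated broadband post-SD enhancement lands in bins 5-25", {
  cfg <- sleepSimConfig(postSdBroadbandGain = 1.5, reboundDeltaGain = 1,
                        sdLeakProb = 0)
  hypB <- simulateHypnogram(cfg, seed = 31)
  hypS <- applySleepDeprivation(hypB, cfg, seed = 32)
  tmpl <- eegTemplates(binSigma = 0.02, epochSigma = 0.02)
  specB <- simulateEEG(hypB, tmpl, seed = 33)
  specS <- simulateEEG(hypS, tmpl, seed = 34)
  r <- recoverySpectrumNormalized(specS, hypS, specB, hypB,
                                  windowHours = c(6, 7))
  expect_true(all(r[5:25] > 130))
  expect_true(all(r[1:4] < 115))
})

test_that("spectra CSV round-trips on the labeled bin grid", {
  set.seed(8)
  ss <- SpectralSeries(matrix(runif(50 * 25), 50, 25), defaultGrid)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  writeSpectraCsv(ss, f)
  back <- readSpectraCsv(f)
  expect_equal(binFrequencies(back), round(defaultGrid, 3))
  expect_equal(powerMatrix(back), powerMatrix(ss), tolerance = 1e-6,
               ignore_attr = TRUE)
})
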