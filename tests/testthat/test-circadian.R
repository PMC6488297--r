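test_that("periodogram finds a noiseless square wave's period exactly", {
  # period 144 bins = 24.0 h, 14 days
  x <- rep(rep(c(0, 100), each = 72), 14)
  pg <- chiSquaredPeriodogram(x)
  expect_equal(peakPeriod(pg), 24.0)
  expect_true(peakSignificant(pg))
  tb <- periodogramTable(pg)
  expect_equal(tb$df, (120:168) - 1)
  expect_true(all(tb$qp >= 0, na.rm = TRUE))
})

test_that("periodogram recovers any on-grid period of a noiseless input", {
  for (pBins in c(126, 138, 150, 165)) {  # 21.0, 23.0, 25.0, 27.5 h
    pat <- rep(c(rep(0, pBins %/% 2), rep(60, pBins - pBins %/% 2)), 30)
    x <- pat[1:3024]  # 21 days
    pg <- chiSquaredPeriodogram(x)
    expect_equal(peakPeriod(pg), pBins / 6, tolerance = 1e-9)
  }
})

test_that("Qp is invariant under affine rescaling of counts", {
  set.seed(51)
  ws <- simulateWheel(wheelSimConfig(days = 14), seed = 3)
  x <- wheelCounts(ws)
  q1 <- periodogramTable(chiSquaredPeriodogram(x))$qp
  q2 <- periodogramTable(chiSquaredPeriodogram(3.7 * x + 11))$qp
  expect_equal(q1, q2, tolerance = 1e-9)
})

test_that("periodogram errors on constants and short series", {
  expect_error(chiSquaredPeriodogram(rep(5, 3024)), "zero variance")
  expect_error(chiSquaredPeriodogram(rnorm(600)), "at least 7 days")
})

test_that("simulated free-run period and LD entrainment are recovered", {
  ws <- simulateWheel(wheelSimConfig(days = 14, schedule = "LD"), seed = 61)
  expect_equal(peakPeriod(chiSquaredPeriodogram(ws)), 24.0)
  wsDD <- simulateWheel(wheelSimConfig(days = 14, schedule = "DD",
                                       tauH = 23.5), seed = 62)
  expect_lte(abs(peakPeriod(chiSquaredPeriodogram(wsDD)) - 23.5), 0.17)
})

test_that("onset/offset detect a dark-phase-filling active window", {
  ws <- simulateWheel(wheelSimConfig(days = 14, schedule = "LD",
                                     alphaH = 12), seed = 71)
  oo <- detectOnsetOffset(ws, 5)
  expect_equal(oo$onsetH, 12, tolerance = 1 / 6 + 1e-9)
  expect_equal(oo$offsetH, 24, tolerance = 1 / 6 + 1e-9)

  zero <- WheelSeries(rep(0, 2 * 144), schedule = rep("LD", 2))
  expect_true(is.na(detectOnsetOffset(zero, 1)$onsetH))
})

test_that("simulated alpha of 10 h is recovered within 0.5 h", {
  ws <- simulateWheel(wheelSimConfig(days = 14, schedule = "LD",
                                     alphaH = 10), seed = 81)
  alphas <- vapply(seq_len(14), function(d)
    detectOnsetOffset(ws, d)$alphaH, 0)
  expect_lt(abs(mean(alphas, na.rm = TRUE) - 10), 0.5)
})

test_that("weekly summaries report period, alpha and mean daily activity", {
  cfg <- wheelSimConfig(days = 35, schedule = c(rep("LD", 14), rep("DD", 21)),
                        tauH = 23.7, ddDecay = 0.6)
  ws <- simulateWheel(cfg, seed = 91)
  wk <- weeklySummary(ws)
  expect_equal(wk$week, c("LD Week 1", "LD Week 2", "DD Week 1",
                          "DD Week 2", "DD Week 3"))
  expect_equal(wk$periodH[1:2], c(24, 24))
  expect_true(all(abs(wk$periodH[3:5] - 23.7) <= 0.2))
  expect_true(all(wk$periodSignificant))
  # mean daily revolutions equals total counts / days for each week
  bpd <- 144
  for (i in seq_len(5)) {
    days <- ((i - 1) * 7 + 1):(i * 7)
    tot <- sum(wheelCounts(ws)[((days[1] - 1) * bpd + 1):(days[7] * bpd)])
    expect_equal(wk$activityRevPerDay[i], tot / 7)
  }
  # DD decay knob produces a monotone weekly activity decline
  expect_true(all(diff(wk$activityRevPerDay[3:5]) < 0))
})

test_that("actogram matrices conserve counts and double-plot correctly", {
  ws <- WheelSeries(seq_len(2 * 144), schedule = rep("LD", 2))
  m <- buildActogram(ws)
  expect_equal(dim(m), c(2L, 144L))
  expect_equal(sum(m), sum(wheelCounts(ws)))
  expect_equal(colSums(m), wheelCounts(ws)[1:144] + wheelCounts(ws)[145:288])
  d <- buildActogram(ws, doublePlotted = TRUE)
  expect_equal(dim(d), c(2L, 288L))
  expect_equal(d[1, ], c(m[1, ], m[2, ]), ignore_attr = TRUE)
  expect_true(all(is.na(d[2, 145:288])))
})

test_that("free-running onset drifts by (24 - tau) * 6 bins per day", {
  tau <- 23.5
  ws <- simulateWheel(wheelSimConfig(days = 14, schedule = "DD", tauH = tau,
                                     baselineRate = 0), seed = 95)
  m <- buildActogram(ws)
  onsetBin <- apply(m, 1, function(r) which(r > 100)[1])
  drift <- diff(onsetBin)
  expect_equal(mean(drift), -(24 - tau) * 6, tolerance = 0.2)
})

test_that("wheel CSV and AWD files round-trip to identical metrics", {
  ws <- simulateWheel(wheelSimConfig(days = 14), seed = 99)
  fc <- tempfile(fileext = ".csv"); fa <- tempfile(fileext = ".awd")
  on.exit(unlink(c(fc, fa)))
  writeWheelCsv(ws, fc)
  writeAWD(ws, fa)
  b1 <- readWheelCsv(fc, schedule = lightSchedule(ws))
  b2 <- readAWD(fa, schedule = lightSchedule(ws))
  expect_equal(wheelCounts(b1), wheelCounts(ws))
  expect_equal(wheelCounts(b2), wheelCounts(ws))
  expect_equal(b2@binMin, 10)
  expect_equal(peakPeriod(chiSquaredPeriodogram(b1)),
               peakPeriod(chiSquaredPeriodogram(b2)))
})
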