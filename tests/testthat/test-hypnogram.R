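test_that("validateHypnogram handles clean input, bad codes, and gaps", {
  raw <- data.frame(epoch_index = 0:899, zt_seconds = (0:899) * 4,
                    state = "N", artifact = 0L)
  hyp <- validateHypnogram(raw)
  expect_s4_class(hyp, "Hypnogram")
  expect_equal(nEpochs(hyp), 900L)
  expect_equal(attr(hyp, "report")$stateCounts[["N"]], 900L)
  expect_equal(attr(hyp, "report")$nMissing, 0L)

  bad <- raw; bad$state[11] <- "X"
  expect_error(validateHypnogram(bad), "unknown state code 'X' at epoch 10")

  shuffled <- raw[c(2, 1, 3:900), ]
  expect_error(validateHypnogram(shuffled), "non-monotone")

  # a 10-epoch gap inside hour 1 -> 10 missing epochs, hour invalid
  gap <- raw[-(101:110), ]
  hg <- validateHypnogram(gap)
  expect_equal(sum(isMissing(hg)), 10L)
  tab <- timeInStateHourly(hg)
  expect_false(tab$valid[1])
  expect_equal(tab$nEpochs[1], 890L)
})

test_that("segmentBouts returns maximal runs that tile the recording", {
  hyp <- Hypnogram(c("W", "W", "N", "N", "N", "R", "W"))
  b <- segmentBouts(hyp)
  expect_equal(b$state, c("W", "N", "R", "W"))
  expect_equal(b$nEpochs, c(2L, 3L, 1L, 1L))
  expect_equal(b$startEpoch, c(0L, 2L, 5L, 6L))
  expect_equal(b$durationS, c(8, 12, 4, 4))

  one <- segmentBouts(Hypnogram(rep("N", 900)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$durationS, 3600)

  expect_error(segmentBouts(new("Hypnogram", states = character(0),
                                artifact = logical(0), missing = logical(0),
                                epochLengthS = 4, ztStartHour = 1)))
})

test_that("per-state bout epoch totals match per-state epoch counts", {
  set.seed(101)
  hyp <- randomHypnogram(10000)
  b <- segmentBouts(hyp)
  for (s in c("W", "N", "R")) {
    expect_equal(sum(b$nEpochs[!is.na(b$state) & b$state == s]),
                 sum(epochStates(hyp) == s))
  }
})

test_that("hourly state percentages are correct and conserve to 100", {
  hyp <- blockHypnogram(list(
    list(states = "W", times = 900),
    list(states = c("W", "N", "R"), times = c(450, 300, 150))))
  tab <- timeInStateHourly(hyp)
  expect_equal(tab$pctW, c(100, 50))
  expect_equal(tab$pctN[2], 100 * 300 / 900)
  expect_equal(tab$pctR[2], 100 * 150 / 900)
  expect_true(all(abs(tab$pctW + tab$pctN + tab$pctR - 100) < 1e-9))

  short <- Hypnogram(rep("W", 600))  # only 600 epochs recorded that hour
  expect_false(timeInStateHourly(short)$valid[1])
})

test_that("total sleep time and wake percentage are complementary", {
  hyp <- patternHypnogram(c(rep("N", 2), "R", "W"), hours = 24)
  expect_equal(totalSleepTime(hyp, "light"), 75)
  expect_equal(totalSleepTime(hyp, "dark"), 75)
  expect_equal(wakePercentage(hyp, c(1, 12)) + totalSleepTime(hyp, "light"),
               100)
  allWake <- patternHypnogram("W", hours = 24)
  expect_equal(totalSleepTime(allWake, "light"), 0)
  expect_error(totalSleepTime(Hypnogram(rep("W", 600)), "dark"),
               "no valid hours")
})

test_that("wake percentage counts forced-wake windows with leaks", {
  # 4500-epoch window with 135 sleep epochs -> 97.0%
  st <- rep("W", 4500)
  st[seq_len(135)] <- "N"
  hyp <- Hypnogram(c(st, rep("N", 900)))
  expect_equal(wakePercentage(hyp, c(1, 5)), 97)
  expect_equal(wakePercentage(patternHypnogram("W", 5), c(1, 5)), 100)
  expect_error(wakePercentage(patternHypnogram("W", 2), c(5, 6)))
})

test_that("bouts are assigned to the block containing their start epoch", {
  # one NREM bout spanning hours 5-7 starts in block 1 (hours 1-6)
  st <- rep("W", 24 * 900)
  st[(4 * 900 + 1):(7 * 900)] <- "N"
  hyp <- Hypnogram(st)
  bs <- boutStatsByBlock(hyp)
  nrow1 <- bs[bs$block == 1 & bs$state == "N", ]
  nrow2 <- bs[bs$block == 2 & bs$state == "N", ]
  expect_equal(nrow1$nBouts, 1L)
  expect_equal(nrow2$nBouts, 0L)
  expect_equal(nrow1$meanDurationS, 3 * 3600)

  # alternating W/N: bout count equals epochs in block, mean duration 4 s
  alt <- patternHypnogram(c("W", "N"), hours = 24)
  ba <- boutStatsByBlock(alt)
  expect_equal(sum(ba$nBouts[ba$block == 1]), 6 * 900)
  expect_equal(unique(ba$meanDurationS[!is.na(ba$meanDurationS)]), 4)
  expect_error(boutStatsByBlock(alt, blockHours = 5), "divide 24")
})

test_that("latency skips sub-threshold runs and reports unreached onsets", {
  # first 7-epoch N run starts 150 epochs after t0 -> 600 s
  st <- rep("W", 2 * 900)
  st[151:157] <- "N"
  hyp <- Hypnogram(st)
  expect_equal(as.numeric(latencyToState(hyp, 1, "N")), 600)

  # repeated 6-epoch runs ignored; first qualifying run at epoch 300
  st2 <- rep("W", 2 * 900)
  for (s in c(51, 101, 201)) st2[s:(s + 5)] <- "N"
  st2[301:307] <- "N"
  hyp2 <- Hypnogram(st2)
  expect_equal(as.numeric(latencyToState(hyp2, 1, "N")), 1200)

  lat <- latencyToState(patternHypnogram("W", 2), 1, "N")
  expect_true(is.na(lat))
  expect_false(attr(lat, "reached"))
})

test_that("latency is monotone non-increasing as the criterion weakens", {
  set.seed(77)
  for (rep in 1:50) {
    hyp <- randomHypnogram(600)
    lats <- sapply(1:8, function(k)
      as.numeric(latencyToState(hyp, 1, "N",
                                latencyCriteria(nremMinEpochs = k))))
    lats[is.na(lats)] <- Inf
    expect_false(is.unsorted(lats))
  }
})

test_that("hypnogram CSV round-trips including missing epochs", {
  set.seed(5)
  hyp <- randomHypnogram(1800, pMissing = 0.01)
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  writeHypnogramCsv(hyp, f)
  back <- readHypnogramCsv(f)
  expect_equal(epochStates(back)[seq_len(max(which(!is.na(epochStates(hyp)))))],
               epochStates(hyp)[seq_len(max(which(!is.na(epochStates(hyp)))))])
  expect_equal(ztStart(back), 1)
})
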