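# Shared fixtures, built in code.

# Hypnogram with exactly the requested per-hour composition.
blockHypnogram <- function(hourStates, perHour = 900, epochLengthS = 4) {
  Hypnogram(unlist(lapply(hourStates, function(h) rep(h$states, h$times))),
            epochLengthS = epochLengthS)
}

# n hours of a repeating state pattern.
patternHypnogram <- function(pattern, hours = 1, epochLengthS = 4) {
  eph <- 3600 / epochLengthS
  Hypnogram(rep(pattern, length.out = hours * eph),
            epochLengthS = epochLengthS)
}

# Random valid hypnogram (possibly with missing gaps) for property tests.
randomHypnogram <- function(n, pMissing = 0, epochLengthS = 4) {
  st <- sample(c("W", "N", "R"), n, replace = TRUE)
  if (pMissing > 0) st[runif(n) < pMissing] <- NA
  Hypnogram(st, epochLengthS = epochLengthS)
}

# Brute-force bout segmentation oracle: a plain loop, independent of rle().
boutOracle <- function(states) {
  out <- list()
  start <- 1L
  for (i in seq_along(states)[-1L]) {
    same <- identical(states[i], states[start]) ||
      (is.na(states[i]) && is.na(states[start]))
    if (!same) {
      out[[length(out) + 1L]] <- c(start, i - start)
      start <- i
    }
  }
  out[[length(out) + 1L]] <- c(start, length(states) - start + 1L)
  data.frame(startEpoch = vapply(out, `[`, 0, 1L) - 1L,
             nEpochs = vapply(out, `[`, 0, 2L))
}

# Brute-force latency oracle: scan every epoch for a qualifying run.
latencyOracle <- function(states, startIdx, state, minEp, epochLengthS = 4) {
  n <- length(states)
  for (i in startIdx:n) {
    if (i + minEp - 1L > n) break
    seg <- states[i:(i + minEp - 1L)]
    if (all(!is.na(seg) & seg == state))
      return((i - startIdx) * epochLengthS)
  }
  NA_real_
}

# Closed-form Welch t-test oracle (no stats::t.test involved).
welchOracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# Manual Benjamini-Hochberg step-up oracle.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

defaultGrid <- spectralConfig()$binHz
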