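#' Two-sample t-test (Welch by default)
#'
#' Unpaired two-sample t-test. The Welch (unequal-variance) form with
#' Satterthwaite degrees of freedom is the default because group spectral
#' and latency comparisons routinely involve unequal within-group variances;
#' the classic pooled form is available via `varEqual = TRUE`.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @param varEqual use the pooled-variance form.
#' @return list with class `"TestResult"`: `statistic`, `df` (fractional for
#'   Welch), `pValue`, and group means +/- SEM.
#' @export
welchT <- function(a, b, varEqual = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each sample must contain at least two observations")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both samples")
  tt <- stats::t.test(a, b, var.equal = varEqual)
  structure(list(
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    pValue = tt$p.value,
    meanA = mean(a), semA = stats::sd(a) / sqrt(length(a)),
    meanB = mean(b), semB = stats::sd(b) / sqrt(length(b))
  ), class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("t(%.2f) = %.3f, p = %.4g\n", x$df, x$statistic, x$pValue))
  cat(sprintf("  group A: %.4g +/- %.4g   group B: %.4g +/- %.4g\n",
              x$meanA, x$semA, x$meanB, x$semB))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; monotone, clipped at 1, input
#' order preserved.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Penalized-spline smooth with pointwise 95% confidence interval
#'
#' Fits a penalized cubic regression spline (basis dimension `k`, smoothing
#' parameter chosen by generalized cross-validation) and evaluates fit and
#' pointwise 95% interval (fit +/- 1.96 standard errors) on a common grid.
#'
#' @param x,y numeric vectors, at least 10 points, `x` not all equal.
#' @param k spline basis dimension (default 20, reduced if `x` has fewer
#'   distinct values).
#' @param grid evaluation grid; default 200 equispaced points over
#'   `range(x)`.
#' @return list with class `"SmoothFit"`: `grid`, `fit`, `lo`, `hi`, `edf`.
#' @export
smoothWithCI <- function(x, y, k = 20, grid = NULL) {
  stopifnot(length(x) == length(y))
  if (length(x) < 10) stop("need at least 10 points")
  if (diff(range(x)) == 0) stop("x values are all equal (degenerate)")
  k <- min(k, length(unique(x)) - 1L)
  dat <- data.frame(x = x, y = y)
  fit <- mgcv::gam(y ~ s(x, k = k, bs = "cr"), data = dat)
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 200L)
  pr <- mgcv::predict.gam(fit, newdata = data.frame(x = grid), se.fit = TRUE)
  structure(list(grid = grid,
                 fit = as.numeric(pr$fit),
                 lo = as.numeric(pr$fit - 1.96 * pr$se.fit),
                 hi = as.numeric(pr$fit + 1.96 * pr$se.fit),
                 edf = sum(fit$edf)),
            class = "SmoothFit")
}

#' @export
print.SmoothFit <- function(x, ...) {
  cat(sprintf("SmoothFit: %d grid points over [%.4g, %.4g], edf = %.2f\n",
              length(x$grid), min(x$grid), max(x$grid), x$edf))
  invisible(x)
}

#' Intervals where two confidence bands do not overlap
#'
#' Non-overlap of pointwise 95% confidence intervals is used as the
#' significance criterion when comparing smoothed spectra between groups.
#' Returns the maximal grid intervals on which the two bands are disjoint.
#'
#' @param fitA,fitB [smoothWithCI()] results on the identical grid.
#' @return data.frame with columns `fromIdx`, `toIdx`, `from`, `to`
#'   (grid indices and grid values); zero rows when the bands always overlap.
#' @export
ciNonoverlap <- function(fitA, fitB) {
  if (length(fitA$grid) != length(fitB$grid) ||
      !isTRUE(all.equal(fitA$grid, fitB$grid)))
    stop("fits must share an identical grid")
  disjoint <- fitA$hi < fitB$lo | fitB$hi < fitA$lo
  runsToIntervals(disjoint, fitA$grid)
}

## maximal TRUE runs of a logical vector -> interval table
runsToIntervals <- function(flag, grid) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(fromIdx = starts[keep], toIdx = ends[keep],
             from = grid[starts[keep]], to = grid[ends[keep]])
}
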