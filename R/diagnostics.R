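#' Summarize the distribution of window GC residuals
#'
#' Computes moment and histogram summaries of the residuals \eqn{D_i} of a
#' window profile, together with the matched Gaussian reference (a normal
#' density with the same mean and standard deviation as the residuals).
#' For most prokaryotic chromosomes the residual distribution is close to
#' Gaussian, consistent with window GC being a sum of many weakly coupled
#' per-base contributions; strong departures (bimodality, heavy skew) point
#' to compositional substructure such as large GC-shifted islands.
#'
#' @param profile A [WindowProfile-class] with at least 2 windows.
#' @param nBins Number of equal-width histogram bins over
#'   `[min(D), max(D)]` (default 30).
#' @return A [DensitySummary-class]. When the residuals have zero variance
#'   the summary is flagged degenerate and skewness/kurtosis are `NA`.
#' @examples
#' g <- simulateIidGenome(gc = 0.5, length = 20000, seed = 1)
#' residualDensity(scanWindows(g, 100))
#' @importFrom e1071 skewness kurtosis
#' @importFrom stats sd
#' @export
residualDensity <- function(profile, nBins = 30L) {
  stopifnot(is(profile, "WindowProfile"))
  d <- gcResiduals(profile)
  n <- length(d)
  if (n < 2L)
    stop("need at least 2 windows to summarize residuals (got ", n, ")")
  if (nBins < 1L) stop("'nBins' must be >= 1")
  m <- mean(d)
  s <- sd(d)
  degenerate <- s == 0
  if (degenerate) {
    breaks <- c(d[1L] - 0.5, d[1L] + 0.5)
    counts <- n
    skew <- NA_real_
    kurt <- NA_real_
  } else {
    breaks <- seq(min(d), max(d), length.out = nBins + 1L)
    h <- graphics::hist(d, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    counts <- h$counts
    skew <- e1071::skewness(d, type = 1)
    kurt <- e1071::kurtosis(d, type = 1)
  }
  new("DensitySummary",
      chromosomeId = chromosomeId(profile),
      n = as.integer(n),
      mean = m, sd = s,
      skewness = skew, excessKurtosis = kurt,
      breaks = as.numeric(breaks), counts = as.integer(counts),
      gaussianMean = m, gaussianSd = s,
      degenerate = degenerate)
}

#' Classify a residual distribution against a Gaussian reference
#'
#' A moment-threshold verdict: `"gaussian_like"` when both the absolute
#' skewness and the absolute excess kurtosis fall within their tolerances,
#' `"non_gaussian"` otherwise, `"degenerate"` passed through for
#' zero-variance profiles. Moment thresholds are used instead of formal
#' normality tests because window GC is discrete (multiples of 1/w), which
#' makes Shapiro-Wilk or Kolmogorov-Smirnov reject at large N for
#' discreteness that is irrelevant to the bell-shape question.
#'
#' @param summary A [DensitySummary-class].
#' @param skewTol Absolute skewness tolerance (default 0.15).
#' @param kurtTol Absolute excess-kurtosis tolerance (default 0.3).
#' @return One of `"gaussian_like"`, `"non_gaussian"`, `"degenerate"`.
#' @export
gaussianAgreement <- function(summary, skewTol = 0.15, kurtTol = 0.3) {
  stopifnot(is(summary, "DensitySummary"))
  if (isDegenerate(summary)) return("degenerate")
  if (abs(summary@skewness) <= skewTol &&
      abs(summary@excessKurtosis) <= kurtTol) "gaussian_like"
  else "non_gaussian"
}

#' Loess trend of GCVAR against mean GC across chromosomes
#'
#' Fits a locally weighted quadratic regression (loess, tricube weights) of
#' GCVAR on mean GC over a cohort of chromosomes and evaluates it on an
#' equally spaced grid spanning the observed GC range. The relationship is
#' typically non-linear, which is why a smoother rather than a straight
#' line summarizes it.
#'
#' @param records A data.frame with numeric columns `meanGC` and `gcvar`
#'   (e.g. from [gcvarScan()] joined to metadata, or [simulateCohort()]).
#' @param span Loess span (default 0.75).
#' @param nPoints Grid size (default 100).
#' @return A [TrendCurve-class]. Rows with non-finite `gcvar` (degenerate
#'   chromosomes) are dropped with a logged count.
#' @importFrom stats loess loess.control predict
#' @export
gcvarGcTrend <- function(records, span = 0.75, nPoints = 100L) {
  if (!all(c("meanGC", "gcvar") %in% colnames(records)))
    stop("'records' must have columns 'meanGC' and 'gcvar'")
  ok <- is.finite(records$gcvar) & is.finite(records$meanGC)
  dropped <- sum(!ok)
  if (dropped > 0L)
    gcvarMessage("dropping ", dropped,
                 " record(s) with non-finite GCVAR or mean GC")
  df <- records[ok, c("meanGC", "gcvar")]
  if (nrow(df) < 10L)
    stop("need at least 10 records with finite GCVAR (got ", nrow(df), ")")
  fit <- loess(gcvar ~ meanGC, data = df, span = span, degree = 2,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  x <- seq(min(df$meanGC), max(df$meanGC), length.out = nPoints)
  y <- predict(fit, newdata = data.frame(meanGC = x))
  new("TrendCurve", x = x, y = as.numeric(y), span = span,
      nDropped = as.integer(dropped))
}
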