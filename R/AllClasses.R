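#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges start end width seqnames
#' @importFrom IRanges IRanges
NULL

#' WindowProfile: per-window GC content along one chromosome
#'
#' Holds the non-overlapping window GC fractions \eqn{GC_i}, the residuals
#' \eqn{D_i = GC_i - \bar{GC}} against the chromosome mean GC, and the window
#' coordinates for a single chromosome at a single window length. Windows
#' with more ambiguous (N) bases than the ambiguity threshold are dropped and
#' counted in `nExcluded`.
#'
#' @slot chromosomeId Chromosome identifier (FASTA header first token).
#' @slot windowLength Window length in bp.
#' @slot windows A [GenomicRanges::GRanges] of the retained windows in
#'   genomic order, with metadata columns `gc` (window GC fraction) and
#'   `residual` (window GC minus chromosome mean GC).
#' @slot meanGC Chromosome-wide mean GC fraction, computed over the whole
#'   chromosome including any trailing partial window, over unambiguous
#'   bases only.
#' @slot nExcluded Number of windows dropped for excess ambiguity.
#'
#' @seealso [scanWindows()], [computeGCVar()]
#' @exportClass WindowProfile
setClass("WindowProfile",
  representation(
    chromosomeId = "character",
    windowLength = "integer",
    windows = "GRanges",
    meanGC = "numeric",
    nExcluded = "integer"
  )
)

setValidity("WindowProfile", function(object) {
  msg <- character()
  if (length(object@chromosomeId) != 1L)
    msg <- c(msg, "chromosomeId must be a single string")
  if (length(object@windowLength) != 1L || object@windowLength < 1L)
    msg <- c(msg, "windowLength must be a single positive integer")
  mc <- mcols(object@windows)
  if (!all(c("gc", "residual") %in% colnames(mc)))
    msg <- c(msg, "windows must carry 'gc' and 'residual' metadata columns")
  else {
    if (any(mc$gc < 0 | mc$gc > 1, na.rm = TRUE))
      msg <- c(msg, "window GC fractions must lie in [0, 1]")
    if (any(abs(mc$residual - (mc$gc - object@meanGC)) > 1e-9, na.rm = TRUE))
      msg <- c(msg, "residuals must equal gc - meanGC")
  }
  if (length(object@meanGC) != 1L ||
      object@meanGC < 0 || object@meanGC > 1)
    msg <- c(msg, "meanGC must be a single value in [0, 1]")
  if (object@nExcluded < 0L)
    msg <- c(msg, "nExcluded must be non-negative")
  if (length(msg)) msg else TRUE
})

#' GCVarResult: the GCVAR statistic for one chromosome
#'
#' GCVAR is the natural log of the mean absolute deviation of window GC
#' fractions from the chromosome mean GC. A perfectly homogeneous profile
#' (all residuals zero) is flagged `degenerate` and carries `-Inf`.
#'
#' @slot chromosomeId Chromosome identifier.
#' @slot windowLength Window length in bp used for the profile.
#' @slot nWindows Number of windows entering the statistic.
#' @slot meanAbsDev Mean of |D_i| (dimensionless GC fraction units).
#' @slot gcvar `log(meanAbsDev)`; `-Inf` when degenerate.
#' @slot degenerate `TRUE` iff `meanAbsDev == 0`.
#'
#' @seealso [computeGCVar()], [windowSensitivity()]
#' @exportClass GCVarResult
setClass("GCVarResult",
  representation(
    chromosomeId = "character",
    windowLength = "integer",
    nWindows = "integer",
    meanAbsDev = "numeric",
    gcvar = "numeric",
    degenerate = "logical"
  )
)

setValidity("GCVarResult", function(object) {
  msg <- character()
  if (object@meanAbsDev < 0) msg <- c(msg, "meanAbsDev must be >= 0")
  if (object@degenerate != (object@meanAbsDev == 0))
    msg <- c(msg, "degenerate flag must mirror meanAbsDev == 0")
  if (!object@degenerate &&
      abs(object@gcvar - log(object@meanAbsDev)) > 1e-9)
    msg <- c(msg, "gcvar must equal log(meanAbsDev)")
  if (object@degenerate && is.finite(object@gcvar))
    msg <- c(msg, "degenerate result must carry -Inf")
  if (length(msg)) msg else TRUE
})

#' DensitySummary: residual distribution of one window profile
#'
#' Moment summary and histogram of the window residuals D_i, with the
#' matched Gaussian reference (same mean and sd as the residuals) used to
#' judge Gaussian-likeness of within-chromosome GC variation.
#'
#' @slot chromosomeId Chromosome identifier.
#' @slot n Number of residuals summarized.
#' @slot mean,sd Sample mean and sd (n-1 denominator) of the residuals.
#' @slot skewness Third standardized sample moment; `NA` when degenerate.
#' @slot excessKurtosis Fourth standardized moment minus 3; `NA` when
#'   degenerate.
#' @slot breaks,counts Histogram bin edges and counts over `[min, max]`.
#' @slot gaussianMean,gaussianSd Parameters of the overlaid normal density;
#'   always equal to `mean` and `sd`.
#' @slot degenerate `TRUE` when the residuals have zero variance.
#' @seealso [residualDensity()], [gaussianAgreement()]
#' @exportClass DensitySummary
setClass("DensitySummary",
  representation(
    chromosomeId = "character",
    n = "integer",
    mean = "numeric",
    sd = "numeric",
    skewness = "numeric",
    excessKurtosis = "numeric",
    breaks = "numeric",
    counts = "integer",
    gaussianMean = "numeric",
    gaussianSd = "numeric",
    degenerate = "logical"
  )
)

setValidity("DensitySummary", function(object) {
  msg <- character()
  if (object@sd < 0) msg <- c(msg, "sd must be >= 0")
  if (!identical(object@gaussianMean, object@mean) ||
      !identical(object@gaussianSd, object@sd))
    msg <- c(msg, "gaussian reference must match the empirical moments")
  if (sum(object@counts) != object@n)
    msg <- c(msg, "histogram counts must sum to n")
  if (object@sd == 0 && !object@degenerate)
    msg <- c(msg, "zero sd requires the degenerate flag")
  if (length(msg)) msg else TRUE
})

#' TrendCurve: smoothed GCVAR-vs-GC relationship across chromosomes
#'
#' A loess (locally weighted quadratic) smooth of GCVAR against mean GC,
#' evaluated on an equally spaced grid spanning the observed GC range.
#'
#' @slot x Grid of mean-GC values, strictly increasing.
#' @slot y Smoothed GCVAR at each grid point.
#' @slot span Loess span used.
#' @slot nDropped Records dropped for non-finite GCVAR before smoothing.
#' @seealso [gcvarGcTrend()]
#' @exportClass TrendCurve
setClass("TrendCurve",
  representation(
    x = "numeric",
    y = "numeric",
    span = "numeric",
    nDropped = "integer"
  )
)

setValidity("TrendCurve", function(object) {
  msg <- character()
  if (length(object@x) != length(object@y))
    msg <- c(msg, "x and y must have equal length")
  if (any(diff(object@x) <= 0))
    msg <- c(msg, "x must be strictly increasing")
  if (any(!is.finite(object@y)))
    msg <- c(msg, "y must be finite at every grid point")
  if (length(msg)) msg else TRUE
})

#' RegressionFit: a fitted GCVAR or GC-response linear model
#'
#' Wraps an ordinary least squares fit with sum-to-zero factor coding. The
#' `terms` table reports one row per reportable effect, including the
#' reconstructed effect of each factor's omitted level (so every phylum,
#' oxygen class etc. has an effect-versus-factor-average with its own
#' standard error and confidence interval).
#'
#' @slot modelKind One of `"full"` (GCVAR on GC, size and all lifestyle
#'   factors), `"interaction"` (GCVAR on oxygen plus per-phylum GC slopes),
#'   `"gc_response"` (mean GC on phylum and oxygen) or `"gc_marginal"`
#'   (mean GC on oxygen alone).
#' @slot coding Contrast scheme descriptor (always `"sum-to-zero"` for
#'   factors entering as main effects).
#' @slot terms `data.frame` with columns `term`, `type` (factor name,
#'   `"gc_slope"`, `"continuous"` or `"intercept"`), `level`, `estimate`,
#'   `se`, `t`, `p`, `ciLow`, `ciHigh`, `reconstructed`.
#' @slot fit The underlying [stats::lm] object.
#' @slot effectCov Covariance matrix of the full effect vector, in `terms`
#'   row order; used by [linearContrast()].
#' @slot nObs Rows used in the fit.
#' @slot nDropped Rows dropped for missing covariates or non-finite response.
#' @slot residualSd Residual standard deviation estimate.
#' @slot rSquared Coefficient of determination.
#' @slot confidence Confidence level of the reported intervals.
#' @slot gcScale `"fraction"` or `"percent"`; the scale GC entered the
#'   design on (it changes the magnitude of the GC coefficient).
#' @seealso [fitGCVarModel()], [effectIntervals()], [linearContrast()]
#' @exportClass RegressionFit
setClass("RegressionFit",
  representation(
    modelKind = "character",
    coding = "character",
    terms = "data.frame",
    fit = "ANY",
    effectCov = "matrix",
    nObs = "integer",
    nDropped = "integer",
    residualSd = "numeric",
    rSquared = "numeric",
    confidence = "numeric",
    gcScale = "character"
  )
)

setValidity("RegressionFit", function(object) {
  msg <- character()
  tt <- object@terms
  need <- c("term", "type", "level", "estimate", "se", "t", "p",
            "ciLow", "ciHigh", "reconstructed")
  if (!all(need %in% colnames(tt)))
    msg <- c(msg, "terms table is missing required columns")
  else {
    ok <- is.finite(tt$se) & tt$se > 0
    bad <- ok & !(tt$ciLow < tt$estimate & tt$estimate < tt$ciHigh)
    if (any(bad))
      msg <- c(msg, "confidence intervals must bracket their estimates")
  }
  if (nrow(tt) != nrow(object@effectCov))
    msg <- c(msg, "effectCov dimension must match the terms table")
  if (object@confidence <= 0 || object@confidence >= 1)
    msg <- c(msg, "confidence must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})
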