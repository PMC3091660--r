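#' @include AllClasses.R
NULL

#' Accessors for gcvar S4 objects
#'
#' Small accessor generics so slots are never reached into directly:
#' `chromosomeId()`, `windowLength()`, `nWindows()`, `meanGC()`,
#' `gcValues()`, `gcResiduals()`, `windowRanges()`, `nExcludedWindows()`,
#' `meanAbsDev()`, `gcvarValue()`, `isDegenerate()`, `modelKind()`,
#' `modelTerms()`.
#'
#' @param object A [WindowProfile-class], [GCVarResult-class],
#'   [DensitySummary-class] or [RegressionFit-class] object, as applicable.
#' @return The corresponding component: identifiers and counts as length-1
#'   vectors, per-window values as numeric vectors, window coordinates as a
#'   [GenomicRanges::GRanges], the term table as a `data.frame`.
#' @name accessors
#' @aliases chromosomeId windowLength nWindows meanGC gcValues gcResiduals
#'   windowRanges nExcludedWindows meanAbsDev gcvarValue isDegenerate
#'   modelKind modelTerms
#' @examples
#' p <- scanWindows(Biostrings::DNAString("GGGGAAAA"), windowLength = 4,
#'                  chromosomeId = "toy")
#' gcValues(p)
#' gcvarValue(computeGCVar(p))
NULL

#' @rdname accessors
#' @export
setGeneric("chromosomeId", function(object) standardGeneric("chromosomeId"))
#' @rdname accessors
#' @export
setGeneric("windowLength", function(object) standardGeneric("windowLength"))
#' @rdname accessors
#' @export
setGeneric("nWindows", function(object) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("meanGC", function(object) standardGeneric("meanGC"))
#' @rdname accessors
#' @export
setGeneric("gcValues", function(object) standardGeneric("gcValues"))
#' @rdname accessors
#' @export
setGeneric("gcResiduals", function(object) standardGeneric("gcResiduals"))
#' @rdname accessors
#' @export
setGeneric("windowRanges", function(object) standardGeneric("windowRanges"))
#' @rdname accessors
#' @export
setGeneric("nExcludedWindows",
           function(object) standardGeneric("nExcludedWindows"))
#' @rdname accessors
#' @export
setGeneric("meanAbsDev", function(object) standardGeneric("meanAbsDev"))
#' @rdname accessors
#' @export
setGeneric("gcvarValue", function(object) standardGeneric("gcvarValue"))
#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(object) standardGeneric("isDegenerate"))
#' @rdname accessors
#' @export
setGeneric("modelKind", function(object) standardGeneric("modelKind"))
#' @rdname accessors
#' @export
setGeneric("modelTerms", function(object) standardGeneric("modelTerms"))

#' @rdname accessors
setMethod("chromosomeId", "WindowProfile", function(object) object@chromosomeId)
#' @rdname accessors
setMethod("chromosomeId", "GCVarResult", function(object) object@chromosomeId)
#' @rdname accessors
setMethod("chromosomeId", "DensitySummary",
          function(object) object@chromosomeId)
#' @rdname accessors
setMethod("windowLength", "WindowProfile", function(object) object@windowLength)
#' @rdname accessors
setMethod("windowLength", "GCVarResult", function(object) object@windowLength)
#' @rdname accessors
setMethod("nWindows", "WindowProfile",
          function(object) length(object@windows))
#' @rdname accessors
setMethod("nWindows", "GCVarResult", function(object) object@nWindows)
#' @rdname accessors
setMethod("meanGC", "WindowProfile", function(object) object@meanGC)
#' @rdname accessors
setMethod("gcValues", "WindowProfile",
          function(object) mcols(object@windows)$gc)
#' @rdname accessors
setMethod("gcResiduals", "WindowProfile",
          function(object) mcols(object@windows)$residual)
#' @rdname accessors
setMethod("windowRanges", "WindowProfile", function(object) object@windows)
#' @rdname accessors
setMethod("nExcludedWindows", "WindowProfile",
          function(object) object@nExcluded)
#' @rdname accessors
setMethod("meanAbsDev", "GCVarResult", function(object) object@meanAbsDev)
#' @rdname accessors
setMethod("gcvarValue", "GCVarResult", function(object) object@gcvar)
#' @rdname accessors
setMethod("isDegenerate", "GCVarResult", function(object) object@degenerate)
#' @rdname accessors
setMethod("isDegenerate", "DensitySummary",
          function(object) object@degenerate)
#' @rdname accessors
setMethod("modelKind", "RegressionFit", function(object) object@modelKind)
#' @rdname accessors
setMethod("modelTerms", "RegressionFit", function(object) object@terms)

setMethod("show", "WindowProfile", function(object) {
  cat("WindowProfile for", object@chromosomeId, "\n")
  cat("  window length:", object@windowLength, "bp;",
      length(object@windows), "windows",
      sprintf("(%d excluded for ambiguity)\n", object@nExcluded))
  cat(sprintf("  chromosome mean GC: %.4f\n", object@meanGC))
})

setMethod("show", "GCVarResult", function(object) {
  cat("GCVarResult for", object@chromosomeId, "\n")
  cat(sprintf("  w = %d bp, N = %d windows\n",
              object@windowLength, object@nWindows))
  if (object@degenerate)
    cat("  degenerate profile (zero mean absolute deviation); GCVAR = -Inf\n")
  else
    cat(sprintf("  mean |D_i| = %.6g; GCVAR = %.4f\n",
                object@meanAbsDev, object@gcvar))
})

setMethod("show", "DensitySummary", function(object) {
  cat("DensitySummary for", object@chromosomeId,
      sprintf("(n = %d residuals)\n", object@n))
  cat(sprintf("  mean = %.3g, sd = %.3g, skewness = %.3g, excess kurtosis = %.3g\n",
              object@mean, object@sd, object@skewness,
              object@excessKurtosis))
  if (object@degenerate) cat("  degenerate: zero residual variance\n")
})

setMethod("show", "TrendCurve", function(object) {
  cat("TrendCurve:", length(object@x), "grid points, span",
      object@span, "\n")
  cat(sprintf("  GC range [%.3f, %.3f]; %d records dropped\n",
              min(object@x), max(object@x), object@nDropped))
})

setMethod("show", "RegressionFit", function(object) {
  cat("RegressionFit (", object@modelKind, " model, ", object@coding,
      " coding)\n", sep = "")
  cat(sprintf("  n = %d observations (%d dropped), residual sd = %.4g, R^2 = %.3f\n",
              object@nObs, object@nDropped, object@residualSd,
              object@rSquared))
  cat(sprintf("  GC scale: %s; %.0f%% confidence intervals\n",
              object@gcScale, 100 * object@confidence))
  print(utils::head(object@terms[, c("term", "estimate", "se", "p")], 8))
  if (nrow(object@terms) > 8)
    cat("  ...", nrow(object@terms) - 8, "more terms\n")
})

#' @describeIn accessors Coerce a GCVarResult to a one-row data.frame.
#' @param x,row.names,optional,... Standard [base::as.data.frame] arguments.
#' @export
as.data.frame.GCVarResult <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  data.frame(
    chromosomeId = x@chromosomeId,
    windowLength = x@windowLength,
    nWindows = x@nWindows,
    meanAbsDev = x@meanAbsDev,
    gcvar = x@gcvar,
    degenerate = x@degenerate,
    stringsAsFactors = FALSE, row.names = row.names
  )
}

#' @describeIn accessors Coerce a TrendCurve to a data.frame of grid points.
#' @export
as.data.frame.TrendCurve <- function(x, row.names = NULL,
                                     optional = FALSE, ...) {
  data.frame(meanGC = x@x, gcvar = x@y, row.names = row.names)
}
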