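#' Profile GC content in non-overlapping windows
#'
#' Tiles a chromosome with non-overlapping windows of `windowLength` bp
#' starting at position 1, discarding the trailing partial window, and
#' computes each window's GC fraction over its unambiguous bases:
#' \deqn{GC_i = (\#G + \#C) / (\#A + \#C + \#G + \#T).}
#' The chromosome mean GC is computed the same way over the *whole*
#' chromosome (including the discarded tail), and each window's residual is
#' \deqn{D_i = GC_i - \bar{GC}.}
#' Windows whose fraction of ambiguous (N) bases exceeds
#' `ambiguityThreshold` are excluded from the profile (assembly gaps must
#' not masquerade as AT-rich windows); a window that is entirely N never
#' produces a division error, it is simply excluded.
#'
#' @param seq A [Biostrings::DNAString], a single-element
#'   [Biostrings::DNAStringSet], or a character string over
#'   `{A, C, G, T, N}`.
#' @param windowLength Window length in bp (default 100, the most sensitive
#'   setting for chromosome-scale GC heterogeneity).
#' @param chromosomeId Identifier for the profile; defaults to the sequence
#'   name when available.
#' @param ambiguityThreshold Maximum tolerated N fraction per window
#'   (default 0.5); windows strictly above it are dropped.
#' @return A [WindowProfile-class].
#' @examples
#' p <- scanWindows(Biostrings::DNAString("GGGGAAAA"), windowLength = 4,
#'                  chromosomeId = "toy")
#' gcValues(p)      # 1.0 0.0
#' gcResiduals(p)   # +0.5 -0.5
#' @importFrom Biostrings DNAString letterFrequency
#' @importFrom IRanges successiveViews
#' @export
scanWindows <- function(seq, windowLength = 100L, chromosomeId = NULL,
                        ambiguityThreshold = 0.5) {
  if (is(seq, "DNAStringSet")) {
    if (length(seq) != 1L)
      stop("'seq' must be a single chromosome; got ", length(seq),
           " sequences (iterate or use gcvarScan())")
    if (is.null(chromosomeId)) chromosomeId <- names(seq)
    seq <- seq[[1L]]
  }
  if (is.character(seq)) seq <- DNAString(seq)
  if (!is(seq, "DNAString")) stop("'seq' must be DNA sequence input")
  if (is.null(chromosomeId) || !length(chromosomeId))
    chromosomeId <- "chromosome"
  windowLength <- as.integer(windowLength)
  if (is.na(windowLength) || windowLength < 1L)
    stop("'windowLength' must be a positive integer")
  L <- length(seq)
  if (L < windowLength)
    stop("sequence '", chromosomeId, "' (", L,
         " bp) is shorter than one window of ", windowLength, " bp")

  n <- L %/% windowLength
  counts <- letterFrequency(
    successiveViews(seq, rep.int(windowLength, n)),
    c("A", "C", "G", "T", "N"))
  unambig <- rowSums(counts[, c("A", "C", "G", "T"), drop = FALSE])
  keep <- counts[, "N"] / windowLength <= ambiguityThreshold & unambig > 0L
  gc <- ifelse(unambig > 0L,
               (counts[, "G"] + counts[, "C"]) / unambig, NA_real_)

  whole <- letterFrequency(seq, c("A", "C", "G", "T"))
  denom <- sum(whole)
  if (denom == 0L)
    stop("sequence '", chromosomeId, "' contains no unambiguous bases")
  mgc <- unname((whole[["G"]] + whole[["C"]]) / denom)

  starts <- (seq_len(n)[keep] - 1L) * windowLength + 1L
  gr <- GRanges(chromosomeId,
                IRanges(start = starts, width = windowLength))
  mcols(gr)$gc <- gc[keep]
  mcols(gr)$residual <- gc[keep] - mgc
  new("WindowProfile",
      chromosomeId = as.character(chromosomeId),
      windowLength = windowLength,
      windows = gr,
      meanGC = mgc,
      nExcluded = sum(!keep))
}

#' Compute the GCVAR statistic from a window profile
#'
#' GCVAR is the natural log of the mean absolute deviation of window GC
#' fractions from the chromosome mean:
#' \deqn{GCVAR = \log\left(\frac{1}{N}\sum_{i=1}^{N} |D_i|\right).}
#' Low GCVAR means a compositionally homogeneous chromosome; high GCVAR
#' means heterogeneity (GC-shifted islands, rRNA operons, and similar).
#' A profile with all residuals exactly zero is flagged degenerate and
#' reported as `-Inf` with a warning rather than an error, so batch runs
#' over many chromosomes never abort.
#'
#' @param profile A [WindowProfile-class] with at least one window.
#' @return A [GCVarResult-class].
#' @examples
#' p <- scanWindows(Biostrings::DNAString("GGGGAAAA"), windowLength = 4)
#' gcvarValue(computeGCVar(p))  # log(0.5)
#' @export
computeGCVar <- function(profile) {
  stopifnot(is(profile, "WindowProfile"))
  n <- nWindows(profile)
  if (n < 1L)
    stop("profile for '", chromosomeId(profile),
         "' has no retained windows")
  mad <- mean(abs(gcResiduals(profile)))
  degenerate <- mad == 0
  if (degenerate)
    warning("chromosome '", chromosomeId(profile),
            "' is perfectly GC-homogeneous at w = ",
            windowLength(profile), "; GCVAR is -Inf")
  new("GCVarResult",
      chromosomeId = chromosomeId(profile),
      windowLength = windowLength(profile),
      nWindows = n,
      meanAbsDev = mad,
      gcvar = if (degenerate) -Inf else log(mad),
      degenerate = degenerate)
}

#' GCVAR across a grid of window lengths
#'
#' Recomputes the profile and GCVAR independently at each window length.
#' Under a compositionally homogeneous (iid) chromosome the expected mean
#' absolute deviation scales as \eqn{w^{-1/2}}, so GCVAR decreases by about
#' `log(2)` for every 4-fold increase in window length; departures from
#' that scaling indicate genuine long-range structure.
#'
#' @param seq Sequence input as for [scanWindows()].
#' @param windowLengths Integer vector of window lengths
#'   (default `c(100, 500, 1000, 2000)`).
#' @param ... Passed on to [scanWindows()].
#' @return A list of [GCVarResult-class], one per window length.
#' @export
windowSensitivity <- function(seq, windowLengths = c(100L, 500L, 1000L, 2000L),
                              ...) {
  if (!length(windowLengths)) stop("'windowLengths' must be non-empty")
  lapply(windowLengths, function(w) {
    tryCatch(computeGCVar(scanWindows(seq, windowLength = w, ...)),
             error = function(e)
               stop("window length ", w, ": ", conditionMessage(e),
                    call. = FALSE))
  })
}

#' Batch GCVAR over a set of chromosomes
#'
#' Runs [scanWindows()] and [computeGCVar()] over every chromosome of a
#' [Biostrings::DNAStringSet], optionally at several window lengths, and
#' collects the results into the package's standard per-chromosome table.
#'
#' @param seqs A named [Biostrings::DNAStringSet] (e.g. from
#'   [readGenomeFasta()]).
#' @param windowLengths Integer vector of window lengths (default 100).
#' @param ambiguityThreshold Passed to [scanWindows()].
#' @param onError `"skip"` (log and continue, the default) or `"stop"`.
#' @return A `data.frame` with columns `chromosomeId`, `windowLength`,
#'   `nWindows`, `nExcludedWindows`, `meanGC`, `meanAbsDev`, `gcvar`,
#'   `degenerate`; one row per chromosome and window length. Skipped
#'   chromosomes are recorded in the `"skipped"` attribute.
#' @export
gcvarScan <- function(seqs, windowLengths = 100L, ambiguityThreshold = 0.5,
                      onError = c("skip", "stop")) {
  onError <- match.arg(onError)
  if (!is(seqs, "DNAStringSet"))
    stop("'seqs' must be a DNAStringSet; see readGenomeFasta()")
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  rows <- list()
  skipped <- character()
  for (i in seq_along(seqs)) {
    for (w in windowLengths) {
      res <- tryCatch({
        p <- scanWindows(seqs[[i]], windowLength = w,
                         chromosomeId = ids[i],
                         ambiguityThreshold = ambiguityThreshold)
        r <- withCallingHandlers(
          computeGCVar(p),
          warning = function(wn) {
            gcvarMessage(conditionMessage(wn))
            invokeRestart("muffleWarning")
          })
        cbind(as.data.frame(r)[, 1:3],
              nExcludedWindows = nExcludedWindows(p),
              meanGC = meanGC(p),
              as.data.frame(r)[, 4:6])
      }, error = function(e) {
        if (onError == "stop") stop(e)
        gcvarMessage("skipping ", ids[i], " at w = ", w, ": ",
                     conditionMessage(e))
        skipped <<- c(skipped, ids[i])
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  if (!length(rows))
    stop("no chromosome could be profiled")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- unique(skipped)
  out
}
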