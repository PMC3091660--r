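#' Simulate a compositionally homogeneous (iid) chromosome
#'
#' Draws every base independently: G and C each with probability `gc/2`,
#' A and T each with probability `(1 - gc)/2` (strand-symmetric, consistent
#' with Chargaff's parity rules). This is the null model for a chromosome
#' with no compositional substructure: its window GC fractions are
#' binomial, the residuals are approximately Gaussian, and the expected
#' mean absolute deviation has the half-normal closed form
#' \eqn{E|D| = \sqrt{2 p (1-p) / (\pi w)}}.
#'
#' @param gc Target GC fraction in `[0, 1]`.
#' @param length Chromosome length in bp.
#' @param seed Integer seed; the draw is reproducible given the seed and
#'   the caller's RNG state is left untouched.
#' @return A [Biostrings::DNAString].
#' @examples
#' g <- simulateIidGenome(0.5, 1000, seed = 1)
#' Biostrings::letterFrequency(g, "GC", as.prob = TRUE)
#' @export
simulateIidGenome <- function(gc, length, seed = NULL) {
  if (!is.numeric(gc) || length(gc) != 1L || is.na(gc) || gc < 0 || gc > 1)
    stop("'gc' must be a single fraction in [0, 1]")
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("'length' must be >= 1")
  bases <- withSeed(seed, .drawBases(gc, length))
  DNAString(paste(bases, collapse = ""))
}

#' @noRd
.drawBases <- function(gc, n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Simulate a chromosome carrying GC-shifted island blocks
#'
#' Draws an iid background at `backgroundGc`, then redraws each island
#' span iid at its own GC fraction. This emulates chromosomally integrated
#' foreign DNA (horizontally transferred regions) whose base composition
#' differs from the host chromosome — the principal biological mechanism
#' behind high GCVAR.
#'
#' @param backgroundGc Background GC fraction.
#' @param length Chromosome length in bp.
#' @param islands A data.frame with columns `start` (0-based bp), `length`
#'   (bp) and `gc` (island GC fraction). Islands must lie within the
#'   chromosome and must not overlap. An empty data.frame (or `NULL`)
#'   reduces to [simulateIidGenome()].
#' @param seed Integer seed.
#' @return A list with elements `sequence` (a [Biostrings::DNAString]) and
#'   `islands` (a [GenomicRanges::GRanges] of the island spans with their
#'   GC fractions, ready for [writeIslandBed()]).
#' @examples
#' sim <- simulateIslandGenome(0.4, 50000,
#'   islands = data.frame(start = 10000, length = 5000, gc = 0.8),
#'   seed = 1)
#' sim$islands
#' @export
simulateIslandGenome <- function(backgroundGc, length, islands = NULL,
                                 seed = NULL) {
  length <- as.integer(length)
  if (is.null(islands) || nrow(islands) == 0L) {
    sq <- simulateIidGenome(backgroundGc, length, seed)
    return(list(sequence = sq,
                islands = GRanges(seqnames = character(),
                                  ranges = IRanges())))
  }
  if (!all(c("start", "length", "gc") %in% colnames(islands)))
    stop("'islands' needs columns start, length, gc")
  if (any(islands$gc < 0 | islands$gc > 1))
    stop("island GC fractions must lie in [0, 1]")
  if (any(islands$length < 1L)) stop("island lengths must be >= 1")
  if (any(islands$start < 0L) ||
      any(islands$start + islands$length > length))
    stop("islands must lie within the chromosome [0, ", length, ")")
  ord <- order(islands$start)
  islands <- islands[ord, , drop = FALSE]
  ends <- islands$start + islands$length
  if (nrow(islands) > 1L &&
      any(islands$start[-1L] < ends[-nrow(islands)]))
    stop("islands must not overlap")
  bases <- withSeed(seed, {
    b <- .drawBases(backgroundGc, length)
    for (i in seq_len(nrow(islands))) {
      idx <- seq.int(islands$start[i] + 1L, ends[i])
      b[idx] <- .drawBases(islands$gc[i], islands$length[i])
    }
    b
  })
  gr <- GRanges("island_genome",
                IRanges(start = islands$start + 1L,
                        width = islands$length))
  mcols(gr)$gc <- islands$gc
  list(sequence = DNAString(paste(bases, collapse = "")), islands = gr)
}

#' Write island annotations as a BED file
#'
#' Four-column BED (chrom, start, end, name) with 0-based half-open
#' coordinates; the name records the island GC fraction.
#'
#' @param islands A [GenomicRanges::GRanges] as returned by
#'   [simulateIslandGenome()].
#' @param path Output path.
#' @param chrom Chromosome name for the first column (default the GRanges
#'   seqnames).
#' @return Invisibly, the number of lines written.
#' @export
writeIslandBed <- function(islands, path, chrom = NULL) {
  stopifnot(is(islands, "GRanges"))
  nm <- if (!is.null(mcols(islands)$gc))
    sprintf("gc=%.4g", mcols(islands)$gc) else "."
  chr <- if (is.null(chrom)) as.character(seqnames(islands)) else chrom
  lines <- sprintf("%s\t%d\t%d\t%s", chr,
                   start(islands) - 1L, end(islands), nm)
  writeLines(lines, path)
  invisible(length(lines))
}

## -------------------------------------------------------------------------
## Cohort simulation: generative twins of the regression models.

.defaultPhylumGC <- c(
  Acidobacteria = 0.60, Actinobacteria = 0.66, Bacteroidetes = 0.44,
  Betaproteobacteria = 0.64, Chlamydiae = 0.43, Crenarchaeota = 0.48,
  Cyanobacteria = 0.48, Deltaproteobacteria = 0.58,
  Epsilonproteobacteria = 0.38, Euryarchaeota = 0.46, Firmicutes = 0.37,
  Gammaproteobacteria = 0.47, Planctomycetes = 0.55, Spirochaetes = 0.37)

.defaultPhyla <- c("Actinobacteria", "Bacteroidetes", "Crenarchaeota",
                   "Euryarchaeota", "Firmicutes", "Gammaproteobacteria")

## Fill a partial factor-effect vector so the full set sums to zero: given
## levels keep their values, missing levels share the balancing remainder.
.completeEffects <- function(eff, levels, what) {
  if (is.null(eff)) return(stats::setNames(rep(0, length(levels)), levels))
  if (is.null(names(eff)) || !all(names(eff) %in% levels))
    stop("effects for '", what, "' must be named with levels from: ",
         paste(levels, collapse = ", "))
  out <- stats::setNames(rep(NA_real_, length(levels)), levels)
  out[names(eff)] <- eff
  missing <- is.na(out)
  if (any(missing)) {
    out[missing] <- -sum(out[!missing]) / sum(missing)
  } else if (abs(sum(out)) > 1e-8) {
    message("[gcvar] centering '", what,
            "' effects to sum to zero (sum-coded truth)")
    out <- out - mean(out)
  }
  out
}

#' Describe the ground truth of a simulated cohort
#'
#' Bundles the generative model for [simulateCohort()]: which regression
#' structure the responses follow, the coefficient truth, the residual
#' noise, and the sampling distributions of the covariates. Factor effects
#' are completed/centered to sum to zero within each factor, so the truth
#' lives on the same scale as the sum-coded estimates reported by
#' [fitGCVarModel()] (levels omitted from a partial specification absorb
#' the balancing remainder).
#'
#' @param model `"full"` (GCVAR response on all covariates),
#'   `"interaction"` (GCVAR response with per-phylum GC slopes) or
#'   `"gc_response"` (mean GC as the response on phylum + oxygen).
#' @param coefficients Named list: `intercept`; factor effect vectors
#'   `phylum`, `oxygen`, `temperature`, `pathogenicity`, `habitat` (named
#'   by level, possibly partial); `gc` and `size` slopes (full model);
#'   `gcSlopes` named per phylum (interaction model).
#' @param noiseSd Residual standard deviation (>= 0).
#' @param phyla Phylum names in the cohort (default six common groups,
#'   two archaeal).
#' @param phylumProbs Sampling probabilities per phylum (default uniform).
#' @param oxygenProbs Either a probability vector over
#'   aerobic/facultative/anaerobic (default 0.47/0.34/0.19, a typical
#'   curated-cohort mix), or a matrix with one row per phylum to induce
#'   phylum-oxygen confounding.
#' @param temperatureProbs,pathogenicityProbs,habitatProbs Probability
#'   vectors for the remaining lifestyle factors.
#' @param gcMeans,gcSd Per-phylum mean GC (named; defaults follow typical
#'   phylum GC contents) and common sd (default 0.05) used when mean GC is
#'   a covariate.
#' @param sizeMeanLog,sizeSdLog Log-normal parameters for genome size in
#'   Mb (defaults `log(3.2)` and 0.45, spanning roughly 1.5-8 Mb).
#' @return A `cohortTruth` list (class `"cohortTruth"`).
#' @export
cohortTruth <- function(model = c("full", "interaction", "gc_response"),
                        coefficients = list(), noiseSd = 0.15,
                        phyla = .defaultPhyla,
                        phylumProbs = NULL,
                        oxygenProbs = c(aerobic = 0.47, facultative = 0.34,
                                        anaerobic = 0.19),
                        temperatureProbs = c(psychrophilic = 0.05,
                                             mesophilic = 0.85,
                                             thermophilic = 0.10),
                        pathogenicityProbs = c(pathogenic = 0.45,
                                               `non-pathogenic` = 0.55),
                        habitatProbs = c(aquatic = 0.15,
                                         `host-associated` = 0.30,
                                         multiple = 0.25,
                                         specialized = 0.15,
                                         terrestrial = 0.15),
                        gcMeans = NULL, gcSd = 0.05,
                        sizeMeanLog = log(3.2), sizeSdLog = 0.45) {
  model <- match.arg(model)
  if (noiseSd < 0) stop("'noiseSd' must be >= 0")
  if (is.null(phylumProbs))
    phylumProbs <- stats::setNames(rep(1 / length(phyla), length(phyla)),
                                   phyla)
  if (!isTRUE(all.equal(sum(phylumProbs), 1)))
    stop("phylum probabilities must sum to 1")
  if (is.matrix(oxygenProbs)) {
    if (!all(rownames(oxygenProbs) %in% phyla) ||
        nrow(oxygenProbs) != length(phyla))
      stop("oxygenProbs matrix needs one row per phylum")
    if (!isTRUE(all.equal(unname(rowSums(oxygenProbs)),
                          rep(1, nrow(oxygenProbs)))))
      stop("each phylum's oxygen probabilities must sum to 1")
    oxygenProbs <- oxygenProbs[, .oxygenLevels, drop = FALSE]
  } else {
    if (!isTRUE(all.equal(sum(oxygenProbs), 1)))
      stop("oxygen probabilities must sum to 1")
    oxygenProbs <- oxygenProbs[.oxygenLevels]
  }
  if (is.null(gcMeans)) {
    gcMeans <- ifelse(phyla %in% names(.defaultPhylumGC),
                      .defaultPhylumGC[phyla], 0.5)
    names(gcMeans) <- phyla
  }
  if (!all(phyla %in% names(gcMeans)))
    stop("'gcMeans' must name every phylum")

  co <- coefficients
  co$intercept <- co$intercept %||% 0
  co$phylum <- .completeEffects(co$phylum, phyla, "phylum")
  co$oxygen <- .completeEffects(co$oxygen, .oxygenLevels, "oxygen")
  if (model == "full") {
    co$temperature <- .completeEffects(co$temperature, .temperatureLevels,
                                       "temperature")
    co$pathogenicity <- .completeEffects(co$pathogenicity,
                                         .pathogenicityLevels,
                                         "pathogenicity")
    co$habitat <- .completeEffects(co$habitat, .habitatLevels, "habitat")
    co$gc <- co$gc %||% 0
    co$size <- co$size %||% 0
  }
  if (model == "interaction") {
    if (is.null(co$gcSlopes))
      co$gcSlopes <- stats::setNames(rep(0, length(phyla)), phyla)
    if (!all(phyla %in% names(co$gcSlopes)))
      stop("'gcSlopes' must name every phylum")
  }
  structure(list(model = model, coefficients = co, noiseSd = noiseSd,
                 phyla = phyla, phylumProbs = phylumProbs,
                 oxygenProbs = oxygenProbs,
                 temperatureProbs = temperatureProbs,
                 pathogenicityProbs = pathogenicityProbs,
                 habitatProbs = habitatProbs,
                 gcMeans = gcMeans, gcSd = gcSd,
                 sizeMeanLog = sizeMeanLog, sizeSdLog = sizeSdLog),
            class = "cohortTruth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort of chromosome records with known regression truth
#'
#' Draws covariates from the distributions in a [cohortTruth()] and writes
#' the response directly from the linear predictor plus Gaussian noise —
#' the generative twin of the regression models, used for parameter
#' recovery, coverage and confounding experiments. (Responses are written
#' at the record level rather than by simulating and measuring full
#' genome sequences; sequence-level end-to-end checks use
#' [simulateIidGenome()] at small n.)
#'
#' For `model = "gc_response"` the linear predictor produces `meanGC`
#' itself (clamped away from 0/1) and `gcvar` is `NA`; otherwise `meanGC`
#' is drawn per phylum from `gcMeans`/`gcSd` and the predictor produces
#' `gcvar`.
#'
#' @param truth A [cohortTruth()] object.
#' @param n Number of chromosome records.
#' @param seed Integer seed; recorded in the returned truth echo.
#' @return A list with `records` (a data.frame accepted by
#'   [chromosomeRecords()]) and `truth` (the input truth with `seed` and
#'   `n` recorded).
#' @examples
#' truth <- cohortTruth(coefficients = list(
#'   intercept = -3.2, gc = 0.37,
#'   oxygen = c(anaerobic = 0.11)), noiseSd = 0.15)
#' sim <- simulateCohort(truth, n = 100, seed = 1)
#' head(sim$records)
#' @importFrom stats rnorm rlnorm
#' @export
simulateCohort <- function(truth, n, seed = NULL) {
  if (!inherits(truth, "cohortTruth"))
    stop("'truth' must come from cohortTruth()")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("'n' must be >= 1")
  co <- truth$coefficients
  records <- withSeed(seed, {
    phylum <- sample(truth$phyla, n, replace = TRUE,
                     prob = truth$phylumProbs[truth$phyla])
    oxygen <- if (is.matrix(truth$oxygenProbs)) {
      vapply(phylum, function(ph)
        sample(.oxygenLevels, 1L, prob = truth$oxygenProbs[ph, ]),
        character(1))
    } else {
      sample(.oxygenLevels, n, replace = TRUE, prob = truth$oxygenProbs)
    }
    temperature <- sample(.temperatureLevels, n, replace = TRUE,
                          prob = truth$temperatureProbs)
    pathogenicity <- sample(.pathogenicityLevels, n, replace = TRUE,
                            prob = truth$pathogenicityProbs)
    habitat <- sample(.habitatLevels, n, replace = TRUE,
                      prob = truth$habitatProbs)
    sizeMb <- rlnorm(n, truth$sizeMeanLog, truth$sizeSdLog)
    noise <- rnorm(n, 0, truth$noiseSd)
    if (truth$model == "gc_response") {
      meanGC <- co$intercept + co$phylum[phylum] + co$oxygen[oxygen] +
        noise
      meanGC <- pmin(pmax(meanGC, 0.01), 0.99)
      gcvar <- rep(NA_real_, n)
    } else {
      meanGC <- rnorm(n, truth$gcMeans[phylum], truth$gcSd)
      meanGC <- pmin(pmax(meanGC, 0.05), 0.95)
      lp <- if (truth$model == "full") {
        co$intercept + co$phylum[phylum] + co$oxygen[oxygen] +
          co$temperature[temperature] +
          co$pathogenicity[pathogenicity] + co$habitat[habitat] +
          co$gc * meanGC + co$size * sizeMb
      } else {
        co$intercept + co$oxygen[oxygen] + co$gcSlopes[phylum] * meanGC
      }
      gcvar <- lp + noise
    }
    data.frame(
      chromosomeId = sprintf("sim_%05d", seq_len(n)),
      phylum = phylum, oxygen = oxygen, temperature = temperature,
      pathogenicity = pathogenicity, habitat = habitat,
      sizeMb = sizeMb, meanGC = as.numeric(meanGC),
      gcvar = as.numeric(gcvar),
      stringsAsFactors = FALSE, row.names = NULL)
  })
  echo <- truth
  echo$seed <- seed
  echo$n <- n
  list(records = chromosomeRecords(records), truth = echo)
}

#' Serialize a simulated cohort and its ground truth
#'
#' Writes the records as TSV and the truth as a flat two-column
#' (key, value) TSV with dotted keys, so the scenario that generated a
#' cohort travels with it.
#'
#' @param cohort As returned by [simulateCohort()].
#' @param recordsPath,truthPath Output paths.
#' @return Invisibly, `recordsPath`.
#' @export
writeCohort <- function(cohort, recordsPath, truthPath) {
  writeTsv(cohort$records, recordsPath)
  flat <- .flattenTruth(cohort$truth)
  writeTsv(data.frame(key = names(flat), value = unname(flat),
                      stringsAsFactors = FALSE), truthPath)
  invisible(recordsPath)
}

#' @noRd
.flattenTruth <- function(x, prefix = character()) {
  out <- character()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- paste(c(prefix, nm), collapse = ".")
    if (is.list(v)) {
      out <- c(out, .flattenTruth(v, c(prefix, nm)))
    } else if (is.matrix(v)) {
      for (r in rownames(v))
        for (cc in colnames(v))
          out[paste(key, r, cc, sep = ".")] <- format(v[r, cc])
    } else if (length(v) > 1L && !is.null(names(v))) {
      for (l in names(v)) out[paste(key, l, sep = ".")] <- format(v[[l]])
    } else if (length(v)) {
      out[key] <- paste(format(v), collapse = ",")
    }
  }
  out
}
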