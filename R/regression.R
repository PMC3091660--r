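## Factor level sets for chromosome metadata. Phylum is free-form (22
## groups in a typical curated prokaryote cohort); the lifestyle factors
## have fixed vocabularies.
.oxygenLevels <- c("aerobic", "facultative", "anaerobic")
.temperatureLevels <- c("psychrophilic", "mesophilic", "thermophilic")
.pathogenicityLevels <- c("pathogenic", "non-pathogenic")
.habitatLevels <- c("aquatic", "host-associated", "multiple",
                    "specialized", "terrestrial")

.modelKinds <- c("full", "interaction", "gc_response", "gc_marginal")

#' Validate a table of chromosome records
#'
#' Checks and lightly normalizes the one-row-per-chromosome table used by
#' the regression and trend functions. Required columns are
#' `chromosomeId`, `phylum`, `oxygen` and `meanGC`; `temperature`,
#' `pathogenicity`, `habitat`, `sizeMb` and `gcvar` are required only by
#' the models that use them. Categorical columns must use the controlled
#' vocabularies (`oxygen`: aerobic/facultative/anaerobic; `temperature`:
#' psychrophilic/mesophilic/thermophilic; `pathogenicity`:
#' pathogenic/non-pathogenic; `habitat`: aquatic/host-associated/multiple/
#' specialized/terrestrial). Missing values stay `NA` and are dropped,
#' with a logged count, by the model that needs them.
#'
#' @param records A data.frame.
#' @return The validated data.frame (invisibly unchanged apart from
#'   whitespace trimming of categorical columns).
#' @export
chromosomeRecords <- function(records) {
  if (!is.data.frame(records)) stop("'records' must be a data.frame")
  need <- c("chromosomeId", "phylum", "oxygen", "meanGC")
  miss <- setdiff(need, colnames(records))
  if (length(miss))
    stop("records are missing required column(s): ",
         paste(miss, collapse = ", "))
  vocab <- list(oxygen = .oxygenLevels, temperature = .temperatureLevels,
                pathogenicity = .pathogenicityLevels,
                habitat = .habitatLevels)
  for (col in names(vocab)) {
    if (!col %in% colnames(records)) next
    v <- trimws(as.character(records[[col]]))
    v[v == ""] <- NA_character_
    bad <- !is.na(v) & !v %in% vocab[[col]]
    if (any(bad))
      stop("invalid ", col, " value(s): ",
           paste(unique(v[bad]), collapse = ", "),
           " (allowed: ", paste(vocab[[col]], collapse = ", "), ")")
    records[[col]] <- v
  }
  if ("sizeMb" %in% colnames(records) &&
      any(records$sizeMb <= 0, na.rm = TRUE))
    stop("sizeMb must be positive")
  if (any(records$meanGC <= 0 | records$meanGC >= 1, na.rm = TRUE))
    stop("meanGC must lie strictly between 0 and 1 (fraction scale)")
  records
}

## Variables each model kind needs, and its response.
.modelSpec <- function(model) {
  switch(model,
    full = list(response = "gcvar",
                factors = c("phylum", "oxygen", "temperature",
                            "pathogenicity", "habitat"),
                continuous = c("meanGC", "sizeMb"),
                interaction = FALSE),
    interaction = list(response = "gcvar", factors = "oxygen",
                       continuous = character(), interaction = TRUE),
    gc_response = list(response = "meanGC",
                       factors = c("phylum", "oxygen"),
                       continuous = character(), interaction = FALSE),
    gc_marginal = list(response = "meanGC", factors = "oxygen",
                       continuous = character(), interaction = FALSE),
    stop("unknown model kind: ", model))
}

#' Build the design for one of the GCVAR / GC-response models
#'
#' Assembles the model frame, sum-to-zero contrasts and model matrix for
#' the requested model:
#' \describe{
#'   \item{full}{GCVAR ~ GC + size + phylum + oxygen + temperature +
#'     pathogenicity + habitat, all factors sum-coded.}
#'   \item{interaction}{GCVAR ~ oxygen + GC:phylum — no global GC slope or
#'     phylum main effect; instead one GC regression coefficient per
#'     phylum, absorbing the tendency of genomes within a phylum to share
#'     GC content.}
#'   \item{gc_response}{mean GC ~ phylum + oxygen (the phylum-adjusted
#'     test of an aerobiosis association with GC).}
#'   \item{gc_marginal}{mean GC ~ oxygen alone (the unadjusted
#'     comparison, vulnerable to phylogenetic confounding).}
#' }
#' Rows with missing values in any used column, or a non-finite response
#' (degenerate GCVAR sentinels), are dropped with a logged count.
#'
#' @param records A data.frame accepted by [chromosomeRecords()].
#' @param model Model kind; see above.
#' @param gcScale `"fraction"` (default) or `"percent"`; the scale on
#'   which mean GC enters the design. The GC coefficient's magnitude
#'   depends on this choice, so it is recorded in every fit.
#' @return A list with elements `model`, `formula`, `response`, `data`
#'   (cleaned model frame), `contrasts`, `modelMatrix`, `nDropped`.
#' @importFrom stats reformulate model.matrix contr.sum
#' @export
buildDesign <- function(records, model = .modelKinds,
                        gcScale = c("fraction", "percent")) {
  model <- match.arg(model)
  gcScale <- match.arg(gcScale)
  spec <- .modelSpec(model)
  records <- chromosomeRecords(records)
  used <- unique(c(spec$response, spec$factors, spec$continuous,
                   if (spec$interaction) c("phylum", "meanGC")))
  miss <- setdiff(used, colnames(records))
  if (length(miss))
    stop("model '", model, "' needs column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stop("empty record set")

  keep <- rep(TRUE, nrow(records))
  for (col in used) {
    v <- records[[col]]
    keep <- keep & !is.na(v) & (!is.numeric(v) | is.finite(v))
  }
  nDropped <- sum(!keep)
  if (nDropped > 0L)
    gcvarMessage("dropping ", nDropped,
                 " record(s) with missing covariates or non-finite response")
  d <- records[keep, used, drop = FALSE]
  if (nrow(d) == 0L) stop("no usable records after dropping missing rows")

  if (gcScale == "percent" && "meanGC" %in% used)
    d$meanGC <- d$meanGC * 100

  ffac <- unique(c(spec$factors, if (spec$interaction) "phylum"))
  for (f in ffac) {
    d[[f]] <- droplevels(factor(d[[f]]))
    if (nlevels(d[[f]]) < 2L)
      stop("factor '", f, "' has a single level ('",
           levels(d[[f]]), "') and is unidentifiable in model '",
           model, "'")
  }
  if (spec$interaction) {
    few <- table(d$phylum) < 2L
    if (any(few))
      warning("phylum-specific GC slopes rest on a single record for: ",
              paste(names(few)[few], collapse = ", "))
  }

  rhs <- c(spec$factors, spec$continuous,
           if (spec$interaction) "meanGC:phylum")
  fml <- reformulate(rhs, response = spec$response)
  environment(fml) <- baseenv()
  contrasts <- stats::setNames(
    rep(list("contr.sum"), length(spec$factors)), spec$factors)
  mm <- model.matrix(fml, data = d, contrasts.arg = contrasts)
  list(model = model, formula = fml, response = spec$response,
       data = d, factors = spec$factors,
       interaction = spec$interaction, contrasts = contrasts,
       modelMatrix = mm, nDropped = as.integer(nDropped),
       gcScale = gcScale)
}

## Map lm coefficients to the full reportable effect vector: for each
## sum-coded k-level factor the omitted level's effect is minus the sum of
## the others; intercept, continuous terms and per-phylum slopes map 1:1.
.effectMap <- function(design, coefNames) {
  rows <- list()
  addRow <- function(term, type, level, w) {
    v <- stats::setNames(numeric(length(coefNames)), coefNames)
    v[names(w)] <- w
    rows[[length(rows) + 1L]] <<- list(term = term, type = type,
                                       level = level, w = v)
  }
  addRow("(Intercept)", "intercept", NA_character_,
         c("(Intercept)" = 1))
  for (f in design$factors) {
    lev <- levels(design$data[[f]])
    k <- length(lev)
    cn <- paste0(f, seq_len(k - 1L))
    stopifnot(all(cn %in% coefNames))
    for (j in seq_len(k - 1L))
      addRow(paste0(f, ":", lev[j]), f, lev[j],
             stats::setNames(1, cn[j]))
    addRow(paste0(f, ":", lev[k]), f, lev[k],
           stats::setNames(rep(-1, k - 1L), cn))
  }
  cont <- setdiff(colnames(design$modelMatrix),
                  c("(Intercept)",
                    unlist(lapply(design$factors, function(f)
                      paste0(f, seq_len(nlevels(design$data[[f]]) - 1L))))))
  for (cn in cont) {
    if (grepl("^meanGC:phylum", cn)) {
      lev <- sub("^meanGC:phylum", "", cn)
      addRow(paste0("gcSlope:", lev), "gc_slope", lev,
             stats::setNames(1, cn))
    } else {
      nm <- switch(cn, meanGC = "gc", sizeMb = "size", cn)
      addRow(nm, "continuous", NA_character_, stats::setNames(1, cn))
    }
  }
  rows
}

#' Fit a GCVAR or GC-response linear model
#'
#' Ordinary least squares with sum-to-zero factor coding, so each factor
#' level's effect is its deviation from the factor average and statements
#' like "phyla with GCVAR above the average phylum" are directly readable
#' from the term table. The omitted level of each factor is reconstructed
#' (estimate, standard error, t, p, CI) from the coefficient covariance,
#' so every level is reportable.
#'
#' @param records A data.frame accepted by [chromosomeRecords()].
#' @param model One of `"full"`, `"interaction"`, `"gc_response"`,
#'   `"gc_marginal"`; see [buildDesign()].
#' @param confidence Confidence level for the Wald intervals (default
#'   0.95).
#' @param gcScale `"fraction"` (default) or `"percent"`.
#' @return A [RegressionFit-class].
#' @examples
#' truth <- cohortTruth(coefficients = list(
#'   intercept = -3, gc = 0.4,
#'   oxygen = c(aerobic = -0.05, facultative = -0.05, anaerobic = 0.1)),
#'   noiseSd = 0.1)
#' rec <- simulateCohort(truth, n = 200, seed = 7)
#' fit <- fitGCVarModel(rec$records, model = "full")
#' effectIntervals(fit, terms = "oxygen")
#' @importFrom stats lm vcov coef pt qt df.residual
#' @export
fitGCVarModel <- function(records, model = .modelKinds, confidence = 0.95,
                          gcScale = c("fraction", "percent")) {
  model <- match.arg(model)
  gcScale <- match.arg(gcScale)
  if (confidence <= 0 || confidence >= 1)
    stop("'confidence' must lie strictly between 0 and 1")
  design <- buildDesign(records, model, gcScale)
  p <- ncol(design$modelMatrix)
  if (nrow(design$data) <= p)
    stop("need more observations (", nrow(design$data),
         ") than design columns (", p, ")")
  fit <- lm(design$formula, data = design$data,
            contrasts = design$contrasts)
  cf <- coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; aliased term(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  V <- vcov(fit)
  map <- .effectMap(design, names(cf))
  Tm <- do.call(rbind, lapply(map, `[[`, "w"))
  est <- as.numeric(Tm %*% cf)
  Vfull <- Tm %*% V %*% t(Tm)
  se <- sqrt(pmax(diag(Vfull), 0))
  df <- df.residual(fit)
  tstat <- est / se
  pval <- 2 * pt(-abs(tstat), df)
  q <- qt((1 + confidence) / 2, df)
  terms <- data.frame(
    term = vapply(map, `[[`, "", "term"),
    type = vapply(map, `[[`, "", "type"),
    level = vapply(map, `[[`, "", "level"),
    estimate = est, se = se, t = tstat, p = pval,
    ciLow = est - q * se, ciHigh = est + q * se,
    reconstructed = !vapply(map, function(m) any(m$w == 1), TRUE),
    stringsAsFactors = FALSE)
  rownames(Vfull) <- colnames(Vfull) <- terms$term
  s <- summary(fit)
  gcvarMessage("fitted '", model, "' model: n = ", nrow(design$data),
               " (", design$nDropped, " dropped), GC scale = ", gcScale)
  new("RegressionFit",
      modelKind = model, coding = "sum-to-zero",
      terms = terms, fit = fit, effectCov = Vfull,
      nObs = nrow(design$data), nDropped = design$nDropped,
      residualSd = s$sigma, rSquared = s$r.squared,
      confidence = confidence, gcScale = gcScale)
}

#' Confidence-interval table for fitted effects
#'
#' Extracts estimates and confidence intervals, with a significance flag
#' (interval excludes zero), in a shape ready for forest-style plotting of
#' factor effects.
#'
#' @param fit A [RegressionFit-class].
#' @param terms Optional filter: a character vector of term types (e.g.
#'   `"phylum"`, `"oxygen"`) and/or exact term names. Unknown entries are
#'   an error.
#' @return A data.frame with columns `term`, `type`, `level`, `estimate`,
#'   `ciLow`, `ciHigh`, `significant`.
#' @export
effectIntervals <- function(fit, terms = NULL) {
  stopifnot(is(fit, "RegressionFit"))
  tt <- modelTerms(fit)
  if (!is.null(terms)) {
    unknown <- setdiff(terms, c(tt$type, tt$term))
    if (length(unknown))
      stop("unknown term(s) in filter: ", paste(unknown, collapse = ", "))
    tt <- tt[tt$type %in% terms | tt$term %in% terms, , drop = FALSE]
  }
  data.frame(term = tt$term, type = tt$type, level = tt$level,
             estimate = tt$estimate, ciLow = tt$ciLow, ciHigh = tt$ciHigh,
             significant = tt$ciLow > 0 | tt$ciHigh < 0,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Linear contrast of fitted effects
#'
#' Estimates a weighted combination of reportable effects with its
#' standard error from the effect covariance, and a two-sided t-test.
#' Within each factor the weights must sum to zero (a single weighted
#' level is a cell mean, not a contrast).
#'
#' @param fit A [RegressionFit-class].
#' @param weights Named numeric vector; names are term names from
#'   `modelTerms(fit)` (e.g. `"phylum:Firmicutes"`).
#' @return A one-row data.frame: `estimate`, `se`, `t`, `df`, `p`.
#' @export
linearContrast <- function(fit, weights) {
  stopifnot(is(fit, "RegressionFit"))
  if (is.null(names(weights)) || any(names(weights) == ""))
    stop("'weights' must be a named numeric vector of term names")
  tt <- modelTerms(fit)
  unknown <- setdiff(names(weights), tt$term)
  if (length(unknown))
    stop("weights reference unknown term(s): ",
         paste(unknown, collapse = ", "))
  w <- stats::setNames(numeric(nrow(tt)), tt$term)
  w[names(weights)] <- weights
  for (f in setdiff(unique(tt$type), c("intercept", "continuous"))) {
    idx <- tt$type == f
    if (any(w[idx] != 0) && abs(sum(w[idx])) > 1e-8)
      stop("weights within factor '", f, "' must sum to zero (got ",
           signif(sum(w[idx]), 4), ")")
  }
  if (w["(Intercept)"] != 0)
    stop("the intercept cannot enter a contrast")
  est <- sum(w * tt$estimate)
  v <- as.numeric(t(w) %*% fit@effectCov %*% w)
  se <- sqrt(max(v, 0))
  df <- df.residual(fit@fit)
  tstat <- est / se
  data.frame(estimate = est, se = se, t = tstat, df = df,
             p = 2 * pt(-abs(tstat), df), row.names = NULL)
}

#' Archaea-versus-bacteria contrast of phylum effects
#'
#' The mean of the archaeal phylum effects minus the mean of the bacterial
#' phylum effects, from a fit whose phylum factor is sum-coded. Archaeal
#' phyla are identified by name (both the conventional and a common
#' variant spelling of Euryarchaeota are recognized by default).
#'
#' @param fit A [RegressionFit-class] from the `"full"` model.
#' @param archaea Character vector of archaeal phylum names.
#' @return As [linearContrast()].
#' @export
domainContrast <- function(fit,
                           archaea = c("Crenarchaeota", "Euryarchaeota",
                                       "Euryarcheota")) {
  tt <- modelTerms(fit)
  ph <- tt[tt$type == "phylum", , drop = FALSE]
  if (nrow(ph) == 0L)
    stop("fit has no phylum main effects (model '", modelKind(fit), "')")
  isA <- ph$level %in% archaea
  if (!any(isA) || all(isA))
    stop("need at least one archaeal and one bacterial phylum in the fit")
  w <- ifelse(isA, 1 / sum(isA), -1 / sum(!isA))
  linearContrast(fit, stats::setNames(w, ph$term))
}
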