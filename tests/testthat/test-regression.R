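test_that("record validation enforces vocabularies and ranges", {
  rec <- toyRecords()
  expect_silent(chromosomeRecords(rec))
  bad <- rec; bad$oxygen[1] <- "microaerophilic"
  expect_error(chromosomeRecords(bad), "microaerophilic")
  bad2 <- rec; bad2$meanGC[1] <- 1.2
  expect_error(chromosomeRecords(bad2), "meanGC")
  expect_error(chromosomeRecords(rec[, -2]), "phylum")
})

test_that("design dimensions follow sum-coding arithmetic", {
  rec <- toyRecords()
  d <- buildDesign(rec, "full")
  # intercept + 2 phylum + 2 oxygen + 1 temperature (2 levels here)
  # + 1 pathogenicity + 4 habitat + GC + size
  expect_equal(ncol(d$modelMatrix), 1 + 2 + 2 + 1 + 1 + 4 + 1 + 1)
  di <- buildDesign(rec, "interaction")
  # intercept + 2 oxygen + 3 per-phylum GC slopes
  expect_equal(ncol(di$modelMatrix), 1 + 2 + 3)
  expect_true(all(grepl("meanGC:phylum",
                        colnames(di$modelMatrix)[4:6])))
  dg <- buildDesign(rec, "gc_response")
  expect_equal(ncol(dg$modelMatrix), 1 + 2 + 2)
})

test_that("single-level factors are unidentifiable-term errors", {
  rec <- toyRecords()
  rec$oxygen <- "aerobic"
  expect_error(buildDesign(rec, "full"), "oxygen")
  expect_error(buildDesign(rec[0, ], "full"), "empty")
})

test_that("missing covariates and sentinel responses are dropped with a count", {
  rec <- toyRecords()
  rec$gcvar <- rnorm(nrow(rec))
  rec$gcvar[1] <- -Inf
  rec$habitat[2] <- NA
  expect_message(d <- buildDesign(rec, "full"), "dropping 2")
  expect_equal(nrow(d$data), nrow(rec) - 2)
  expect_equal(d$nDropped, 2L)
})

test_that("noiseless linear data is recovered exactly", {
  rec <- toyRecords()
  rec$gcvar <- 2 + 0.37 * rec$meanGC
  fit <- suppressMessages(suppressWarnings(fitGCVarModel(rec, "full")))
  tt <- modelTerms(fit)
  expect_equal(tt$estimate[tt$term == "gc"], 0.37, tolerance = 1e-10)
  expect_equal(tt$estimate[tt$term == "(Intercept)"], 2, tolerance = 1e-10)
  factors <- tt$type %in% c("phylum", "oxygen", "temperature",
                            "pathogenicity", "habitat")
  expect_lt(max(abs(tt$estimate[factors])), 1e-10)
})

test_that("sum-coded level effects sum to zero within every factor", {
  truth <- cohortTruth(coefficients = list(
    intercept = -3, gc = 0.4, oxygen = c(anaerobic = 0.11),
    phylum = c(Firmicutes = 0.12, Crenarchaeota = 0.22)), noiseSd = 0.15)
  sim <- simulateCohort(truth, n = 400, seed = 13)
  fit <- suppressMessages(fitGCVarModel(sim$records, "full"))
  tt <- modelTerms(fit)
  for (f in c("phylum", "oxygen", "temperature", "pathogenicity",
              "habitat")) {
    expect_lt(abs(sum(tt$estimate[tt$type == f])), 1e-10)
  }
  # every level is reportable, including the reconstructed one
  expect_equal(sum(tt$type == "oxygen"), 3)
  expect_equal(sum(tt$reconstructed[tt$type == "oxygen"]), 1)
})

test_that("estimates are invariant to record order", {
  truth <- cohortTruth(coefficients = list(intercept = -3, gc = 0.4),
                       noiseSd = 0.2)
  sim <- simulateCohort(truth, n = 200, seed = 17)
  f1 <- suppressMessages(fitGCVarModel(sim$records, "full"))
  set.seed(18)
  f2 <- suppressMessages(
    fitGCVarModel(sim$records[sample(nrow(sim$records)), ], "full"))
  expect_equal(modelTerms(f1)$estimate, modelTerms(f2)$estimate,
               tolerance = 1e-12)
})

test_that("OLS matches a brute-force normal-equations solution", {
  set.seed(23)
  for (i in 1:5) {
    n <- sample(30:50, 1)
    rec <- toyRecords(n)
    rec$meanGC <- runif(n, 0.3, 0.7)
    rec$sizeMb <- runif(n, 1, 8)
    rec$gcvar <- rnorm(n, -3, 0.5)
    fit <- suppressMessages(fitGCVarModel(rec, "full"))
    d <- buildDesign(rec, "full")
    X <- d$modelMatrix
    beta <- solve(t(X) %*% X, t(X) %*% rec$gcvar)
    expect_equal(unname(coef(fit@fit)), as.numeric(beta),
                 tolerance = 1e-8)
  }
})

test_that("confidence intervals follow the t-quantile arithmetic", {
  rec <- toyRecords()
  set.seed(29)
  rec$gcvar <- rnorm(nrow(rec), -3, 0.3)
  fit <- suppressMessages(fitGCVarModel(rec, "full", confidence = 0.95))
  tt <- modelTerms(fit)
  df <- stats::df.residual(fit@fit)
  q <- qt(0.975, df)
  expect_equal(tt$ciHigh - tt$estimate, q * tt$se, tolerance = 1e-12)
  expect_true(all(tt$ciLow < tt$estimate & tt$estimate < tt$ciHigh))
})

test_that("effect intervals flag significance and honor filters", {
  truth <- cohortTruth(coefficients = list(
    intercept = -3, gc = 0.4, oxygen = c(anaerobic = 0.3)),
    noiseSd = 0.1)
  sim <- simulateCohort(truth, n = 400, seed = 31)
  fit <- suppressMessages(fitGCVarModel(sim$records, "full"))
  ci <- effectIntervals(fit, terms = "oxygen")
  expect_equal(nrow(ci), 3)
  expect_true(ci$significant[ci$level == "anaerobic"])
  expect_equal(ci$significant, ci$ciLow > 0 | ci$ciHigh < 0)
  expect_error(effectIntervals(fit, terms = "plasmid"), "unknown")
  one <- effectIntervals(fit, terms = "gc")
  expect_equal(one$term, "gc")
})

test_that("linear contrasts validate weights and recover injected effects", {
  phyla <- c("Crenarchaeota", "Euryarchaeota", "Firmicutes",
             "Gammaproteobacteria", "Bacteroidetes", "Actinobacteria")
  truth <- cohortTruth(
    phyla = phyla,
    coefficients = list(
      intercept = -3, gc = 0.3,
      phylum = c(Crenarchaeota = 0.2, Euryarchaeota = 0.2)),
    noiseSd = 0.15)
  sim <- simulateCohort(truth, n = 300, seed = 37)
  fit <- suppressMessages(fitGCVarModel(sim$records, "full"))

  ct <- domainContrast(fit)
  # truth: mean archaeal effect - mean bacterial effect = 0.2 - (-0.1) = 0.3
  expect_lt(abs(ct$estimate - 0.3), 3 * ct$se)
  expect_lt(ct$p, 0.01)

  # self-contrast is exactly zero
  w <- setNames(c(1, -1), c("phylum:Firmicutes", "phylum:Firmicutes"))
  z <- linearContrast(fit, setNames(0, "phylum:Firmicutes"))
  expect_equal(z$estimate, 0)

  expect_error(linearContrast(fit, setNames(1, "phylum:Firmicutes")),
               "sum to zero")
  expect_error(linearContrast(fit, setNames(1, "phylum:Archaeoglobi")),
               "unknown")
  expect_error(linearContrast(fit, setNames(c(0.5, -0.5),
    c("(Intercept)", "phylum:Firmicutes"))), "contrast|sum to zero")
})

test_that("null lifestyle covariates come out non-significant", {
  # generative truth gives size, temperature, pathogenicity and habitat
  # zero effect; their terms should rarely reject
  rejections <- 0L
  total <- 0L
  for (s in 1:20) {
    truth <- cohortTruth(coefficients = list(
      intercept = -3, gc = 0.37, oxygen = c(anaerobic = 0.11)),
      noiseSd = 0.15)
    sim <- simulateCohort(truth, n = 300, seed = 1000 + s)
    fit <- suppressMessages(fitGCVarModel(sim$records, "full"))
    tt <- modelTerms(fit)
    idx <- tt$type %in% c("temperature", "pathogenicity", "habitat") |
      tt$term == "size"
    rejections <- rejections + sum(tt$p[idx] < 0.05)
    total <- total + sum(idx)
  }
  expect_lt(rejections / total, 0.10)
})

test_that("rank deficiency and underdetermined designs are clear errors", {
  rec <- toyRecords(12)
  rec$gcvar <- rnorm(12)
  expect_error(suppressMessages(fitGCVarModel(rec, "full")),
               "more observations")
})
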