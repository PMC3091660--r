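test_that("iid genome generation is seeded, bounded and on-target", {
  g1 <- simulateIidGenome(0.5, 5000, seed = 3)
  g2 <- simulateIidGenome(0.5, 5000, seed = 3)
  expect_identical(as.character(g1), as.character(g2))
  g3 <- simulateIidGenome(0.5, 5000, seed = 4)
  expect_false(identical(as.character(g1), as.character(g3)))

  # boundary: gc = 0 gives a pure A/T sequence
  at <- simulateIidGenome(0, 1000, seed = 5)
  expect_equal(sum(Biostrings::letterFrequency(at, c("G", "C"))), 0)

  # 3-sigma binomial bound on realized GC at n = 1e4
  g <- simulateIidGenome(0.5, 1e4, seed = 6)
  gcFrac <- sum(Biostrings::letterFrequency(g, c("G", "C"))) / 1e4
  expect_lt(abs(gcFrac - 0.5), 0.015)

  expect_error(simulateIidGenome(1.2, 100), "fraction")
  expect_error(simulateIidGenome(0.5, 0), ">= 1")
})

test_that("seeded generators leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulateIidGenome(0.5, 1000, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("island genomes shift windows inside the island only", {
  sim <- simulateIslandGenome(0.4, 1e5,
    islands = data.frame(start = 2e4, length = 1e4, gc = 0.8), seed = 8)
  p <- scanWindows(sim$sequence, 100)
  gr <- windowRanges(p)
  inIsland <- GenomicRanges::start(gr) > 2e4 &
    GenomicRanges::end(gr) <= 3e4
  expect_equal(mean(gcValues(p)[inIsland]), 0.8, tolerance = 0.02)
  expect_equal(mean(gcValues(p)[!inIsland]), 0.4, tolerance = 0.02)

  # islands recorded 1-based internally, exported 0-based
  expect_equal(GenomicRanges::start(sim$islands), 20001L)
  f <- tempfile(fileext = ".bed")
  writeIslandBed(sim$islands, f)
  expect_equal(readLines(f), "island_genome\t20000\t30000\tgc=0.8")
})

test_that("island genomes raise GCVAR over the matched iid background", {
  base <- simulateIidGenome(0.4, 2e5, seed = 12)
  withIsland <- simulateIslandGenome(0.4, 2e5,
    islands = data.frame(start = 5e4, length = 2e4, gc = 0.8), seed = 12)
  g0 <- gcvarValue(computeGCVar(scanWindows(base, 100)))
  g1 <- gcvarValue(computeGCVar(scanWindows(withIsland$sequence, 100)))
  expect_gt(g1, g0)
})

test_that("degenerate island layouts behave as documented", {
  # empty island list is the iid generator
  s0 <- simulateIslandGenome(0.4, 2000, islands = NULL, seed = 2)
  expect_identical(as.character(s0$sequence),
                   as.character(simulateIidGenome(0.4, 2000, seed = 2)))
  # a whole-genome island is iid at the island GC (in distribution):
  # check realized GC against a 3-sigma bound
  s1 <- simulateIslandGenome(0.2, 1e4,
    islands = data.frame(start = 0, length = 1e4, gc = 0.7), seed = 2)
  gcFrac <- sum(Biostrings::letterFrequency(s1$sequence, c("G", "C"))) / 1e4
  expect_lt(abs(gcFrac - 0.7), 3 * sqrt(0.21 / 1e4))

  expect_error(simulateIslandGenome(0.4, 1000,
    islands = data.frame(start = 900, length = 200, gc = 0.5)), "within")
  expect_error(simulateIslandGenome(0.4, 1000,
    islands = data.frame(start = c(0, 50), length = c(100, 100),
                         gc = 0.5)), "overlap")
})

test_that("cohort truth completes and centers factor effects", {
  tr <- cohortTruth(coefficients = list(oxygen = c(anaerobic = 0.11)))
  expect_equal(sum(tr$coefficients$oxygen), 0)
  expect_equal(tr$coefficients$oxygen[["anaerobic"]], 0.11)
  expect_equal(tr$coefficients$oxygen[["aerobic"]], -0.055)
  expect_message(
    tr2 <- cohortTruth(coefficients = list(
      oxygen = c(aerobic = 0.1, facultative = 0.1, anaerobic = 0.1))),
    "centering")
  expect_equal(unname(tr2$coefficients$oxygen), c(0, 0, 0))
  expect_error(cohortTruth(coefficients = list(oxygen = c(microbe = 1))),
               "levels")
  expect_error(cohortTruth(noiseSd = -1), "noiseSd")
})

test_that("noiseless cohorts are recovered exactly by the fit", {
  truth <- cohortTruth(coefficients = list(
    intercept = -3.1, gc = 0.37, size = 0.02,
    oxygen = c(anaerobic = 0.11),
    phylum = c(Firmicutes = 0.12, Crenarchaeota = 0.22)),
    noiseSd = 0)
  sim <- simulateCohort(truth, n = 400, seed = 41)
  fit <- suppressMessages(suppressWarnings(
    fitGCVarModel(sim$records, "full")))
  tt <- modelTerms(fit)
  expect_equal(tt$estimate[tt$term == "gc"], 0.37, tolerance = 1e-10)
  expect_equal(tt$estimate[tt$term == "size"], 0.02, tolerance = 1e-10)
  expect_equal(tt$estimate[tt$term == "oxygen:anaerobic"], 0.11,
               tolerance = 1e-10)
  expect_equal(tt$estimate[tt$term == "phylum:Firmicutes"],
               unname(truth$coefficients$phylum["Firmicutes"]),
               tolerance = 1e-10)
  expect_equal(tt$estimate[tt$term == "(Intercept)"], -3.1,
               tolerance = 1e-10)
})

test_that("cohort simulation is deterministic given the seed", {
  truth <- cohortTruth(noiseSd = 0.2)
  a <- simulateCohort(truth, 50, seed = 43)
  b <- simulateCohort(truth, 50, seed = 43)
  expect_identical(a$records, b$records)
  expect_equal(a$truth$seed, 43)
})

test_that("cohorts and truth serialize to readable TSV", {
  truth <- cohortTruth(coefficients = list(
    intercept = -3, gc = 0.37, oxygen = c(anaerobic = 0.11)),
    noiseSd = 0.15)
  sim <- simulateCohort(truth, 30, seed = 47)
  rec <- tempfile(fileext = ".tsv")
  tru <- tempfile(fileext = ".tsv")
  writeCohort(sim, rec, tru)
  back <- readTsv(rec)
  expect_equal(nrow(back), 30)
  flat <- readTsv(tru)
  expect_true("coefficients.oxygen.anaerobic" %in% flat$key)
  expect_equal(as.numeric(flat$value[flat$key == "seed"]), 47)
})
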