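# Independent naive oracle for the windowed GC statistic: plain string
# slicing and character counting, no shared code with the package path.
naiveGCVar <- function(s, w, ambiguityThreshold = 0.5) {
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  isGC <- chars %in% c("G", "C")
  isBase <- chars %in% c("A", "C", "G", "T")
  mgc <- sum(isGC) / sum(isBase)
  n <- length(chars) %/% w
  gcw <- numeric(0)
  for (i in seq_len(n)) {
    idx <- seq.int((i - 1L) * w + 1L, i * w)
    den <- sum(isBase[idx])
    if ((w - den) / w > ambiguityThreshold || den == 0L) next
    gcw <- c(gcw, sum(isGC[idx]) / den)
  }
  list(meanGC = mgc, gc = gcw, mad = mean(abs(gcw - mgc)),
       gcvar = log(mean(abs(gcw - mgc))))
}

randomDnaChar <- function(n, p = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - p) / 2, p / 2, p / 2, (1 - p) / 2)),
        collapse = "")
}

# Closed-form expected GCVAR of an iid chromosome: window GC is
# Binomial(w, p)/w, so D is approximately N(0, p(1-p)/w) and
# E|D| = sqrt(2 p (1-p) / (pi w)).
iidGCVarLimit <- function(p, w) 0.5 * log(2 * p * (1 - p) / (pi * w))

# Balanced small cohort with every factor at >= 2 levels, for design and
# fit unit tests.
toyRecords <- function(n = 48) {
  # deterministic but mutually non-aliased covariate patterns: cyclic
  # assignments for some factors, block assignments for others, and a
  # scrambled residue sequence for meanGC so no column is collinear
  i <- seq_len(n)
  data.frame(
    chromosomeId = sprintf("c%03d", i),
    phylum = rep(c("Firmicutes", "Crenarchaeota", "Gammaproteobacteria"),
                 length.out = n),
    oxygen = rep(c("aerobic", "facultative", "anaerobic"),
                 each = ceiling(n / 3), length.out = n),
    temperature = rep(c("mesophilic", "thermophilic"), length.out = n),
    pathogenicity = rep(c("pathogenic", "non-pathogenic"),
                        each = ceiling(n / 2), length.out = n),
    habitat = rep(c("aquatic", "host-associated", "multiple",
                    "specialized", "terrestrial"), length.out = n),
    sizeMb = seq(1.5, 8, length.out = n),
    meanGC = 0.3 + 0.4 * ((i * 37) %% 101) / 101,
    gcvar = 0,
    stringsAsFactors = FALSE)
}
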