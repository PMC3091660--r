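# gcvar

Intra-genomic GC content heterogeneity analysis for prokaryotic
chromosomes.

Bacterial and archaeal chromosomes differ not only in their mean GC
content but in how evenly GC is distributed along the chromosome:
horizontally acquired islands, rRNA operons and replication-associated
regions can all deviate from the chromosome average. `gcvar` is for
comparative genomicists who want a per-chromosome summary of that
heterogeneity and want to relate it to lifestyle covariates (oxygen
requirement, growth temperature, habitat, pathogenicity) and phylogeny
(phylum) across a cohort of genomes.

## The statistic and the models

The chromosome is tiled with non-overlapping windows of *w* bp (default
100), discarding the trailing partial window, so *N* = ⌊*L*/*w*⌋. With
*GC*ᵢ the GC fraction of window *i* and *GC̄* the chromosome mean GC,

> *D*ᵢ = *GC*ᵢ − *GC̄*,  GCVAR = log( (1/*N*) Σᵢ |*D*ᵢ| )

(natural log). Low GCVAR = homogeneous, high GCVAR = heterogeneous. For
a structureless iid chromosome the closed form
GCVAR ≈ ½·log(2*p*(1−*p*)/(π*w*)) holds (≈ −3.22 at *p* = 0.5,
*w* = 100), which the test suite uses as an analytic oracle.

On top of the statistic the package fits, with sum-to-zero factor coding
(every level reported as its deviation from the factor average):

* **full** — GCVAR ~ GC + size + phylum + oxygen + temperature +
  pathogenicity + habitat;
* **interaction** — GCVAR ~ oxygen + GC:phylum (one GC slope per phylum,
  absorbing phylum-dependent GC effects);
* **gc_response** — mean GC ~ phylum + oxygen, and **gc_marginal** —
  mean GC ~ oxygen alone, the pair that demonstrates how a GC–oxygen
  association can appear under phylogenetic confounding and vanish once
  phylum is modeled.

`linearContrast()` / `domainContrast()` test zero-sum combinations of
effects (e.g. archaea vs bacteria). A synthetic-data module generates
iid chromosomes, island-bearing chromosomes and cohorts of chromosome
records with known regression truth, so every stage is testable without
downloading genomes.

## Worked example

```r
library(gcvar)

# a 200 kb chromosome with one 20 kb island at GC 0.8 in a GC 0.4 background
sim <- simulateIslandGenome(0.4, 2e5,
  islands = data.frame(start = 5e4, length = 2e4, gc = 0.8), seed = 1)
computeGCVar(scanWindows(sim$sequence, 100, chromosomeId = "island_demo"))
#> GCVarResult for island_demo
#>   w = 100 bp, N = 2000 windows
#>   mean |D_i| = 0.0813525; GCVAR = -2.5090

# the matched island-free background is far more homogeneous
plain <- simulateIidGenome(0.4, 2e5, seed = 1)
computeGCVar(scanWindows(plain, 100))
#>   mean |D_i| = 0.038262; GCVAR = -3.2633
```

The island genome's GCVAR (−2.51) sits well above its island-free twin
(−3.26, essentially the iid closed form for *p* = 0.4): one island
covering 10% of the chromosome lifts the mean absolute window deviation
more than two-fold.

Cohort-level inference on simulated records with known truth (GC slope
0.37, anaerobic effect +0.11, noise sd 0.15):

```r
truth <- cohortTruth(coefficients = list(
  intercept = -3.2, gc = 0.37, oxygen = c(anaerobic = 0.11)),
  noiseSd = 0.15)
cohort <- simulateCohort(truth, n = 500, seed = 1)
fit <- fitGCVarModel(cohort$records, model = "full")
effectIntervals(fit, terms = "oxygen")
#>                 term   type       level    estimate       ciLow      ciHigh significant
#> 1     oxygen:aerobic oxygen     aerobic -0.04127806 -0.06057039 -0.02198572        TRUE
#> 2   oxygen:anaerobic oxygen   anaerobic  0.09254143  0.06858313  0.11649972        TRUE
#> 3 oxygen:facultative oxygen facultative -0.05126337 -0.07212158 -0.03040515        TRUE
```

The anaerobic effect is estimated at +0.093 with a 95% CI of
(0.069, 0.116), covering the simulation truth of +0.11: anaerobes'
chromosomes are more GC-heterogeneous than the average oxygen class in
this cohort, and the aerobic effect is negative — the ordering the
statistic was designed to expose. (In this cohort no archaeal excess was
injected, and accordingly `domainContrast(fit)` is non-significant,
p ≈ 0.14.)

A thin command-line wrapper (`inst/scripts/gcvar-cli.R`) exposes the
same pipeline as `scan`, `fit`, `simulate` and `trend` subcommands over
FASTA/TSV/bedGraph files.

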