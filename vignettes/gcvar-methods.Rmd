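---
title: "GCVAR: measuring and modeling intra-genomic GC heterogeneity"
author: "gcvar package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GCVAR: measuring and modeling intra-genomic GC heterogeneity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(gcvar))
```

## The statistic

Prokaryotic chromosomes differ widely in mean GC content, but they also
differ in how *evenly* that GC is distributed along the chromosome.
Chromosomally integrated foreign DNA, rRNA operons, and regions near the
replication origin and terminus can all carry a base composition that
departs from the chromosome average, so a chromosome may be GC-homogeneous
or GC-heterogeneous at a fixed mean GC. `gcvar` quantifies this with a
single number per chromosome.

Tile the chromosome with non-overlapping windows of $w$ bp (default
$w = 100$), discarding the trailing partial window, so
$N = \lfloor L / w \rfloor$. For window $i$ let $GC_i$ be the fraction of
G or C among the window's unambiguous bases, and let $\overline{GC}$ be
the same fraction computed over the whole chromosome. The window
residuals and the statistic are

$$D_i = GC_i - \overline{GC}, \qquad
  GCVAR = \log\!\left(\frac{1}{N}\sum_{i=1}^{N} |D_i|\right).$$

Low GCVAR means compositional homogeneity; high GCVAR means
heterogeneity. The log makes the cross-chromosome distribution of the
statistic roughly Gaussian, which is convenient for the linear models
below.

Under a compositionally structureless (iid) chromosome, window GC is
$\mathrm{Binomial}(w, p)/w$, $D_i$ is approximately
$N(0,\, p(1-p)/w)$, and the half-normal identity
$E|D| = \sigma\sqrt{2/\pi}$ gives the closed-form reference

$$GCVAR_{\mathrm{iid}} \approx
  \tfrac{1}{2}\log\!\frac{2\,p(1-p)}{\pi w},$$

about $-3.22$ at $p = 0.5$, $w = 100$. The test suite checks the
pipeline against this closed form, against a naive string-slicing
re-implementation, and against the $w^{-1/2}$ scaling law (GCVAR drops by
$\log 2$ from $w = 100$ to $w = 400$ on iid sequence).

## Conventions the definition leaves open

Several small choices are not forced by the formulas above; the package
fixes them as follows and treats them as part of the method's definition.

* **Log base.** Natural log. The choice is monotone and only rescales
  regression coefficients, but every reported coefficient depends on it,
  so it is stated prominently here.
* **Trailing partial window.** Discarded: $N$ is the maximum number of
  whole windows that fit.
* **Chromosome mean GC.** Computed over the *whole* chromosome,
  including the discarded tail, while each $GC_i$ uses only its window.
  A consequence accepted deliberately: residuals need not sum to exactly
  zero.
* **Ambiguous bases.** All non-ACGT IUPAC codes collapse to `N` at read
  time (`U` maps to `T`); `N` is excluded from both numerator and
  denominator of every GC fraction. Windows with more than 50% `N`
  (threshold configurable via `ambiguityThreshold`) are excluded
  entirely and counted in `nExcludedWindows` — assembly gaps must not
  masquerade as AT-rich windows. A window that is 100% `N` is excluded,
  never a division error.
* **Degenerate chromosomes.** If every residual is zero the mean
  absolute deviation is zero and GCVAR is $-\infty$; the result is
  flagged `degenerate` and carries the sentinel with a warning rather
  than an error, so batch scans never abort. The regression stage drops
  sentinel rows with a logged count.
* **Windows are non-overlapping** by construction, so neighboring
  windows contribute independent evidence; overlapping windows would
  correlate adjacent residuals and bias the mean absolute deviation.

## Residual diagnostics

For most chromosomes the within-chromosome distribution of $D_i$ is
close to Gaussian — window GC is a sum of many weakly coupled per-base
contributions. `residualDensity()` summarizes the residuals (moments and
histogram) together with a Gaussian reference pinned to the *same* mean
and standard deviation, and `gaussianAgreement()` turns that into a
verdict using moment thresholds: `gaussian_like` iff
$|\mathrm{skewness}| \le 0.15$ and $|\mathrm{excess\ kurtosis}| \le 0.3$
(both configurable). Formal normality tests are deliberately not used:
window GC is discrete (multiples of $1/w$), and at $N \sim 10^4$ windows
Shapiro–Wilk or Kolmogorov–Smirnov reject for discreteness that has
nothing to do with the bell-shape question. The thresholds comfortably
pass iid chromosomes (skewness sampling sd at $N = 10^4$ is about 0.025)
and fail 50/50 two-component mixtures, whose residuals are bimodal with
excess kurtosis near $-2$.

Across chromosomes, `gcvarGcTrend()` smooths GCVAR against mean GC with
loess (degree 2, tricube weights, span 0.75 by default, exact "direct"
surface so polynomial signals are reproduced without interpolation
artifacts). The GCVAR–GC relationship is typically non-linear, which is
why no straight line is fitted.

## The regression models

With one row per chromosome (526 chromosomes from 488 genomes at the
scale the method was designed for; each chromosome is an independent
observation and plasmid filtering is the caller's record selection),
`fitGCVarModel()` fits one of four OLS models:

* `full` — GCVAR on mean GC, genome size (Mb), phylum, oxygen
  requirement (aerobic / facultative / anaerobic), growth temperature,
  pathogenicity and habitat.
* `interaction` — GCVAR on oxygen plus a *per-phylum GC slope*
  (`GC:phylum`, no global GC term and no phylum main effect). Genomes
  within a phylum tend to share GC content, so an apparent phylum main
  effect may really be a phylum-dependent GC effect; this model absorbs
  exactly that.
* `gc_response` — mean GC on phylum + oxygen: the phylum-adjusted test
  of whether aerobiosis is associated with mean GC at all.
* `gc_marginal` — mean GC on oxygen alone: the unadjusted comparison,
  kept so the phylogenetic-confounding contrast can be demonstrated on
  data with known truth.

**Sum-to-zero coding.** Factors are coded with `contr.sum`, so each
level's effect is its deviation from the factor average and "above /
below the average phylum" is directly readable. The effect of each
factor's omitted level is reconstructed from the coefficient covariance
(estimate, se, t, p, CI), so every level is reportable and the displayed
effects within a factor sum to zero. This coding is a design choice:
per-level effects with a reportable value for (nearly) every level
cannot be expressed in treatment coding. Whether a published "anaerobic
effect" is versus-average or versus-reference is generally ambiguous;
here it is always versus the factor average, and simulation truths are
centered the same way so recovery is well defined.

**Scales.** GC enters as a fraction in $[0,1]$ by default; `gcScale =
"percent"` rescales it, which multiplies the GC coefficient by $1/100$,
so the scale is recorded in every fit and in the run manifest. Genome
size is in Mb. No multiple-testing correction is applied; p-values are
reported raw, per term.

**Contrasts.** `linearContrast()` estimates any zero-sum weighted
combination of reported effects with its standard error from the full
effect covariance; `domainContrast()` is the canonical example, the mean
of the archaeal phylum effects minus the mean of the bacterial ones.
Weights that do not sum to zero within a factor are rejected — a single
weighted level is a cell mean, not a contrast.

**Model-numbering caveat.** Published descriptions of this model family
sometimes number the interaction model inconsistently between their
methods and results text. The package avoids numeric model names
entirely; the four names above are the interface.

## The synthetic-data generators

The generators exist so that every stage has a ground truth:

* `simulateIidGenome(gc, length, seed)` draws bases iid with
  strand-symmetric probabilities (G and C each `gc/2`, consistent with
  Chargaff parity). This is the null model behind the Gaussian
  diagnostics and the closed-form GCVAR reference.
* `simulateIslandGenome()` redraws specified spans at their own GC — the
  horizontally-transferred-island mechanism. A 10 kb GC-0.8 island in a
  1 Mb GC-0.4 background raises GCVAR in every tested seed.
* `simulateCohort(truth, n, seed)` draws covariates from the
  distributions in a `cohortTruth()` and writes the response directly
  from the linear predictor plus $N(0, \sigma^2)$ noise. Responses are
  written at the record level rather than by generating and measuring
  500 full chromosomes; sequence-level end-to-end checks are done
  separately at small n, and the record-level route is what makes
  100-replicate coverage experiments affordable.

Cohort defaults emulate a curated prokaryote cohort: oxygen mix
0.47 / 0.34 / 0.19 (aerobic / facultative / anaerobic, matching the
roughly 246 : 177 : 103 split of a 526-chromosome curated collection),
mostly mesophiles (85%), per-phylum mean GC set to typical phylum values
(e.g. Firmicutes 0.37, Actinobacteria 0.66) with sd 0.05, and log-normal
genome sizes spanning roughly 1.5–8 Mb. Phylum–oxygen confounding is
induced by giving `oxygenProbs` as a matrix with one row per phylum.

What the generators deliberately do **not** emulate: codon and gene
structure, strand asymmetry (GC skew), repeats, amelioration of island
composition over time, and phylogenetic correlation beyond the phylum
labels. Passing tests therefore demonstrate that the statistic and the
inference machinery behave as specified under the stated generative
assumptions — not that any particular biological association holds in
real genomes.

## Verification experiments and problem sizes

The acceptance-level tests run, at fixed seeds:

* oracle equivalence on 100 random sequences (0.5–5 kb) against a naive
  string-slicing implementation, tolerance $10^{-12}$;
* the closed-form iid limit at $p \in \{0.3, 0.5, 0.7\}$, $L = 10^6$,
  within $\pm 0.02$;
* window scaling $w=100 \to 400$ within $\pm 0.03$ of $-\log 2$;
* exact strand invariance on 20 random cases;
* island monotonicity in 20/20 seeds;
* Gaussian / non-Gaussian classification rates $\ge 95\%$ over 100 iid
  and 100 mixture megabase chromosomes;
* 95% CI coverage of the simulation truths (GC slope 0.37, anaerobic
  effect 0.11, noise sd 0.15, n = 500) in $\ge 90$ of 100 replicates;
* the confounding demonstration: with phylum driving GC and correlating
  with oxygen but no direct oxygen effect, the anaerobic-vs-aerobic
  contrast from the phylum-adjusted fit is non-significant in
  $\ge 90\%$ of replicates while the unadjusted fit rejects in the
  majority (in practice, essentially always);
* OLS agreement with a brute-force normal-equations solve to $10^{-8}$,
  and type-I error $0.05 \pm 0.03$ for a fixed term over 200 all-null
  cohorts.

Cohort sizes (n = 300–500, 100–200 replicates) keep each experiment well
inside a minute while leaving coverage estimates with binomial standard
errors near 2 percentage points. The same experiments, re-seeded from a
single command-line seed, are what `scripts/acceptance.R` recomputes.

## A worked example

```{r example}
# a chromosome with one GC-shifted island
sim <- simulateIslandGenome(0.4, 2e5,
  islands = data.frame(start = 5e4, length = 2e4, gc = 0.8), seed = 1)
profile <- scanWindows(sim$sequence, windowLength = 100,
                       chromosomeId = "island_demo")
computeGCVar(profile)

# the matched island-free background is much more homogeneous
plain <- simulateIidGenome(0.4, 2e5, seed = 1)
computeGCVar(scanWindows(plain, 100))

# cohort-level inference with known truth
truth <- cohortTruth(coefficients = list(
  intercept = -3.2, gc = 0.37, oxygen = c(anaerobic = 0.11)),
  noiseSd = 0.15)
cohort <- simulateCohort(truth, n = 500, seed = 1)
fit <- fitGCVarModel(cohort$records, model = "full")
effectIntervals(fit, terms = "oxygen")
domainContrast(fit)
```

## Known limitations

* GCVAR summarizes the *magnitude* of window deviations only; two
  chromosomes with identical GCVAR can differ completely in where the
  heterogeneity lies. The bedGraph tracks exist for that positional
  view.
* The regression machinery models phylum as a fixed factor; it is not a
  phylogenetic comparative method, and residual phylogenetic correlation
  below the phylum level is not modeled.
* The statistic depends on $w$; results at different window lengths are
  comparable only through the scaling analysis, not directly.
* Moment-based Gaussian verdicts can miss departures that leave the
  third and fourth moments intact.
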