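---
title: "Estimating mutation and gene-conversion rates from mutation-accumulation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mutation and gene-conversion rates from mutation-accumulation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutacc)
```

## The estimation problem

In a mutation-accumulation (MA) experiment, lineages descend from a common
ancestor by single-offspring transfers so that selection is minimized and
spontaneous mutations accumulate nearly neutrally. After `g` generations each
line is sequenced and compared with its ancestor. `mutacc` implements the
downstream analysis for a diploid, clonally propagated organism (the design
mirrors MA studies in *Daphnia*): detection of de novo events from
ancestor/descendant genotype call sets, rate estimation with bootstrap
confidence intervals at four aggregation levels, mutation spectra, and
derived evolutionary quantities. A forward simulator with a complete
ground-truth ledger provides the validation substrate.

Three event classes are analysed, each with its own estimator:

* **Nuclear base substitutions.** A line's rate is
  `mu_bs = x / (g * 2n)`, where `x` counts accepted de novo substitutions
  and `n` is the number of haploid callable sites (`2n` diploid bases at
  risk).
* **Mitochondrial heteroplasmies.** New mtDNA mutations segregate within
  the cell's mtDNA population, so each mutation `i` is observed at an
  allele frequency `f_i` rather than as a discrete genotype. Assuming
  neutrality, the expected frequency of a derived allele stays constant
  through drift, so summed frequencies estimate accumulated mutational
  input: `mu_m = sum(f_i) / (g * n)` with `n` the mtDNA length.
* **Gene conversion (loss of heterozygosity).** Homolog-templated repair
  converts ancestrally heterozygous sites to homozygosity, often in
  multi-site tracts. The per-heterozygous-site rate is
  `mu_g = x_g / (g * n_het)` with `x_g` the number of converted sites and
  `n_het` the ancestral heterozygous-site count.

## Detection model and filters

Detection is a pure function of the call sets and a `filter_config()`:

* A nuclear site is called de novo iff it is ancestrally homozygous,
  callable in ancestor and line, carries a new allele, and passes depth
  (`min_depth`, `max_depth_factor` times the line mean) and quality floors.
  With `require_unique_to_line` (on by default, standard MA practice) a
  variant observed in more than one independently propagated line is
  rejected as ancestral polymorphism or a systematic artifact.
* A heteroplasmy is called iff absent from the ancestor with
  `f >= mito_min_frequency` (default 0.05, a conventional calling floor)
  and implied alternate-read support of at least `mito_min_alt_reads`.
  Because sub-threshold frequencies are real mutational input that the
  floor discards, detection-path mtDNA rates are lower bounds; the
  simulator's truth ledger quantifies the gap.
* Conversion candidates are ancestral het sites homozygous in the line and
  callable in both. A hemizygous deletion also presents as loss of
  heterozygosity but halves coverage, so sites with depth below
  `lod_depth_ratio_min` (default 0.5) times the line mean are excluded.
  Surviving sites are clustered into tracts by single linkage with a
  maximum inter-site gap (`max_gap`, default 10 kb — a generous bound on
  mitotic conversion tract scale; on sorted positions this is exactly the
  consecutive-gap rule, and the test suite checks it against a brute-force
  all-pairs oracle).

Filters never auto-exclude outlier lines; unusually high lines are reported
like any other and exclusion is left to the analyst.

## Aggregation and uncertainty

Line estimates aggregate to genotype, population, and species level under
two schemes, both reported by `aggregate_rates()`:

* `pooled` — summed events over summed exposures (exposure-weighted). This
  is the default: published species-level MA rates are generally not the
  unweighted mean of genotype values, implying exposure weighting.
* `mean_of_means` — the unweighted mean of the next-lower level's values,
  stepping line -> genotype -> population -> species.

Confidence intervals come from a percentile bootstrap that resamples
*lines* with replacement within each group — the line is the independent
unit of an MA design; mutations within a line are not. BCa corrections are
not applied; the percentile interval is the plainest reading of
"bootstrapped CI" and its coverage is verified by simulation in the test
suite (200 replicate experiments, nominal 95% within 3 binomial SEs).

## The simulator

`simulate_ma_experiment()` generates the full experiment and records every
planted event:

* **Reference and ancestry.** I.i.d. bases at a configurable GC content
  (default 0.41, the observed *D. magna* value) over one linear nuclear
  contig and one circular mtDNA contig; ancestral heterozygous sites are
  Bernoulli per callable site with a uniformly drawn alternate allele,
  independently per genotype.
* **Nuclear substitutions.** Per line, Poisson with mean
  `mu_bs * g * 2n`, placed uniformly over callable ancestrally homozygous
  sites, with the six-class spectrum applied via rejection on the central
  base. The default class weights put C:G->T:A first (0.40) and fix the
  transition fraction at 0.6063 so the count-based Ts:Tv is 1.54, matching
  the nuclear ratio reported for *D. magna*; the paper publishes no
  numeric class weights, so this one-line calibration is the package's
  choice.
* **Gene conversion.** Tracts initiate at heterozygous sites at rate
  `mu_g / m` per het-site-generation, where `m = 1 + (L - 1) * rho` is the
  expected number of het sites covered by a tract of geometric mean length
  `L` at het density `rho`; the initiating site plus all het sites within
  the tract convert, with one fair-coin direction per tract. Division by
  `m` makes the planted per-site conversion rate exactly `mu_g`, so the
  `x_g/(g * n_het)` estimator is unbiased by construction. The default
  `L = 340` is calibrated so `m = 2.70` at the default het density,
  matching the observed 35 converted sites over 13 tracts (2.69 per
  tract) in the *D. magna* study. Geometric tract lengths are the standard
  single-parameter conversion model; the heavy geometric tail makes
  single-experiment converted-site counts overdispersed relative to
  Poisson (relative SD near 30% under default scales), which is why
  conversion-rate recovery is asserted within Monte-Carlo SEs rather than
  tight percentage bands.
* **Mitochondrial heteroplasmy.** A Wright–Fisher bottleneck: each
  generation, new per-copy mutations arise as Poisson(`mu_m * n * N`) at
  frequency `1/N`, then every segregating frequency is binomially resampled
  over the `N = 100` mtDNA copies. Neutral drift keeps `E[sum f]` equal to
  `mu_m * g * n`, the property the frequency-sum estimator relies on; the
  test suite verifies it empirically over 200 replicate lines.
* **Noise.** `genotype_error_rate` flips emitted genotype records between
  het and hom; depth and quality are constant pass-through values so that
  the zero-noise round trip (detection output identical to the truth
  ledger) is exact. The model does not create false variants at
  unrecorded hom-ref positions, does not vary coverage along the genome,
  and does not simulate reads; passing tests therefore validate the
  estimators and filters, not robustness to mapping artifacts or
  coverage-driven callability gaps in real data — callability enters only
  through externally supplied masks.
* **Seeding.** One integer seed; the experiment consumes a single
  sequential RNG stream in a fixed stage order (reference, then per
  genotype: ancestry, then per line: substitutions, conversions,
  heteroplasmy), so a config reproduces byte-identical call sets.

Defaults reproduce the study conditions: 9 genotypes from 3 populations,
66 MA lines (7–8 per genotype), `g = 30`, 15 kb circular mtDNA, and the
published species-wide point estimates as planted true rates
(`8.96e-9`, `6.13e-7`, `8.7e-7`). The default `generation_time_days = 16.8`
is the value implied by the published per-generation and per-day nuclear
rate columns (the mtDNA columns imply a slightly different value; the
published table does not state which is exact, so generation time is
per-line metadata).

## Derived quantities

* **Equilibrium GC content** `alpha / (alpha + beta)` from the conditional
  AT->GC (`alpha`) and GC->AT (`beta`) class rates; invariant to common
  rescaling.
* **Expected heterozygosity** at mutation–conversion equilibrium,
  `mu_bs / (mu_bs + mu_g)`.
* **Effective population size** from `pi = 4 Ne mu`; the synonymous-site
  diversity `pi_s` is always an external scalar input (it comes from
  population sequencing, not from the MA experiment) and is never bundled.
* **Heritability and evolvability** of the line-level rate by a one-way
  random-effects decomposition (expected mean squares, with the unbalanced
  `n0` correction). Negative method-of-moments `V_G` is truncated to zero
  and flagged. "Evolvability" admits two mean scalings, so both
  `V_G/mean^2` (the conventional mean-standardized genetic variance) and
  `V_G/mean` are emitted with explicit labels rather than silently picking
  one.
* **Spectrum statistics.** Conditional rates divide counts by the callable
  sites of the matching collapsed context (or central-base class),
  removing composition bias. A site is CpG iff its collapsed central C is
  followed by G — a strand-symmetric convention. The six-class
  homogeneity test is a chi-square against expectations proportional to
  class site exposure (df = 5). Ts:Tv defaults to raw counts with a
  conditional-rate variant exposed, since published ratios rarely state
  which is used.
* **Comparisons.** Spearman correlation with the
  `t = rho * sqrt((n-2)/(1-rho^2))` approximation, and one-way ANOVA with
  Tukey HSD, with an optional log10 transform for rate data. On the
  published genotype-level values neither raw nor log-transformed rates
  reproduce the study's printed F statistic, so the exact response
  variable behind it is treated as unknown; both transforms are exposed
  and the choice is recorded in the output.

## Numerical and convention choices

* Internal coordinates are 1-based closed (VCF-native); BED input/output is
  converted at the boundary by rtracklayer. Context windows wrap on the
  circular mtDNA contig and are dropped at linear contig edges or when any
  window base is not A/C/G/T.
* Multi-sample uniqueness, tract clustering, and all detection steps are
  deterministic; ties cannot arise (positions are unique per line).
* Degenerate inputs are flagged rather than silently handled: single-line
  bootstrap groups (`degenerate = TRUE`), zero control rates
  (`undefined = TRUE`), all-equal heritability inputs (`H2 = NA`),
  perfectly monotone correlations (`t = Inf`), zero transversions
  (`Ts:Tv = Inf`).

## Problem sizes used in validation

The test suite and the acceptance script run the full 66-line design at
1e7 haploid callable bp per line for substitution and conversion recovery,
20 replicate 66-line experiments for mtDNA recovery, and 200 replicate
down-scaled experiments (50 kb genomes) for bootstrap coverage — sizes at
which every Monte-Carlo tolerance in the tests is derived from the
corresponding sampling distribution, not tuned to outcomes. The bundled
`analysis/` workflow uses a 1 Mb demonstration genome so the five stages
run in seconds; at that scale per-experiment event counts are small (tens
of substitutions) and the demo tables wobble accordingly, which the stage
scripts state when they print their findings.

## Known limitations

* Callable-site definitions (depth/quality per line) are consumed as
  externally supplied masks; the package does not derive masks from BAMs.
* The mtDNA detection floor biases detection-path mito rates downward;
  use the truth-frequency path (or lower the floor) on simulated data.
* The noise model exercises genotype-flip errors only; read-level
  artifacts, indels, TEs, and selection during propagation are out of
  scope.
* Tract direction is planted per tract but reported per site; reciprocal
  crossover detection is not attempted.
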