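---
title: "Estimating effective population size from a single SNP sample"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating effective population size from a single SNP sample}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neabc)
```

## The problem

The contemporary effective population size Ne governs how quickly a
population loses genetic variation to drift, and is a central quantity in
conservation genetics: an Ne below roughly 50 flags short-term inbreeding
risk. Estimating Ne from a *single* sample of genotypes — no temporal
replicates, no linkage map, no reference genome — is the setting this
package addresses. The input is one population sample of S diploid
individuals genotyped at L biallelic SNPs in GENEPOP format.

## The estimator

The method is approximate Bayesian computation (ABC) with a local linear
regression adjustment:

1. **Summary statistics.** Five statistics are computed on the observed
   sample: mean expected heterozygosity
   $\hat H_e = \frac{1}{L}\sum_i 2 p_i (1 - p_i)$; the fixation index
   $\hat F_{is} = 1 - \frac{1}{L}\sum_i \hat H_{o,i}/\hat H_{e,i}$
   (negative under the heterozygote excess produced by small two-sex
   populations); the mean $\hat h$ and sample variance $\hat v_h$ of
   per-individual multi-locus homozygosity counts; and the mean over locus
   pairs of the squared Burrows composite disequilibrium correlation
   $\hat r^2$. The Burrows estimator needs no phase information: with
   dosages $X, Y \in \{0,1,2\}$ over the $n$ individuals called at both
   loci, $\hat\Delta = \sum X Y / (2n) - 2 p_A p_B$ and
   $\hat r = \hat\Delta / \sqrt{(p_A(1-p_A)+D_A)(p_B(1-p_B)+D_B)}$, where
   $D$ is the homozygote-excess departure from Hardy–Weinberg at each
   locus. LD of this kind is generated by the finite number of parents and
   is the statistic most directly informative about Ne.

2. **Reference table.** `trials_J` parameter triples (Ne, t, θ) are drawn
   from uniform priors — Ne and t discrete-uniform, θ log-uniform — and for
   each a two-sex Wright–Fisher population of size Ne is simulated forward
   t generations, a progeny cohort is produced, and S individuals are
   sampled at L loci; the same five statistics are recorded.

3. **Rejection and regression.** Statistics are standardized by their
   reference-table median/MAD, the Euclidean distance from the observed
   vector is computed for every record, and the closest
   `acceptance_fraction` are accepted (threshold δ). Accepted records get
   Epanechnikov weights $1-(d/\delta)^2$; Box–Cox transformed Ne
   (λ = −0.2) is regressed on the standardized statistics by weighted
   least squares, and each accepted value is projected to the observed
   statistics (fitted value at the target plus its residual). The
   back-transformed, prior-clamped values form the posterior sample,
   summarized by the weighted median and 2.5%/97.5% weighted quantiles
   (inverted-CDF rule on cumulative weights).

## The simulation model

The forward model has two allogamous sexes with equal counts (Ne/2 each;
odd draws are rounded up). Each offspring draws a uniform-random father
and mother and inherits one uniformly chosen allele from each at every
locus. Loci are unlinked (free recombination), yet share the pedigree of
their carriers — which is exactly what generates the finite-size linkage
disequilibrium the $\hat r^2$ statistic measures. Transmitted alleles
mutate with probability `mu` per generation (default 1.2e-8, effectively
inert over the 2–8 generations simulated; θ is carried as a record-keeping
parameter). Internally the population is stored as a loci-major
allele-dosage matrix — lossless for unordered genotypes — and the
transmission step runs in a small compiled kernel on R's RNG stream, so
one simulation trial costs milliseconds.

Initial allele frequencies are drawn from the neutral-equilibrium folded
site frequency spectrum — density proportional to $1/x$ on the grid
$x \in \{1/(2N_e), \dots, 1-1/(2N_e)\}$, symmetrized — conditioned on the
minor frequency being at least `maf_floor`. This mirrors the idea that the
population's standing variation predates the (possibly non-equilibrium)
recent history being estimated, while guaranteeing every locus starts
polymorphic like the filtered observed panel.

### Matching the observed data's ascertainment

Observed data reach the estimator only after two filters: loci and then
individuals with more than 20% missing data are dropped (loci first, so
individuals are not discarded for loci that were doomed anyway), then loci
with sample minor allele frequency below 0.05 (inclusive boundary: a locus
at exactly the cutoff is kept). The observed loci are therefore
*ascertained on sample MAF*. Reference simulations must undergo the same
ascertainment: each trial simulates a surplus of loci inside one
population (1.6 L + 4), discards loci whose sampled MAF falls below the
cutoff exactly as the filter would, and keeps a random subset of exactly L
passing loci. Without this, simulated samples retain drift-depleted loci
the observed panel cannot contain; in our replicated recovery experiments
that mismatch inflated expected heterozygosity of the observed target
relative to the table (0.320 vs 0.293 at the true Ne in one diagnostic
run) and produced an upward bias of roughly 10% at S = 50. With
ascertainment matched the recovery experiments centre on the true value.
Because all surplus loci come from the same population, the pedigree-driven
LD structure among retained loci is preserved. A trial that cannot supply
L passing loci is redrawn within its own RNG substream (counted, and
warned about when frequent, as it becomes at very small Ne).

The synthetic-data generator applies the same conditioning: a dataset
advertised as L loci delivers L *analysable* loci, the way published SNP
panels are reported. In replicated recovery experiments this symmetry
matters beyond the first-order frequency spectrum: a raw fixture panel
that loses loci to the filter loses them in proportion to its own drift
realization, so its surviving loci carry systematically less
heterozygosity than unconditioned simulations at the same true Ne
(a further ~0.7 within-Ne standard deviations in one diagnostic run),
which reintroduced several percent of upward bias at S = 50. With both
sides ascertained identically, replicated medians centre on the truth.

Samples larger than the drawn Ne are legitimate: the progeny cohort from
the generation-t adults is enlarged to S offspring when S > Ne — the
number of progeny a population produces is not bounded by the number of
breeders — and S individuals are drawn without replacement.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `ne_low`, `ne_high` | 50, 150 | uniform prior on Ne (model supports 4–400) |
| `t_low`, `t_high` | 2, 8 | generations of random mating before sampling |
| `theta_low`, `theta_high` | 4.8e-5, 4.8e-3 | population mutation rate bounds (log-uniform) |
| `mu` | 1.2e-8 | per-locus per-generation mutation rate |
| `trials_J` | 20000 | reference-table size |
| `min_maf` | 0.05 | sample MAF cutoff (observed and simulated alike) |
| `max_missing_*` | 0.20 | missing-data tolerance per locus / individual |
| `acceptance_fraction` | 0.02 | fraction of trials accepted (δ is this distance quantile) |
| `boxcox_lambda` | −0.2 | power transform applied to Ne before regression |

θ is drawn log-uniformly because its default bounds span two orders of
magnitude and only a scale-free reading treats the decades evenly; a
linear-uniform option is available (`theta_scale = "linear"`). The
acceptance threshold is expressed as a *fraction* of trials rather than an
absolute distance so that δ adapts to the scale of the standardized
statistics; with the default 0.02 and J = 20000 the regression sees 400
points. When J is reduced for quick analyses, raise `acceptance_fraction`
so that at least ~50 records are accepted (the engine refuses below 20 and
warns below 100).

## Numerical choices

* **Distance standardization** uses the reference-table median and MAD
  (as computed by `mad()`, consistency constant included). The five
  statistics differ in scale by orders of magnitude (r² is ~1/S,
  multi-locus homozygosity variance is ~L); a raw Euclidean distance would
  be dominated by whichever statistic happens to be largest. A statistic
  that is constant across the table carries no information and is dropped
  from the distance with a warning. A `"none"` mode preserves the raw
  distance for comparison.
* **Burrows pairs** use pairwise deletion for missing data; a pair is
  unusable when fewer than 2 individuals are called at both loci, when
  either locus is monomorphic within them, or when a denominator term is
  non-positive (e.g. an all-heterozygote locus). Unusable pairs are
  excluded from the mean rather than erroring, which lets simulated
  samples containing drift-fixed loci be summarized. For the same reason
  `stats_vector()` skips monomorphic loci in the fixation-index ratio
  (the standalone `fixation_index()` errors instead, pointing at the MAF
  filter).
* **Correlation clamping**: $\hat r$ is clamped to [−1, 1] before
  squaring, so $\hat r^2 \in [0, 1]$ always.
* **Degenerate regression designs** (e.g. all accepted records sharing
  identical statistics) fall back to pure rejection with a warning rather
  than failing.
* **Back-transform overflow**: with λ < 0 the inverse Box–Cox diverges
  when $1 + \lambda y \le 0$; adjusted values past that point correspond
  to arbitrarily large Ne and are clamped to the upper prior bound, as are
  all posterior samples (clamping rather than discarding, which would
  shrink intervals artificially).
* **Reproducibility**: every trial of the reference table runs on its own
  pre-derived L'Ecuyer-CMRG substream, so results are bit-identical for a
  given seed regardless of the number of workers; redraws consume their
  own substream only.
* **Quantiles** are inverted-CDF on cumulative normalized weights — the
  smallest sample whose cumulative weight reaches p — so the reported
  median is always an actually sampled value.

## What the synthetic data generator does and does not emulate

`fixture_spec()`/`make_dataset()` produce GENEPOP files by running the same
Wright–Fisher model at a known true Ne, conditioning the panel on the MAF
floor as described above, and optionally masking genotypes uniformly at
random. They emulate drift, two-sex heterozygote excess, pedigree LD,
MAF-ascertained panels, and missingness *rates*; they do not emulate
genotyping error,
allele dropout, RAD-seq ascertainment, population structure, or
non-uniform missingness mechanisms. Recovery tests on these fixtures
therefore demonstrate internal consistency of the estimator under its own
model assumptions — a necessary condition, not a field validation.

## Problem sizes used in the shipped experiments

The package's replicated recovery experiments (test suite and
`scripts/acceptance.R`) run at desk scale by design: reference tables of
J = 800 simulations with an acceptance fraction of 0.0625 (50 accepted),
two loci settings per grid, and 3–7 replicates per cell. Grand means over
replicates centre on the true value, but individual runs carry visible
Monte-Carlo spread, and fold-over statistics such as the mean absolute
percent deviation are inflated relative to a full-scale analysis
(J = 20000, four loci settings, 10 replicates). For production analyses
use the defaults.

## Known limitations

* All loci are assumed unlinked. With a mapped genome, thin to
  inter-chromosomal pairs; physically linked pairs inflate r² and bias Ne
  downward. No chromosome-number correction is applied.
* One population per analysis: multiple GENEPOP `Pop` blocks are merged
  with a warning, and structured samples will bias the statistics.
* The posterior is clamped to the prior's support, so an Ne at or beyond
  the prior boundary shows up as a posterior piled against that boundary —
  widen the prior and re-run when that happens.
* The all-pairs LD computation is O(L²S) and dominates runtime for large
  panels; `max_pairs` subsamples pairs at a small accuracy cost.
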