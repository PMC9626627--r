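---
title: "Models and methods behind geoffset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind geoffset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`geoffset` quantifies how much the local climate adaptation of a
structured set of populations will be disrupted by projected climate
change. This vignette explains each model in the chain, the tunable
parameters and their defaults, what the synthetic landscape does and
does not emulate, and the numerical and design choices that were
genuinely open.

## The latent-factor association scan

For a dosage matrix $Y$ ($n$ individuals $\times$ $L$ variants, ALT
allele counts 0/1/2, missing cells mean-imputed) and one environmental
variable $e$ at a time, `lfmm_scan()` fits per variant the ordinary
least-squares model

$$ y_\ell = \mu_\ell + \beta_\ell\, z(e) + U \gamma_\ell + \varepsilon $$

where $U$ holds $K$ latent factors that absorb population structure
(default $K = 3$, matching the number of ancestry clusters the
synthetic landscape carries: two groups plus admixture-like spatial
variation). Two estimator details matter:

* **Latent factors from residualized genotypes.** The factors are the
  leading left singular vectors of $Y$ *after projecting out*
  $[1, z(e)]$, recomputed per variable — the least-squares latent
  factor estimator. Estimating $U$ from the raw genotype SVD fails
  when candidate loci are dense (here 2% of loci): the clines under
  test become the factors and mask their own signal. The raw-SVD
  variant is available via `refine = FALSE`.
* **Genomic-inflation calibration.** Individuals within a population
  share their environment, so per-individual standard errors are
  optimistic and drift adds population-level variance. The z-scores
  are rescaled by $\lambda = \mathrm{median}(z^2) / \chi^2_{1,0.5}$
  per variable before conversion to p-values, then
  Benjamini–Hochberg-adjusted per variable with hits unioned across
  variables at FDR 0.05. On a null landscape ($\beta = 0$ for every
  planted locus) the calibrated p-values are indistinguishable from
  uniform and the scan returns essentially no hits.

## The redundancy-analysis outlier scan

`rda_scan()` regresses centered population allele frequencies on the
standardized retained environmental variables, takes the SVD of the
fitted values, and computes each variant's loading as the correlation
of its frequency vector with each constrained-axis score vector. A
variant is flagged when its loading is more than 3 standard deviations
from the center on any constrained axis. Two implementation choices:

* **All constrained axes are scanned by default.** With $k$ retained
  variables the constrained space has rank $k$; scanning a fixed small
  number of axes silently discards retained climate dimensions and
  with them whole groups of associated loci. `k_axes` remains
  configurable.
* **Median/MAD center and scale.** At realistic genome scale the
  candidate fraction is tiny and mean/SD are fine; on a dense
  synthetic panel the candidates themselves fatten a plain SD and push
  the cutoff into the signal. The MAD-consistent estimate of the same
  standard deviation is contamination-robust and identical on the
  null bulk. The cutoff stays at 3 SD.

Variables entering the RDA are pruned with `select_env_variables()`:
walk variables in descending importance (by convention, the turnover
model's ranking fitted on the first-scan candidates) and keep a
variable only if its absolute Spearman correlation with every kept
variable is below 0.6. Variants flagged by both scans form the *core
adaptive set*; the intersection trades a little recall for a much
lower false-discovery rate than either scan alone.

## RONA

For each associated locus $\ell$ and variable $e$,
$p_\ell = a_\ell + b_\ell e$ is fitted across populations by OLS.
RONA for a population is $|\hat p(e_{\mathrm{fut}}) -
\hat p(e_{\mathrm{cur}})|$ with fitted values truncated to $[0,1]$
before differencing; without truncation this is exactly
$|b_\ell|\,|\Delta e|$. Loci are averaged with weights $w_\ell =
R^2_\ell$ (equal weights via `weight_by_r2 = FALSE`), and the four
climate models are summarized as mean ± SE per scenario. The baseline
is the fitted value at the current climate rather than the observed
frequency — the regression line is the model of the equilibrium
frequency, and this choice makes the closed form exact; regressions
are fitted once on current climate and projected into each model's
future.

## The turnover model and the three offsets

`fit_turnover()` re-implements the essentials of the gradient-forest
algorithm: per locus, a forest of depth-unlimited CART regression
trees (minimum node size 2) on bootstrap samples of *populations*,
with a random subspace of `mtry = ceiling(P/3)` predictors per tree.
Every split's impurity decrease is recorded at its threshold;
per-locus importances are normalized to the locus's out-of-bag $R^2$,
loci with $R^2 \le 0$ are dropped, loci are combined with weights
$R^2_\ell / \sum R^2_\ell$, and the result is normalized so total
cumulative importance across predictors is 1. The per-predictor curves
$F_p$ are monotone step functions; `predict()` evaluates them
right-continuously and clamps outside the fitted range. Differences
from the reference algorithm: conditional permutation importance is
simplified to impurity-decrease importance, and split importance is
binned wholly at the threshold without density standardization — the
resulting monotone turnover object is the same, and the simplification
is deterministic and testable. Defaults: 500 trees per locus; with a
single predictor and a step-function response the curve is a single
step at the true threshold, and with a linear response it approaches a
linear ramp.

Offsets live in the transformed space $T(e) = (F_1(e_1), \dots,
F_P(e_P))$:

* local: $\lVert T(e^{\mathrm{cur}}_g) - T(e^{\mathrm{fut}}_g)\rVert_2$
  per grid cell;
* forward: $\min_{g:\ d(i,g) \le d_{\max}} \lVert T(e^{\mathrm{cur}}_i)
  - T(e^{\mathrm{fut}}_g)\rVert_2$ per population, for caps
  $d_{\max} \in \{100, 250, 500, 1000, \infty\}$ km (haversine, Earth
  radius 6371.0088 km); smaller caps can only raise the minimum, so
  forward offsets are monotone in the cap;
* reverse: $\min_i \lVert T(e^{\mathrm{fut}}_g) -
  T(e^{\mathrm{cur}}_i)\rVert_2$ per cell.

Offsets are averaged across climate models (their cross-model Pearson
correlations are reported) and the averaged local/forward/reverse
channels are min–max scaled to $[0, 255]$ (rounding half away from
zero; a constant channel maps to 0) for the RGB composite.

## IBD, IBE and variance partitioning

Genetic distance is Rousset-linearized pairwise Weir–Cockerham
$\theta/(1-\theta)$, with negative pairwise $\theta$ clamped to zero
before linearization only (never inside the F\_ST result itself);
multi-locus $\theta$ uses the ratio-of-sums convention
$\sum a / \sum(a+b+c)$. `mantel_test()` correlates strictly-lower-
triangle entries and permutes population labels jointly
(one-sided upper-tail p over 999 permutations by default — the
association hypothesis). `partial_mantel()` residualizes both
lower-triangle vectors on the control matrix by least squares and
permutes the raw labels of the first matrix before residualization
(the residual method; the permutation choice is recorded in the
result). `partial_rda_partition()` computes the Ezekiel-adjusted
$R^2$ of the seven nested least-squares models over climate, geography
(lon/lat) and structure proxies and decomposes it by
inclusion–exclusion; individual fractions may be slightly negative and
always sum exactly to the full-model adjusted $R^2$. The structure
proxies are population scores on the first three PCs of the
LD-pruned dosage matrix; when partitioning the variance of *candidate*
loci, candidates are excluded from the PCA so that "structure" means
the neutral background rather than the clines being partitioned.

## Genetic load

Derived alleles are counted relative to the annotated ancestral state
(ALT where ancestral is REF and vice versa). The default
`allele_count` mode sums derived dosages — robust to sample size and
invariant to duplicating individuals; `segregating_variant` mode
counts variants carrying the derived allele at least once, since the
field convention ("number of derived mutations") is ambiguous between
the two. Ratios are formed against the synonymous count per
population. SV burden is each individual's het-SV / het-SNP ratio
averaged within populations; individuals without a heterozygous SNP
are excluded with a warning rather than dividing by zero. Correlations
with offsets use Spearman's rank correlation with average ranks and
the two-sided t approximation.

## The synthetic landscape

`simulate_landscape()` generates the full input set plus truth tables.
Its defaults are the study conditions of the package's validation
suite:

* 24 populations of 10 individuals placed uniformly in a
  12° × 13° box, split into a northern and a southern ancestry group
  at the median latitude;
* neutral loci: ancestral frequency Uniform(0.1, 0.9), then a
  hierarchical Balding–Nichols model — group level $F = 0.007$,
  population level $F = 0.015$ — calibrated so the genome-wide
  Weir–Cockerham $\theta$ comes out near 0.02, the weak
  differentiation typical of wide-ranging wind-pollinated trees.
  The latitudinal group split makes isolation by distance emerge
  (between-group pairs are both farther and more differentiated);
* 19 environmental variables built from latitude/longitude trends
  plus smooth cosine-basis random fields (length scale 1.8°, so the
  surfaces have genuine local texture rather than being affine in the
  coordinates) organized in four latent families — two dominant
  "syndromes" (temperature-like and precipitation-like) carrying the
  six causal-eligible variables, two minor ones. Family fields are
  made exactly orthogonal over the sampled sites to one another and
  to the coordinate trends and the north/south step (fixed linear
  combinations of fields, hence still smooth functions evaluable on
  any grid). Within-family correlations are ~0.85–0.99 and
  cross-family ~0, mirroring how real bioclim variables form tightly
  correlated blocks; non-leading variables carry larger own-field
  noise, making them weaker proxies of their syndrome;
* adaptive loci: $\mathrm{logit}(p) = \alpha + \beta\, z(e_c) +
  \mathcal N(0, 0.2)$ with $|\beta| \sim$ Uniform(0.5, 1.5), causal
  variables among the first six, allocated unevenly
  (30/20/15/10/15/10%) — adaptive variants cluster on a few dominant
  climate axes, as they do in real panels where precipitation
  variables dominate;
* genotypes Binomial(2, p) with 2% missingness; variant classes 84%
  SNP / 14% indel / 2% SV; functional classes with probabilities
  0.25/0.10/0.05/0.02/0.58 for synonymous/tolerated/deleterious/LOF/
  noncoding; ancestral allele = REF throughout (no ancestral-state
  inference is simulated);
* future climates: per model and scenario,
  $e_{\mathrm{fut}} = e_{\mathrm{cur}} + s_{\mathrm{scenario}}\,
  \delta_{m}(x)$ where $\delta_m$ is 70% a shared smooth anomaly
  field plus 30% model-specific, and $s_{\mathrm{SSP370}} = 1.2 >
  s_{\mathrm{SSP126}} = 0.6$ is hard-wired so the qualitative
  higher-emissions-larger-offset ordering is testable. The four model
  names follow common CMIP6 global circulation models.

Everything is deterministic given the seed, including file output
(byte-identical reruns). What the generator does **not** emulate:
linkage disequilibrium (loci are independent, so LD pruning is
exercised but removes almost nothing), recombination and demographic
history, selection dynamics through time, genotype-quality artifacts
(inputs are assumed pre-filtered; frequencies use observed alleles
with no imputation), and the real covariance of the 19 BIOCLIM
variables. Passing tests on this landscape therefore demonstrate that
the estimators recover the structures they model — clines, turnover,
differentiation, load gradients — not that any particular real
dataset would yield the same power.

## Numerical choices and degenerate inputs

* MAF > 10% is a strict inequality; a variant at exactly the
  threshold is dropped.
* Missing dosages: frequencies and F\_ST use observed-allele counts;
  PCA, the latent-factor scan and the RDA mean-impute per variant;
  all-missing population cells are `NA` and downstream operations
  tolerate them.
* SVD sign indeterminacy is fixed by making each axis's
  largest-magnitude site score positive; axis-score orthogonality is
  exact to numerical precision.
* Pairwise $\theta = 1$ linearizes to a large sentinel ($10^6$) with
  a warning; sites with non-positive F\_ST denominators are skipped.
* Permutation p-values are $(1 + \#\{\cdot\})/(1 + n_{\mathrm{perm}})$
  and live on the $k/(n_{\mathrm{perm}}+1)$ lattice, never zero.
* Tree bootstrap and predictor subspaces derive from the model seed;
  refitting with the same seed is bit-identical.
* An empty reachable set under a dispersal cap yields `NA` with a
  warning; constant RGB channels map to 0.

## Problem sizes used in validation

The test suite exercises the default landscape (24 × 10 individuals,
5100 loci, 500-tree turnover model, a 12 × 12 offset grid) once and
shares it across checks; module tests run on smaller simulated
instances (around 12 populations and a few hundred loci) and on
closed-form constructions. Permutation-heavy checks use 999
permutations for single tests and 99 for the 500-replicate type-I
error studies. These sizes were chosen to give stable statistical
behavior while keeping a full validation run in the minutes range on
one core.

## Known limitations

* The latent-factor scan is the deterministic least-squares analogue
  of the Bayesian MCMC formulation; it targets the same estimand but
  will not reproduce MCMC-averaged p-values.
* RDA loading scaling (correlation vs eigenvalue-scaled species
  scores) differs between implementations by a per-axis constant; the
  SD-based cutoff absorbs it, but raw loading magnitudes are not
  comparable across packages.
* The turnover model omits density standardization of split
  importance, so cumulative-importance curves are comparable within a
  fit, not numerically identical to other gradient-forest
  implementations.
* Windowed genome statistics (per-window F\_ST, diversity) are out of
  scope: the synthetic landscape has no linkage structure that would
  make windows meaningful.
* Nucleotide diversity requires the caller to supply the callable
  site count; with only variant sites in the denominator the values
  are per-variant-site, not per-genomic-site.
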