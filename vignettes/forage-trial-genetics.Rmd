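---
title: "Quantitative genetics of multi-environment forage trials with forageQG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetics of multi-environment forage trials with forageQG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(forageQG)
```

forageQG analyses balanced randomized complete block design (RCBD) breeding
trials evaluated across years and irrigation regimes, the standard layout
for screening drought tolerance in forage grasses. The package is modelled
on a 100-ecotype Kentucky bluegrass (*Poa pratensis*) trial — 2 blocks,
2 years, a well-watered control and a 50% deficit-irrigation treatment,
seven traits spanning forage yield (FY, DY) and leaf photosynthesis (A,
g~s~, T~r~, Chl, Fv/Fm) — whose published per-environment summary ships
with the package (`bluegrass_summary()`). The raw plot data of that trial
were never released in machine-readable form, so the package pairs every
estimator with a seeded synthetic-trial generator and validates the whole
pipeline by parameter recovery.

## The observation model

Within one year × regime environment the plot value of genotype $i$ in
block $j$ is modelled additively,

$$y_{ij} = \mu + g_i + b_j + \varepsilon_{ij},$$

with genotype effects of variance $\sigma_g^2$ and residuals of variance
$\sigma_e^2$. The balanced two-way ANOVA gives the expected mean squares

$$E(MS_g) = \sigma_e^2 + r\,\sigma_g^2, \qquad E(MS_e) = \sigma_e^2,$$

which `variance_components()` inverts:
$\hat\sigma_g^2 = (MS_g - MS_e)/r$, $\hat\sigma_e^2 = MS_e$, and
$\hat\sigma_p^2 = \hat\sigma_g^2 + \hat\sigma_e^2$. A negative
method-of-moments $\hat\sigma_g^2$ is truncated to zero and flagged
(`negative_truncated`), never silently.

The derived statistics follow the standard selection-theory chain:

* $PCV = 100\,\sigma_p/\mu$ and $GCV = 100\,\sigma_g/\mu$
  (`coefficients_of_variation()`), with the conventional
  low/moderate/high bands at 10% and 20% (`classify_cv()`);
* broad-sense heritability $h^2 = 100\,\sigma_g^2/\sigma_p^2$
  (`heritability()`), identically $100\,(GCV/PCV)^2$ — an identity the
  test suite asserts to $10^{-12}$;
* genetic advance under truncation selection
  $GA = k\,\sigma_p\,h^2/100$ (`genetic_advance()`), with $k = 2.063$, the
  standardized selection differential for keeping the top 5%;
* $GAM = 100\,GA/\mu$ (`genetic_advance_percent()`), the response scaled
  by the trait mean for cross-trait comparison.

**Why $\sigma_p$ in GA.** A form of the genetic-advance formula that
multiplies $k$ by the *error* standard deviation circulates in parts of
the literature. It is not consistent with the selection-theory derivation
($GA = k\,h^2\,\sigma_p$ is the selection differential regressed onto the
genotypic scale), and it does not reproduce the published GA values in
`bluegrass_summary()` — reconstructing FY 2018 non-stress from its printed
mean, PCV and $h^2$ gives 251.5 with the phenotypic SD (printed: 251.19,
0.13% apart) versus roughly 40% off with the error SD. forageQG therefore
uses the phenotypic SD by default and exposes the other variant as
`sd_scale = "error"` for cross-checking against sources that used it.

**Percent reduction.** Drought losses are reported as
$100\,(\bar y_{ctl} - \bar y_{str})/\bar y_{str}$ by default: this
stress-denominator convention is what reproduces the published integer
loss percentages (FY 43% and 46%, DY 24% and 29%) from the published
means. The more common control-denominator form is available via
`denominator = "control"`.

## Combined ANOVA across environments

`combined_anova()` decomposes the full 2-year × 2-regime layout into
irrigation regime (Ir), replicates within regime (Error I), genotype (G),
Ir × G, replicate × genotype within regime (Error II), year (Y), Y × Ir,
Y × G, Y × G × Ir, and a pooled Residual, with blocks nested in regime.
For the reference design (g = 100, r = 2) the df are
(1, 2, 99, 99, 198, 1, 1, 99, 99, 200), summing to 799.

F-test denominators in a split-plot-in-time layout are not uniquely
determined by the sums of squares. The package adopts the conventional
scheme — Ir against Error I, G and Ir × G against Error II, the
year-containing terms against the Residual — records it in the result
object (`f_test_convention`), and prints it alongside the table. Variance
components for the genetic summary are always taken from the
per-environment RCBD tables (one per year × regime), because the summary
statistics are reported per environment; the combined table is
descriptive.

## Genotypic correlations from mean cross-products

`cross_product_components()` extends the mean-square decomposition to
pairs of traits: genotype and error mean cross-products are extracted
from multivariate least-squares fits of the same RCBD layout, and
covariance components follow the same moment equations,
$Cov_g = (MCP_g - MCP_e)/r$, $Cov_p = Cov_g + MCP_e$. Diagonals reproduce
the univariate components exactly. `correlation_matrices()` normalizes to
$r_p$ and $r_g$; genotypic correlations are ratios of moment estimates
and can exceed 1 in absolute value — such entries are flagged
(`abs_gt1`), retained in the numbers, and clamped only for plotting.

Reporting one matrix per irrigation regime requires a pooling rule across
years; forageQG averages the per-year covariance *components* within the
regime before normalizing (`trait_correlations()`), which weights both
years equally and keeps the pooled matrix a valid component average. A
per-year option (`pool_years = FALSE`) is provided.

## Stepwise yield–photosynthesis regression

`stepwise_regression()` implements the classic
forward-with-backward-elimination procedure on least squares: at each step
the candidate with the largest partial F enters if $p <$ `alpha_enter`
(default 0.15, the historical stepwise convention), and entered variables
whose partial $p >$ `alpha_stay` (default 0.15) are removed, worst first.
R's built-in `step()` is AIC-based and does not produce the partial-F /
partial-$R^2$ accounting of the classic procedure, so this is implemented
directly. The invariants the suite enforces: cumulative $R^2$ equals the
$R^2$ of a direct fit on the entered set ($10^{-10}$), partial $R^2$
telescopes as $\Delta R^2$, and the procedure terminates. Near-collinear
candidates (rank-deficient augmented design) are skipped with a warning.
Observations are genotype means per regime with years pooled
(`genotype_means()`), matching the one-model-per-regime reporting layout;
per-year fitting is available through the `years` argument.

## Trait-profile clustering

`cluster_accessions()` z-scores each trait column (traits are on wildly
different scales — g/plot vs mol m⁻² s⁻¹ — so unscaled distances would be
dominated by yield), computes Manhattan distances, and agglomerates with
the ward.D2 criterion. Groups at the requested cut (default 3) are
relabelled so group I has the highest mean standardized profile,
matching the usual "group I = high performers" reading of trial heatmaps.
Merge order is validated against an exhaustive Lance–Williams oracle in
the tests. `save_cluster_heatmap()` renders the two-way heatmap via
pheatmap.

## The synthetic-trial generator

`generate_trial()` draws from the additive Gaussian model

$$y_{tymrij} = \mu_t + s_{tm} + Y_{ty} + g_{ti} + (gY)_{tyi} + (gR)_{tmi}
  + b_{ymj} + \varepsilon,$$

with genotype main effects drawn jointly across traits from a
multivariate normal whose correlation matrix is the true genetic
correlation; all other effects are independent across traits. Generation
is deterministic under the spec seed and leaves the caller's RNG state
untouched.

`paper_trial_spec()` pins the defaults to the reference study conditions:

* design 100 × 2 blocks × 2 years × 2 regimes, seven traits;
* per-trait $\mu$, $\sigma_g^2$, $\sigma_e^2$ back-solved from the
  published 2018 non-stress mean, GCV and PCV;
* drought shifts equal to the published control−stress mean gaps, so the
  generated FY loss is ~43% by the stress-denominator convention;
* year-effect SD set to a quarter of the published 2018→2019 mean jump —
  large enough that year swings of the reported magnitude sit within
  2 SD, small enough that simulated yield means stay strictly positive
  (at half the jump, negative drought-year yield means become plausible,
  which field yields cannot be);
* G × year and G × regime variances at 25% of $\sigma_g^2$ — the
  interactions are strongly significant in the reference trial but their
  components are not separately published, so a moderate common fraction
  is used;
* block variance at a quarter of the error variance;
* a genetic correlation matrix anchored at the published genotypic
  correlations (FY–DY 0.91, g~s~–T~r~ 0.75, g~s~–Chl 0.77, A–Fv/Fm 0.88,
  T~r~–Fv/Fm 0.66) and completed to a positive-definite matrix
  (smallest eigenvalue ≈ 0.09).

What the generator does *not* emulate: spatial field trends within
blocks, non-Gaussian traits (e.g. the bounded Fv/Fm ratio), block effects
shared across traits, heteroscedasticity between regimes, and missing
plots. Passing recovery tests therefore demonstrate estimator correctness
under the additive Gaussian model — the model the ANOVA itself assumes —
not robustness to field pathologies.

`recovery_experiment()` reruns the estimation pipeline over seeded
replicates and compares Monte-Carlo means with the truths the spec
implies. Within a single year × regime subset the G × year and G × regime
draws are confounded with the genotype main effect, so the comparison
truths are the *effective* per-environment values,
$\sigma_g^2 + \sigma_{g\times y}^2 + \sigma_{g\times r}^2$, with the
genotypic correlation attenuated by the uncorrelated interaction
variance.

## Numerical choices and edge cases

* Negative $\hat\sigma_g^2$: truncated to 0, flagged; under a true null
  this happens with frequency ≈ 1/2 (asserted in the suite).
* Zero phenotypic variance: heritability is refused (domain error)
  rather than returned as 0/0.
* Zero-variance traits in correlation work: excluded with a warning.
* $|r_g| > 1$: retained and flagged; clamped only in plots.
* Unbalanced tables: load with a warning listing missing design cells;
  every ANOVA entry point refuses unbalanced subsets (the estimators'
  moment equations assume balance).
* Phenotype round-trips: values are serialized at 17 significant digits
  and re-parsed with R's correctly rounded reader, so written tables
  reload bit-exactly.
* Clustering ties (duplicate accessions): resolved by `stats::hclust`;
  duplicated rows merge first at height 0.

## Validation problem sizes

The test suite validates: exact oracle equivalence of all sums of squares
and cross-products on ≤ 5-genotype layouts ($10^{-9}$); null behaviour of
$MS_g - MS_e$ and of the genotypic covariance over 500 seeded replicates;
recovery of $h^2$ (truth 80%), GCV (truth 20%) and $r_g$ (truth 0.95)
over 500 replicates at the reference design size g = 100, r = 2;
convergence of simulated genotype-effect variance at g = 2000 (within
5%); and end-to-end pipeline determinism under a fixed seed.

## Known limitations

* The moment estimator of $h^2$ is a ratio and carries a small
  finite-sample bias: at g = 100, r = 2 and a true $h^2$ of 80%, its
  exact expectation (computed from the chi-square sampling distributions
  of the mean squares) is 79.71, a bias of −0.29 points. Monte-Carlo
  recovery runs long enough to resolve three-tenths of a point will show
  it. The bias shrinks as $O(1/g)$ and is immaterial at the precision
  summary tables are reported to.
* No REML or mixed-model machinery: unbalanced data are rejected, not
  down-weighted, and there is no narrow-sense heritability, BLUP, or
  family structure.
* The combined-ANOVA F-test denominators are a documented convention
  (above), not an inference the data can settle.
* The standard error conventionally attached to published heritability
  values has no universally agreed formula and is not computed.
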