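---
title: "The vegbench benchmark model: assumptions, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vegbench benchmark model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package estimates

A biodiversity *benchmark* is a target value of a site-condition metric
against which observed sites are scored, for example in offset or restoration
schemes. Rather than an undisturbed historical baseline, vegbench estimates
*best-on-offer* reference states: upper quantiles of the contemporary
distribution of native species richness and summed percent cover, for six
plant growth forms (ferns, forbs, grasses and grass-like plants, shrubs,
trees, and species not otherwise classified), conditional on vegetation
class, bioregion, season, and recent rainfall, and standardized to 0%
nonnative cover.

The data are full floristic inventories of fixed-area (400 m²) plots. Every
native taxon is assigned to one growth form; per-survey responses are the
count of distinct native species per growth form (richness) and the sum of
per-species visually estimated percent covers (cover). Summed cover can
exceed 100% because foliage overlaps; that is a property of the measurement,
not an error. Nonnative cover is summed across all growth forms and used as
a covariate.

## The model

Let $\mathbf{y}_i$ (richness) or $\mathbf{z}_i$ (cover) be the 6-vector
response of survey $i$. The observation models are

$$\mathbf{y}_i \sim \text{Poisson}(\boldsymbol\lambda_i)
\qquad\text{or}\qquad
\log(\mathbf{z}_i + 0.001) \sim \text{Normal}(\log \boldsymbol\lambda_i,
\boldsymbol\sigma),$$

with survey-level multivariate-normal overdispersion on the log rates,

$$\log \boldsymbol\lambda_i \sim \text{MVN}(\boldsymbol\mu_i, \Sigma),
\qquad \Sigma = \text{diag}(\boldsymbol\sigma_s)\,\Phi\,
\text{diag}(\boldsymbol\sigma_s),$$

which induces extra-Poisson variance and residual correlation among growth
forms. The 0.001 offset makes zero cover finite on the log scale (a Box-Cox
transform with exponent 0 and shift 0.001); benchmark predictions are
back-transformed as $\exp(\cdot) - 0.001$, floored at zero.

The linear predictor has two variants. The *dynamic* form gives each
bioregion its own smooth seasonal trajectory:

$$\boldsymbol\mu_i = \boldsymbol\alpha + \boldsymbol\beta_{v(i)} +
\boldsymbol\gamma_{m(i),b(i)} + r_i \boldsymbol\delta_{b(i)} +
e_i \boldsymbol\epsilon + \boldsymbol\zeta_{y(i)} + \boldsymbol\eta_{p(i)},$$

where $v$ indexes vegetation class, $m$ month, $b$ bioregion, $y$ year and
$p$ plot; $r_i$ is standardized 12-month antecedent rainfall and $e_i$
standardized nonnative cover. The *static* form replaces
$\boldsymbol\gamma_{m,b}$ with additive bioregion and month intercepts
$\boldsymbol\gamma_b + \boldsymbol\kappa_m$ (regionally consistent
seasonality; far fewer parameters, more robust where plots are sparse).

Priors: class deviations are nested in formations
($\beta_v \sim N(\theta_{f(v)}, \sigma_v)$, $\theta_f \sim N(0, \sigma_f)$);
bioregion rainfall slopes share a grand mean
($\delta_b \sim N(\iota, \sigma_r)$, $\iota \sim N(0, 10)$);
$\epsilon \sim N(0, 10)$; year and plot effects are exchangeable normals. In
the dynamic variant the monthly effects follow a first-order random walk
that starts in July (the austral mid-winter, a natural low point for
phenology), steps through August to May, and ties June to the mean of May
and July so the cycle closes smoothly. All scale parameters are
6-dimensional with half-normal(0, 2) priors. The correlation matrix $\Phi$
has an LKJ prior with density proportional to $|\Phi|^a$ and $a = 4$,
which concentrates prior mass toward small residual correlations. All
normal distributions are parameterized by their standard deviation
throughout.

Two conventions deserve note. First, the intercept $\boldsymbol\alpha$
carries an improper flat prior (no prior statement is made for it); the
data identify it in any non-degenerate fit, and the synthetic-data
generator fixes it from the scenario rather than drawing it. Second, the
cover observation sd $\boldsymbol\sigma$ is given the same half-normal(0, 2)
prior as the other scale vectors.

## Benchmarks

Benchmarks are marginal posterior quantiles (55th, 65th, 75th by default,
representing lower through higher reference states) of the expected
response for a *new* plot in an *average* year: the cell's
$\boldsymbol\mu$ omits the year and plot deviations, includes the
MVN$(0, \Sigma)$ overdispersion draw, and excludes observation noise. The
rationale: benchmarks describe attainable site states, so site-to-site
heterogeneity (overdispersion) belongs in the distribution while
single-survey sampling noise and transient year effects do not. All four
inclusion flags are exposed because this marginalization is a modelling
judgement, not a mathematical necessity. Marginal (per growth form)
quantiles are used deliberately: a joint 6-dimensional quantile cannot be
summarized as one number per growth form.

*Static* benchmarks are one value per bioregion x class at that cell's
average (50th-quantile) rainfall, with the month intercept set to zero (an
average month). *Dynamic* benchmarks are emitted per month at three
rainfall levels — the 10th, 50th and 90th quantiles of historical 12-month
accumulations for that cell ("below average", "average", "above average").
Nonnative cover is fixed at a raw 0% and mapped through the stored
covariate scaling (not set to a standardized zero — raw zero is generally
not the sample mean). Richness benchmarks are reported as real numbers
(quantiles of a latent rate); consumers may round.

Vegetation classes never observed in a bioregion are still assigned
benchmarks by drawing the class deviation from the posterior of its
formation mean $\theta_f$; such rows are flagged `extrapolated`. Rainfall
levels for unobserved bioregion x class combinations are imputed by three
separate additive linear regressions (one per quantile) on bioregion and
class; because the three regressions are independent, an imputed triple can
invert, in which case it is re-sorted and logged.

## Rainfall handling

The rainfall covariate is the accumulated total over the 12 calendar months
before the survey: a half-open window from the same calendar date one year
earlier up to, but excluding, the survey day (so the window length is 365
or 366 days depending on whether it spans 29 February). Historical levels
anchor the same window at the first day of the survey month for each year
of record and take empirical quantiles with linear order-statistic
interpolation (R type 7; no interpolation rule is canonical here, type 7 is
R's default and changes nothing at the reported precision). 3- and 36-month
windows are available through the `months` argument but are not used in
modelling; they are strongly correlated with the 12-month total.
Grid-to-point interpolation of gridded rainfall products is out of scope:
the package consumes per-location daily series.

## Computation

The posterior is sampled by a No-U-Turn sampler written for this model:
compiled (RcppArmadillo) joint log-density with hand-derived reverse-mode
gradients, dual-averaging step-size adaptation, and windowed estimation of
a Euclidean metric. Two implementation choices matter:

* **Non-centered parameterization** everywhere: hierarchical deviations and
  the overdispersion are sampled as standard-normal innovations scaled
  inside the density, and $\Phi$ is sampled through tanh-transformed
  canonical partial correlations mapped to its Cholesky factor. The
  posterior is identical; the geometry is far better.
* **Dense metric over the population-level subspace.** The flat intercept
  plus several exchangeable mean structures make the posterior extremely
  collinear among intercepts, hierarchical means and scales (conditional
  standard deviations 50-100 times smaller than marginal ones), which
  throttles any diagonal-metric sampler. The sampler therefore estimates a
  dense covariance for the population-level coordinates (a few hundred) and
  a diagonal one for the per-plot and per-survey latent fields, shrinking
  the dense estimate toward its diagonal in short adaptation windows.

Chains run sequentially and all randomness flows from R's RNG, so a seed
fixes the draws exactly (given the same build of the package). The
reference sampler configuration is 4 chains of 5,000 iterations after 5,000
warmup; the package default is 4 x 1,000 + 1,000, which suits the
desk-scale synthetic datasets used throughout the tests. Convergence is
gated on split-Rhat < 1.01 and effective sample size, computed in-package
(split-chain Rhat; Geyer initial-monotone-sequence ESS).

Divergent transitions are counted and reported in the fit metadata; a
post-warmup divergence fraction above 2% triggers a warning. The tests and
acceptance runs use `adapt_delta = 0.9` for the convergence-gate fit.

## The synthetic-data generator

No plot archive ships with the package; every analysis is exercised on
synthetic data drawn from the model itself. A scenario fixes the study
conditions: by default 5 vegetation classes in 2 formations, 3 bioregions,
5 years, and 500 plots surveyed twice (1,000 surveys) across all 12 months;
per-bioregion mean annual rainfall spans a 400-900 mm gradient with 20%
relative sd; nonnative cover is zero for 60% of surveys and exponential
with mean 10% otherwise (the source archive records 0% minimum nonnative
cover in most bioregion-class combinations, so a zero-inflated covariate is
the realistic shape). True intercepts and covariate effects default to the
published state-wide estimates for the six growth forms (mean richness
1, 6, 5, 1, 6, 2; rainfall multipliers 1.19, 1.20, 1.16, 1.24, 1.16, 1.05;
nonnative multipliers 0.95, 0.99, 0.98, 0.96, 0.88, 0.96 — and the
corresponding cover values), so simulated magnitudes match real
floristic data. Hierarchical scales are fixed by the scenario at
field-plausible values (class 0.4, formation 0.3, bioregion 0.2, month
0.15, rainfall 0.1, year 0.15, plot 0.3, residual 0.3, cover observation
0.7, all on the log scale); the remaining fields are drawn from their
priors, with $\Phi$ from the LKJ distribution via the partial-correlation
vine construction.

What the generator deliberately does **not** emulate: realistic
species-abundance distributions (pseudo-species are generated
deterministically as `sp_<growthform>_<k>`), taxonomic synonymy, spatial
autocorrelation within bioregions, observer effects, or
phenology beyond the model's month terms. Passing tests therefore
demonstrate statistical correctness of the machinery — parameter recovery,
calibration, benchmark arithmetic — on data that satisfy the model's
assumptions, not robustness to the violations real archives contain.

For convergence-gate and recovery runs the package's tests use designs with
4 surveys per plot (72 plots x 4 surveys over 6 bioregions for the
convergence check; 250 plots x 4 surveys, 8 classes in 4 formations, for
parameter recovery). Variance components need several groups to be
estimable at all, so the convergence-check design uses 6 bioregions rather
than the bare minimum of 3.
Separating the plot variance from the residual overdispersion requires
within-plot replication; with single-visit designs the two are confounded
and their posteriors mix slowly at any sample size. Problem sizes in the
test-suite fits (hundreds to a thousand surveys, 1,200-2,600 sampler
iterations) were chosen as the smallest designs that identify every
variance component. The recovery replicates re-use the adapted mass matrix
of the first replicate (a warm start re-tunes only the step size; the
posterior is untouched).

## Numerical details and edge cases

* Covariates are standardized with the population (n-denominator) sd, so a
  two-point covariate standardizes to exactly ±1; the scaling is stored and
  reused at prediction time (e.g. the standardized image of raw 0%).
  Standardization is global, not per bioregion.
* Duplicate species entries within a survey (multi-stratum records) count
  once for richness and sum for cover.
* The random-walk sd of the dynamic variant (`sigma_rw`, one 6-vector per
  bioregion) is a distinct parameter from the static variant's bioregion
  scale, though both carry half-normal(0, 2) priors.
* Empirical benchmark quantiles refuse samples below a configurable floor
  (100 draws).
* Ordinal Braun-Blanquet cover classes convert through a pluggable
  label-to-percent table (default: conventional class midpoints). Fitted
  conversion models from reference data can be substituted by supplying a
  different table.
* `effect_multiplier()` converts log-scale slopes to multiplicative factors
  and percent changes per 1 sd of the covariate, matching how effects are
  reported.

## Known limitations

* The sampler is validated on desk-scale problems (hundreds to thousands of
  surveys). The full-archive scale (tens of thousands of plots, 95 classes,
  18 bioregions) is expected to work but has not been run here.
* Single-visit-dominated designs leave plot and overdispersion variance
  weakly identified (slow mixing, wide posteriors); this is a property of
  the model, not the sampler.
* Benchmark uncertainty is not itself reported (only point quantiles);
  posterior intervals for the quantiles could be added by resampling draws.
* The elicitation comparison implements only the arithmetic (band overlap,
  midpoint differences); the elicitation protocol itself is external.
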