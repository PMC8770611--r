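---
title: "Methods: the trait-environment occurrence model and its estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the trait-environment occurrence model and its estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitenv)
```

## The scientific question and the model

Functional traits — specific leaf area (SLA), seed mass (SM), stem wood
density (SD), maximum height (MH) — summarize ecological strategies,
and topography — elevation, slope, aspect — structures the microclimate
plants actually experience. `traitenv` models how the traits *modulate*
species' occurrence responses to the topographic gradients. For species
$j$ at plot $i$,

$$
\mathrm{logit}(p_{ij}) \;=\; \alpha + a_j
  + (\boldsymbol\beta_1 + \mathbf{b}_j)^\top \mathbf{X}_i
  + \boldsymbol\beta_{12}^\top (\mathbf{X}_i \otimes \mathbf{Z}_j)
  + c_i ,
\qquad y_{ij} \sim \mathrm{Bernoulli}(p_{ij}).
$$

The trait-environment associations $\boldsymbol\beta_{12}$ (4 traits
$\times$ 3 environments = 12 terms) are the quantities of interest: a
nonzero element means species with larger values of that trait respond
more positively (or negatively) to that gradient. Traits enter **only**
through these interactions — deliberately not as main effects — so a
trait can shift *where* a species does well but not inflate its
occurrence everywhere. Species-level random intercepts and slopes
$(a_j, \mathbf{b}_j) \sim N(\mathbf{0}, \Sigma)$ (with $\Sigma$ a full
$4\times 4$ covariance) absorb the response variation traits do not
explain, and a plot-level intercept $c_i \sim N(0, \sigma^2_{site})$
absorbs plot nonindependence.

Key assumptions: occurrences are conditionally independent Bernoulli
draws given the random effects; species responses are linear on the
logit scale in the standardized covariates; trait values are fixed,
species-level constants (no intraspecific variation); and the species
pool is exchangeable given the traits (no phylogenetic correlation
structure).

## Preprocessing conventions

All covariates pass through `build_design()`:

* **Aspect folding.** A compass aspect in $[0, 360)$ carries no linear
  information (0 and 360 are the same direction). It is folded to a
  south-north orientation score: values $\le 180$ unchanged, values
  above 180 mapped to $(360 - x)$, so 0 = north-facing and 180 =
  south-facing, with east and west collapsed. Inputs of exactly 360 are
  treated as 0; anything outside $[0, 360]$ is an error naming the
  offending plot.
* **Log transforms.** Every other covariate is natural-log transformed
  (raw distributions in such data are strongly right-skewed; seed mass
  spans four orders of magnitude). A slope of exactly 0° is physically
  plausible, so zeros are handled by an explicit, recorded offset: half
  the smallest positive observed value. The offset and the log flag are
  stored in the standardization record, making every transform exactly
  invertible; a `"none"` policy that errors on zeros is available.
* **Two-SD scaling.** Each column is centred and divided by twice its
  sample SD (the $n-1$ denominator), so standardized columns have SD
  0.5. On this scale coefficients of continuous predictors are
  comparable with each other (and with binary predictors), and the
  intercept is the logit prevalence of an average species at average
  conditions.
* **Standardization population.** Traits are standardized over the
  modelled species; environments over the plots entering the fitted
  dataset, so each grid-sample replicate re-standardizes on its own 150
  plots. The model's "mean environmental conditions" are therefore
  relative to the dataset actually fitted, and every fit carries its
  `StandardizationRecord`s so raw-scale statements (e.g. the trait
  value at which a response crosses zero) remain available through
  `invert_standardization()` and `response_zero_crossing()`.

The fixed-effect design is the intercept, the 3 environment main
effects, and the 12 interactions in a fixed, documented order (traits
SLA, SM, SD, MH crossed with elevation, slope, aspect, trait-major) —
16 terms, which is also the reporting order.

## Spatial subsampling

One-hectare plot sets of one hundred contiguous 10 m plots would
dominate the likelihood and induce spatial autocorrelation. The
sampler thins each set with a 3 × 3 grid and draws 3 plots per cell
without replacement, then unions the draws with all scattered plots:
27 × 3 + 69 = 150 plots per replicate. Because 10 is not divisible by
3, rows and columns are partitioned into contiguous 4/3/3 bands (cell
sizes 16, 12, 12, 12, 9, 9, 12, 9, 9); the partition is a design
choice, fixed and tested. Replicate $r$ derives its seed as
`base_seed + r`, and all seeds are recorded in the outputs, so every
replicate is exactly reproducible. The first replicate is reported in
detail and the cross-replicate min-max ranges alongside, which is how
the aggregate coefficient table should be read.

Whether the thinning sufficed is checked, not assumed: `morans_i()`
computes Moran's I on per-plot mean Pearson residuals (population-level
predictions; deviance residuals are available) with inverse-distance,
row-standardized weights (k-nearest-neighbour binary weights as an
alternative), and a seeded permutation test, one-sided for positive
autocorrelation by default — the direction the design guards against.
The residual definition and the weights are the two genuinely open
choices here; both defaults are recorded in the output's `weight_spec`.

## Estimation

The fit is an approximate Bayesian maximum-posterior (MAP) estimate
with weakly informative priors:

* $N(0, 1)$ independently on every fixed effect;
* inverse-Wishart with $df = 8$ and scale matrix $2 I_4$ on $\Sigma$.
  "Diagonal scale with value 2" is read as the scale matrix (not its
  inverse); the prior mode $\Psi/(df + p + 1) = 2I/13$ is pinned by a
  unit test with zero observations;
* inverse-gamma(shape 0.5, scale 100) on the **site variance**
  $\sigma^2_{site}$ (density $\propto x^{-1.5} e^{-100/x}$). This prior
  is deliberately heavy-tailed and pushes the site variance up when
  data are scarce; with 150 plots the likelihood dominates, but the
  fitted site SD sits somewhat above the generating value in
  simulation, which is visible in the recovery study and expected
  under this prior. Both hyperparameters are configurable in
  `te_priors()`.

Random effects (124 species coordinates + 150 site intercepts in the
default geometry) are integrated out by a **Laplace approximation** at
their joint conditional mode. The inner problem is strictly concave
and solved by damped Newton; the Newton system is factorized through
the Schur complement of the diagonal site block, so the cost is driven
by the species coordinates. The outer optimizer is L-BFGS-B over the
16 fixed effects, the log-Cholesky factor of $\Sigma$ (10 parameters)
and $\log \sigma_{site}$, with box bounds keeping SDs in roughly
$[0.02, 50]$ for conditioning. The gradient of the Laplace objective
is computed analytically in C++ — the envelope term, the direct
log-determinant term, and the implicit mode-shift term involving the
third derivative of the logistic log-likelihood — and is validated
against central finite differences in the test suite. Convergence is
declared at a projected-gradient norm below `pgtol = 1e-5` (the
relative-reduction factor is set small so the gradient criterion is
the operative one); non-convergence returns a fit flagged
`converged = FALSE` with diagnostics rather than an error. Warm starts
for the inner mode are accepted only when they beat the zero start and
are re-solved cold whenever the Newton search stalls, so a stale start
can never corrupt an evaluation.

Standard errors come from the curvature of the approximated log
posterior in the fixed effects at the optimum, holding the variance
parameters at their estimates — the convention of the penalized
mixed-model family this fitter belongs to — and p-values are two-sided
Wald $z$ tests with no degrees-of-freedom correction. Significance
stars use strict thresholds 0.05/0.01/0.001. The latent-scale
conditional $R^2$ is
$(\sigma^2_f + \sigma^2_r)/(\sigma^2_f + \sigma^2_r + \pi^2/3)$, with
$\sigma^2_f$ the variance of the fixed-effect linear predictor over
the fitted cells and $\sigma^2_r$ the sum of the five variance
components; the distribution-specific $\pi^2/3$ is the logistic
residual variance. Summing the variance components treats the
random-slope variances at the standardized-covariate scale
(SD 0.5) as exchangeable with the intercept variances; this is the
recorded choice, and the function is deliberately small so an
alternative weighting can be computed from the fit object directly.

### Accuracy of the Laplace approximation

On instances small enough for exact integration the package's marginal
posterior is compared against adaptive quadrature in the test suite.
The relative error of the Laplace value is far below 1% when
per-species information is moderate or the random-effect variance is
small, but it grows with the variance-to-information ratio: on a
4-observation species integral it reaches roughly 1–3% at a variance
of 2, depending on the response pattern. This is the intrinsic
skewness error of a Gaussian approximation to a Bernoulli-logit
integrand, not an implementation artifact (the same comparison at
variance $\le 1$ passes well under 1%, and the error vanishes as the
variance shrinks). At the analysis' actual geometry — 150 plots and 31
species, species variances around 0.2–1 — the approximation error is
negligible relative to sampling noise, which the parameter-recovery
study confirms end to end.

## The synthetic community generator

`make_scenario()` fixes everything the generator needs; the defaults
are the study conditions: 3 one-hectare sets of one hundred 10 m plots
plus 69 scattered plots, elevations 200–1000 m, 31 species, trait
ranges SLA 5.60–45.05, seed mass 0.10–9259 mg, wood density 0.35–0.85,
maximum height 5–30 m, true fixed effects at the reference
coefficients and random-effect SDs (site 1.32; species intercept 1.01;
elevation 0.70; slope 0.40; aspect 0.42).

Choices where a distribution had to be invented, made once and
recorded here:

* **Topography.** Each set sits on a smooth hillside: a linear
  elevation gradient in a random downhill direction (0.25–0.55 m/m,
  i.e. slopes of roughly 14–29°) plus low-frequency sinusoidal relief;
  slope is derived from the gradient with noise, aspect from the
  downhill bearing with noise. Scattered plots draw elevation
  uniformly over the full range. This creates genuine environmental
  contrast between and within sets, which the sampling design needs.
* **Traits.** Log-uniform within the scenario ranges with the
  endpoints pinned (one species takes each extreme), so fixture
  extremes match the printed ranges exactly — e.g. the 6-fold
  tallest/shortest height ratio. This is a fixture policy, not an
  estimate of a real community's trait distribution.
* **Random effects.** Species effects are drawn independent
  (correlations 0) by default because no off-diagonal information is
  available; a full correlation matrix can be supplied.

What the generator does **not** emulate: dispersal limitation or any
spatial point process in the occurrences (space enters only through
the covariates and the site effect), phylogenetic signal, trait-trait
correlations, intraspecific trait variation, or DEM-derived
covariate error. Passing recovery tests therefore demonstrate that the
estimator recovers the parameters of *this* data-generating process at
the study's dimensions — they do not certify behaviour under model
misspecifications a real forest would add.

## Evaluation metrics

* **AUROC** is rank-based with mid-rank tie handling (the normalized
  Mann-Whitney statistic). "AUROC across all species" is ambiguous
  between pooling all plot-species cells and averaging per-species
  values; `evaluate_fit()` reports both, with pooled as the headline.
* **AUPRC** uses the interpolation-free average-precision summation
  over distinct score thresholds; trapezoidal interpolation in PR
  space overestimates the area and is avoided. Under this convention a
  constant-score classifier scores exactly the species' prevalence,
  which is also the AUPRC of a random classifier — hence
  AUPRC/prevalence reads as "how many times better than random", and
  is reported per species with its mean and min-max range.
* Species observed in no plot (or every plot) of a dataset are
  retained in the fit — the priors regularize them — but flagged, and
  excluded from per-species metrics that are undefined for them.

## Problem sizes in the tests

The suite fits real models at the full study geometry (150 × 31): the
parameter-recovery check runs 200 independent communities, asserting
every fixed-effect mean within 3 Monte-Carlo SEs of truth and ≥ 90%
coverage of the 95% Wald intervals for the interaction terms; the
quadrature comparisons run at 2 species × 4 plots where exact
integration is feasible; metric null checks use $10^4$ cells and a few
hundred permutation simulations. The acceptance script runs the
10-replicate pipeline at full size plus a 40-replicate recovery study.

## Known limitations

* MAP estimation summarizes the posterior by its mode and curvature;
  there is no full posterior sampling, model comparison, or
  cross-validation (all metrics are in-sample, matching the analysis
  design).
* The Laplace error quantified above means marginal-posterior *values*
  on very small species (few informative plots, large variance) are
  approximate at the percent level; coefficient estimates are much
  less sensitive, as the MAP-vs-quadrature test shows (agreement to
  $10^{-3}$).
* The inverse-gamma(0.5, 100) site prior biases the site SD upward at
  these sample sizes; users who want a near-flat alternative can set
  `site_scale` smaller in `te_priors()`.
* Raw-scale trait thresholds require the standardization records of
  the fitted dataset; without them only standardized-scale statements
  are possible.
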