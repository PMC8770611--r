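# traitenv

Hierarchical trait-environment modelling of woody-species occurrence
along topographic gradients.

`traitenv` is for community ecologists asking *which functional traits
modulate where species occur*. Given per-plot topography (elevation,
slope, aspect), per-species functional traits (specific leaf area SLA,
seed mass SM, stem wood density SD, maximum height MH), and a binary
plot-by-species occurrence table, it fits a hierarchical Bayesian
logistic model in which traits act on occurrence *indirectly*, by
modulating each species' response to the environmental gradients. The
package also ships the surrounding analysis machinery: the
preprocessing conventions, a spatial grid-subsampling design with
Moran's I residual diagnostics, precision-recall evaluation against a
prevalence baseline, a synthetic community generator for parameter
recovery experiments, and a pipeline that ties the stages together.

## The model

For species *j* = 1…m at plot *i* = 1…n,

```
logit(p_ij) = α + a_j + (β₁ + b_j)ᵀ X_i + β₁₂ᵀ (X_i ⊗ Z_j) + c_i
y_ij ~ Bernoulli(p_ij)
```

where `X_i` holds the three standardized topographic variables and
`Z_j` the four standardized traits. `α` is the community-wide
prevalence on the logit scale at mean traits and mean environment; `β₁`
(length 3) is the average environmental response; `β₁₂` (length 12 = 4
traits × 3 environments) holds the trait-environment associations — how
a trait shifts a species' response to a gradient. `(a_j, b_j) ~ N(0,
Σ)` are species-level random intercepts and environmental slopes
(Σ is 4×4), and `c_i ~ N(0, σ²_site)` absorbs plot-level
nonindependence. Traits enter only through the interactions, not as
main effects: a trait cannot change a species' occurrence everywhere,
only its response to where it is.

Estimation is approximate Bayesian maximum posterior: weakly
informative priors — normal(0, 1) on each fixed effect,
inverse-Wishart(df = 8, scale 2·I₄) on Σ, inverse-gamma(0.5, 100) on
σ²_site — and random effects integrated out by a Laplace approximation
at their joint conditional mode. The inner Newton solver and the
analytic gradient of the Laplace objective are implemented in
C++ (RcppArmadillo); the outer quasi-Newton optimizer works on the 16
fixed effects, the log-Cholesky factor of Σ, and log σ_site.

Preprocessing follows the conventions such models assume: aspect is
folded to a 0–180° south–north orientation score (0 = north-facing),
every other covariate is natural-log transformed (with a recorded
offset policy for zeros), and all covariates are centred and divided by
**twice** their SD, so coefficients are comparable across continuous
predictors and the intercept reads as prevalence at average conditions.

## Worked example

Simulate a community under the default scenario (3 one-hectare sets of
one hundred 10 m × 10 m plots plus 69 scattered plots, 31 species,
elevations 200–1000 m), thin the plot sets with the 3 × 3 grid
subsampling, and fit the model to the first replicate:

```r
library(traitenv)

scenario   <- make_scenario(seed = 42)
community  <- simulate_community(scenario)

replicates <- generate_replicates(community$plots, n_replicates = 10,
                                  base_seed = 42)
plots_r1 <- community$plots[match(
  replicates$plot_id[replicates$replicate_id == 1],
  community$plots$plot_id), ]

design <- build_design(plots_r1, community$traits)
design
#> <te_design> 150 plots x 31 species; 16 fixed-effect terms (12 trait-environment interactions)

fit <- fit_trait_env(community$occurrence, design)
tidy(fit)
#> # A tibble: 16 × 5
#>    term           estimate std.error statistic  p.value
#>    <chr>             <dbl>     <dbl>     <dbl>    <dbl>
#>  1 Intercept       -1.95       0.224   -8.71   2.94e-18
#>  2 Elevation        0.118      0.324    0.364  7.16e- 1
#>  3 Slope            0.239      0.313    0.765  4.44e- 1
#>  4 Aspect           0.542      0.313    1.73   8.32e- 2
#>  5 SLA: Elevation   0.309      0.323    0.958  3.38e- 1
#>  ⋮
#> 12 SD: Slope       -0.653      0.273   -2.39   1.68e- 2
#> 16 MH: Aspect       0.0797     0.239    0.333  7.39e- 1
```

The intercept (−1.95, so an average species occupies
`plogis(-1.95) ≈ 12%` of plots at mean conditions) and one interaction
(SD: Slope) come out significant in this draw; single 150-plot
replicates are noisy, which is exactly why the pipeline averages over
ten of them. Random-effect spread and overall fit:

```r
tidy(fit, effects = "ran_pars")
#> 1 Site (Intercept)       1.73
#> 2 Species (Intercept)    0.958
#> 3 Species (Elevation)    0.660
#> 4 Species (Slope)        0.610
#> 5 Species (Aspect)       0.362

glance(fit)
#>   log_posterior converged grad_norm conditional_r2 n_sites m_species
#> 1        -2006. TRUE       9.50e-6           0.602     150        31
```

Evaluation against the prevalence baseline and the spatial diagnostic:

```r
metrics <- evaluate_fit(fit)
round(c(pooled_auroc = metrics$pooled_auroc,
        ratio_mean   = metrics$ratio_summary$mean), 3)
#> pooled_auroc   ratio_mean
#>        0.867        3.814

morans_i(plot_residuals(fit), plots_r1[, c("x", "y")], seed = 42)[, 1:3]
#>         I expected_I p_value
#> 1 0.00412   -0.00671   0.212
```

A pooled AUROC of 0.867 and per-species AUPRC averaging 3.8 times the
random-classifier baseline say the model discriminates well in-sample;
Moran's I on per-plot residuals is indistinguishable from its null
expectation −1/(N−1), so the grid subsampling did its job. Where an
interaction is strong, `response_zero_crossing()` converts it into a
threshold trait value (on the raw scale via the stored standardization
records) at which the mean environmental response changes sign, and
`trait_response_profile()` / `autoplot()` draw the centred response
lines with their species points.

The whole analysis — simulate or ingest CSVs, subsample, fit each
replicate, evaluate, aggregate coefficient ranges, render a report —
runs from one call:

```r
run <- run_pipeline(pipeline_config(scenario = scenario,
                                    n_replicates = 10, base_seed = 42,
                                    out_dir = "runs/demo"))
write_report(run$dir)
```

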