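#' Tidy the fixed or random effects of a fitted occurrence model
#'
#' @param x A `te_fit` object.
#' @param effects `"fixed"` for the 16 fixed-effect rows (coefficient,
#'   SE, Wald z and two-sided p), or `"ran_pars"` for the random-effect
#'   SD rows (site intercept; species intercept and environmental
#'   slopes).
#' @param ... Unused.
#' @return A tibble in reporting order.
#' @export
tidy.te_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") {
    x$fixed %>%
      rename(std.error = "std_error", p.value = "p_value")
  } else {
    x$random_sd %>% rename(estimate = "sd") %>%
      mutate(effect = "ran_pars", .before = 1)
  }
}

#' One-row summary of a fitted occurrence model
#'
#' @param x A `te_fit` object.
#' @param ... Unused.
#' @return A tibble with the log posterior at the mode, convergence flag,
#'   outer gradient norm, latent-scale conditional R-squared, and the
#'   data dimensions.
#' @export
glance.te_fit <- function(x, ...) {
  tibble(
    log_posterior = x$log_posterior,
    converged = x$converged,
    grad_norm = x$grad_norm,
    conditional_r2 = conditional_r2(x),
    n_sites = x$n_sites,
    m_species = x$m_species
  )
}

#' Significance stars at the conventional thresholds
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05 (strict
#' inequalities; p = 0.05 gets no star), empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    .default = ""
  )
}

#' Fixed-effect summary table with significance stars
#'
#' The reporting table of the analysis: one row per fixed effect in the
#' documented order (intercept, the 3 environment main effects, then the
#' 12 trait-environment interactions), with coefficient, SE, two-sided
#' Wald p-value and significance stars.
#'
#' @param fit A `te_fit` object.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`, `signif`.
#' @export
summarize_fixed_effects <- function(fit) {
  stopifnot(inherits(fit, "te_fit"))
  tidy(fit) %>% mutate(signif = significance_stars(.data$p.value))
}

#' Latent-scale conditional R-squared
#'
#' Variance explained by fixed plus random effects on the logit scale:
#' `(v_f + v_r) / (v_f + v_r + pi^2 / 3)`, where `v_f` is the variance of
#' the fixed-effect linear predictor over the fitted plot x species cells,
#' `v_r` is the sum of the model's variance components (site variance
#' plus the species intercept and slope variances), and `pi^2 / 3` is the
#' logistic distribution-specific residual variance.
#'
#' @param fit A `te_fit` object.
#' @return Scalar in `[0, 1]`.
#' @export
conditional_r2 <- function(fit) {
  stopifnot(inherits(fit, "te_fit"))
  eta_fixed <- linear_predictor(
    fit$fixed_list,
    as.matrix(fit$design$X[, -1]),
    as.matrix(fit$design$Z[, -1])
  )
  v_f <- stats::var(as.vector(eta_fixed))
  v_r <- sum(diag(fit$Sigma)) +
    (if (fit$re_site) fit$sigma_site^2 else 0)
  (v_f + v_r) / (v_f + v_r + pi^2 / 3)
}

#' Trait-modulated environmental response profile
#'
#' For one trait x environment pair, the centred response line
#' `beta12[t, e] * z` over a grid of standardized trait values `z` (the
#' value at the community-mean trait, z = 0, is 0 by construction), with
#' a 95% band from the coefficient's SE, plus the per-species estimated
#' responses to that environment (`beta1[e] + b_j[e]`, centred across
#' species) positioned at each species' standardized trait value.
#'
#' @param fit A converged `te_fit`.
#' @param trait One of `"sla"`, `"seed_mass"`, `"wood_density"`,
#'   `"max_height"` (or a label such as `"MH"`).
#' @param environment One of `"elevation"`, `"slope"`, `"aspect"`.
#' @param grid Standardized trait values for the line (default: 101
#'   points spanning the observed standardized trait range).
#' @param level Confidence level for the band.
#' @return An object of class `te_profile`: a list with tibbles `line`
#'   (`z`, `response`, `lower`, `upper`) and `species` (`species_id`,
#'   `trait_value`, `response`), plus the coefficient and its SE.
#' @export
trait_response_profile <- function(fit, trait, environment, grid = NULL,
                                   level = 0.95) {
  stopifnot(inherits(fit, "te_fit"))
  trait <- resolve_name(trait, te_traits(), te_trait_labels(), "trait")
  environment <- resolve_name(environment, te_environments(),
                              te_env_labels(), "environment")
  ii <- fit$design$interactions
  row <- which(ii$trait == trait & ii$environment == environment)
  if (length(row) != 1) abort("Unknown trait/environment pair.")
  term <- ii$term[row]
  est <- fit$fixed$estimate[match(term, fit$fixed$term)]
  se <- fit$fixed$std_error[match(term, fit$fixed$term)]
  zcrit <- qnorm(1 - (1 - level) / 2)

  zt <- fit$design$Z[[trait]]
  if (is.null(grid)) grid <- seq(min(zt), max(zt), length.out = 101)
  line <- tibble(
    z = grid,
    response = est * grid,
    lower = est * grid - zcrit * abs(grid) * se,
    upper = est * grid + zcrit * abs(grid) * se
  )
  e_idx <- match(environment, te_environments())
  resp_sp <- fit$fixed_list$beta1[e_idx] + fit$random_modes_list$b[, e_idx]
  species <- tibble(
    species_id = fit$design$Z$species_id,
    trait_value = zt,
    response = resp_sp - mean(resp_sp)
  )
  structure(
    list(line = line, species = species, trait = trait,
         environment = environment, term = term, coefficient = est,
         se = se, level = level),
    class = "te_profile"
  )
}

resolve_name <- function(x, canonical, labels, what) {
  if (x %in% canonical) return(x)
  hit <- names(labels)[match(tolower(x), tolower(labels))]
  if (!is.na(hit)) return(hit)
  abort(paste0("Unknown ", what, ": '", x, "'. Expected one of ",
               paste(canonical, collapse = ", "), "."))
}

#' Standardized trait value where the mean environmental response is zero
#'
#' The uncentred species-mean response to environment e at standardized
#' trait z is `beta1[e] + beta12[t, e] * z`; it crosses zero at
#' `z* = -beta1[e] / beta12[t, e]`. With the stored standardization
#' records the crossing can be expressed on the raw trait scale, which is
#' how thresholds such as a maximum height beyond which the elevation
#' response turns negative are read off.
#'
#' @inheritParams trait_response_profile
#' @param scale `"standardized"` or `"raw"` (back-transformed through the
#'   trait's standardization record).
#' @return Scalar crossing point (`NA` if the interaction coefficient is
#'   zero).
#' @export
response_zero_crossing <- function(fit, trait, environment,
                                   scale = c("standardized", "raw")) {
  scale <- match.arg(scale)
  stopifnot(inherits(fit, "te_fit"))
  trait <- resolve_name(trait, te_traits(), te_trait_labels(), "trait")
  environment <- resolve_name(environment, te_environments(),
                              te_env_labels(), "environment")
  e_idx <- match(environment, te_environments())
  t_idx <- match(trait, te_traits())
  b1 <- fit$fixed_list$beta1[e_idx]
  b12 <- fit$fixed_list$B[e_idx, t_idx]
  if (b12 == 0) return(NA_real_)
  zstar <- -b1 / b12
  if (scale == "standardized") return(zstar)
  rec <- fit$design$records %>% filter(.data$name == trait)
  invert_standardization(zstar, rec)
}
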