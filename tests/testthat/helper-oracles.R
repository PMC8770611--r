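# Shared fixtures and independent oracles for the test suite.

# local seeded evaluation (tests do not need RNG-state restoration)
with_seed <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# A te_design built directly from standardized matrices, bypassing
# build_design, for reduced-dimension model tests (e.g. 1 environment x
# 1 trait).
manual_design <- function(X, Z, plot_ids = NULL, species_ids = NULL) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (is.null(plot_ids)) plot_ids <- paste0("p", seq_len(nrow(X)))
  if (is.null(species_ids)) species_ids <- paste0("s", seq_len(nrow(Z)))
  if (is.null(colnames(X))) colnames(X) <- paste0("env", seq_len(ncol(X)))
  if (is.null(colnames(Z))) colnames(Z) <- paste0("tr", seq_len(ncol(Z)))
  ii <- interaction_index(colnames(Z), colnames(X))
  structure(list(
    X = tibble::as_tibble(cbind(data.frame(plot_id = plot_ids), X)),
    Z = tibble::as_tibble(cbind(data.frame(species_id = species_ids), Z)),
    records = NULL,
    interactions = ii,
    terms = c("Intercept", colnames(X), ii$term)
  ), class = "te_design")
}

# Independent 1-D inverse-Wishart log density (p = 1, scale psi): used by
# the quadrature oracles; coded from the density formula, not from package
# internals.
oracle_log_iw1 <- function(v, df, psi) {
  0.5 * df * log(psi) - 0.5 * df * log(2) - lgamma(df / 2) -
    0.5 * (df + 2) * log(v) - 0.5 * psi / v
}

# Exact (adaptive quadrature) marginal log posterior for an intercept-only
# species random effect, no site effect. `eta0` is the fixed linear
# predictor (n x m); integrates each species' intercept on (-15, 15).
oracle_quad_marginal <- function(eta0, Y, v, fixed_par, fixed_sd = 1,
                                 iw_df = 8, iw_scale = 2) {
  ll <- 0
  for (j in seq_len(ncol(Y))) {
    f <- function(a) {
      sapply(a, function(ai) {
        exp(sum(Y[, j] * (eta0[, j] + ai) - log1p(exp(eta0[, j] + ai))) +
              dnorm(ai, 0, sqrt(v), log = TRUE))
      })
    }
    ll <- ll + log(integrate(f, -15, 15, rel.tol = 1e-12)$value)
  }
  ll + sum(dnorm(fixed_par, 0, fixed_sd, log = TRUE)) +
    oracle_log_iw1(v, iw_df, iw_scale)
}

# A small but complete te_fit-shaped object with controllable components,
# for summary/profile/aggregation tests that do not need a real
# optimization.
fake_fit <- function(estimates, std_errors = rep(0.1, length(estimates)),
                     Sigma = diag(0.25, 4), sigma_site = 0.5,
                     Z = NULL, b = NULL, design = NULL) {
  if (is.null(design)) {
    ii <- interaction_index()
    Zt <- if (is.null(Z)) {
      tibble::tibble(species_id = paste0("s", 1:3),
                     sla = c(-0.5, 0, 0.5), seed_mass = c(-0.5, 0, 0.5),
                     wood_density = c(-0.5, 0, 0.5),
                     max_height = c(-0.5, 0, 0.5))
    } else Z
    design <- structure(list(
      X = tibble::tibble(plot_id = paste0("p", 1:4),
                         elevation = c(-0.5, -0.2, 0.2, 0.5),
                         slope = c(0.1, -0.1, 0.3, -0.3),
                         aspect = c(-0.4, 0.4, -0.1, 0.1)),
      Z = Zt,
      records = tibble::tibble(
        name = c("elevation", "slope", "aspect", te_traits()),
        log_applied = c(TRUE, TRUE, FALSE, rep(TRUE, 4)),
        offset = 0,
        center = c(6, 2, 90, 2.5, 2, -0.6, 2.7),
        scale = c(0.8, 1.2, 90, 1.1, 4, 0.3, 0.9)
      ),
      interactions = ii,
      terms = c("Intercept", unname(c(elevation = "Elevation",
                                      slope = "Slope", aspect = "Aspect")),
                ii$term)
    ), class = "te_design")
  }
  m <- nrow(design$Z)
  zv <- estimates / std_errors
  fx <- te_fixed(alpha = estimates[1], beta1 = estimates[2:4],
                 beta12 = estimates[5:16])
  structure(list(
    fixed = tibble::tibble(
      term = design$terms, estimate = estimates, std_error = std_errors,
      statistic = zv, p_value = 2 * pnorm(-abs(zv))
    ),
    fixed_list = fx,
    Sigma = Sigma,
    sigma_site = sigma_site,
    random_sd = tibble::tibble(
      term = c("Site (Intercept)", "Species (Intercept)",
               "Species (Elevation)", "Species (Slope)",
               "Species (Aspect)"),
      sd = c(sigma_site, sqrt(diag(Sigma)))
    ),
    random_modes_list = list(
      a = rep(0, m),
      b = if (is.null(b)) matrix(0, m, 3) else b,
      c = rep(0, nrow(design$X))
    ),
    log_posterior = -1, converged = TRUE, grad_norm = 0,
    n_sites = nrow(design$X), m_species = m,
    re_species_slopes = TRUE, re_site = TRUE,
    design = design
  ), class = "te_fit")
}

# Deterministic tiny fitted model shared by summary-level tests (cached per
# session to keep the suite fast).
tiny_fit_cache <- new.env(parent = emptyenv())
tiny_real_fit <- function() {
  if (is.null(tiny_fit_cache$fit)) {
    sc <- make_scenario(m_species = 8, n_sets = 1, n_scattered = 30,
                        seed = 21)
    dat <- simulate_community(sc)
    plots <- dat$plots[dat$plots$set_id == "scattered", ]
    des <- build_design(plots, dat$traits)
    tiny_fit_cache$fit <- fit_trait_env(dat$occurrence, des)
  }
  tiny_fit_cache$fit
}
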