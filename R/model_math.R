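#' Fixed-effect and random-effect containers
#'
#' `te_fixed()` bundles the 16 fixed effects of the occurrence model: the
#' intercept `alpha` (overall prevalence on the logit scale), `beta1`
#' (average response to each environmental variable at mean trait values)
#' and `beta12` (the trait-environment associations, one per trait x
#' environment pair in the order of [interaction_index()]).
#'
#' @param alpha Scalar intercept (logit scale).
#' @param beta1 Numeric vector of environment main effects (length 3 for
#'   elevation, slope, aspect).
#' @param beta12 Numeric vector of interaction coefficients, trait-major
#'   (length `length(traits) * length(beta1)`), or a matrix with one row
#'   per environment and one column per trait.
#' @param n_env,n_traits Dimensions used to validate/recycle inputs.
#' @return A list with elements `alpha`, `beta1`, `beta12` (vector) and
#'   `B` (environment x trait matrix).
#' @export
te_fixed <- function(alpha = 0, beta1 = NULL, beta12 = NULL,
                     n_env = 3, n_traits = 4) {
  if (is.null(beta1)) beta1 <- rep(0, n_env)
  n_env <- length(beta1)
  if (is.null(beta12)) beta12 <- rep(0, n_env * n_traits)
  if (is.matrix(beta12)) {
    stopifnot(nrow(beta12) == n_env)
    n_traits <- ncol(beta12)
    B <- beta12
    beta12 <- as.vector(B) # column-major = trait-major for env x trait
  } else {
    if (length(beta12) %% n_env != 0) {
      abort("`beta12` length must be a multiple of the number of environments.")
    }
    n_traits <- length(beta12) / n_env
    B <- matrix(beta12, nrow = n_env, ncol = n_traits)
  }
  list(alpha = alpha, beta1 = beta1, beta12 = beta12, B = B)
}

#' Linear predictor of the trait-environment occurrence model
#'
#' Computes, on the logit scale, the probability surface
#' `alpha + a_j + (beta1 + b_j) . X_i + beta12 . (X_i x Z_j) + c_i`
#' for every plot i and species j, where the interaction term sums
#' `beta12` over all trait-environment pairs. `X` and `Z` are assumed
#' standardized as by [build_design()].
#'
#' @param fixed A fixed-effect bundle from [te_fixed()].
#' @param X Numeric matrix (or data frame) of plots x environments.
#' @param Z Numeric matrix (or data frame) of species x traits.
#' @param random Optional list with `a` (species intercept deviations,
#'   length m), `b` (m x n_env species slope deviations), `c` (site
#'   intercept deviations, length n); missing components are zero.
#' @return An n x m matrix of logits.
#' @examples
#' fx <- te_fixed(alpha = -2.23)
#' linear_predictor(fx, X = matrix(0, 1, 3), Z = matrix(0, 1, 4))
#' @export
linear_predictor <- function(fixed, X, Z, random = NULL) {
  X <- as.matrix(X)
  Z <- as.matrix(Z)
  n <- nrow(X); m <- nrow(Z)
  if (ncol(X) != length(fixed$beta1)) {
    abort("Dimension mismatch: ncol(X) != length(beta1).")
  }
  if (ncol(Z) != ncol(fixed$B)) {
    abort("Dimension mismatch: ncol(Z) != number of traits in beta12.")
  }
  a <- if (!is.null(random$a)) random$a else rep(0, m)
  b <- if (!is.null(random$b)) as.matrix(random$b) else matrix(0, m, ncol(X))
  cc <- if (!is.null(random$c)) random$c else rep(0, n)
  if (length(a) != m || nrow(b) != m || ncol(b) != ncol(X) || length(cc) != n) {
    abort("Dimension mismatch in random-effect components.")
  }
  eta <- matrix(fixed$alpha, n, m)
  eta <- eta + drop(X %*% fixed$beta1) + X %*% fixed$B %*% t(Z)
  eta <- eta + X %*% t(b)
  eta <- eta + matrix(a, n, m, byrow = TRUE) + cc
  eta
}

# log inverse-Wishart density with scale matrix Psi, up to nothing (all
# constants included)
dinvwishart_log <- function(Sigma, df, Psi) {
  p <- nrow(Sigma)
  lmvg <- 0.25 * p * (p - 1) * log(pi) +
    sum(lgamma(df / 2 + (1 - seq_len(p)) / 2))
  ldPsi <- determinant(Psi, logarithm = TRUE)$modulus
  ldSig <- determinant(Sigma, logarithm = TRUE)$modulus
  as.numeric(
    0.5 * df * ldPsi - 0.5 * df * p * log(2) - lmvg -
      0.5 * (df + p + 1) * ldSig - 0.5 * sum(diag(solve(Sigma, Psi)))
  )
}

dinvgamma_log <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

#' Joint log posterior of the occurrence model
#'
#' The un-marginalized posterior density: the Bernoulli-logit log
#' likelihood over all plot x species cells, the Gaussian log densities of
#' the species and site random effects given their variance components,
#' and the log prior densities (normal on fixed effects, inverse-Wishart
#' on the species covariance, inverse-gamma on the site variance). All
#' normalizing constants are included, so values are comparable across
#' variance components.
#'
#' @inheritParams linear_predictor
#' @param Y Binary n x m occurrence matrix (may have zero rows for a
#'   data-free prior evaluation).
#' @param variance Optional list with `Sigma` (species random-effect
#'   covariance; its order is intercept then environment slopes) and
#'   `sigma_site` (site SD). When `NULL` the random-effect and
#'   covariance-prior terms are omitted (a fixed-effects-only model).
#' @param priors A [te_priors()] specification.
#' @return Scalar log posterior density.
#' @export
log_posterior <- function(fixed, X, Z, Y, random = NULL, variance = NULL,
                          priors = te_priors()) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  n <- nrow(X); m <- nrow(Z)
  lp <- 0
  if (n > 0 && m > 0) {
    Y <- as.matrix(Y)
    stopifnot(nrow(Y) == n, ncol(Y) == m, all(Y %in% c(0, 1)))
    eta <- linear_predictor(fixed, X, Z, random)
    # numerically safe softplus for large |eta|
    sp <- ifelse(eta > 35, eta, log1p(exp(eta)))
    ll <- sum(Y * eta - sp)
    if (!is.finite(ll)) abort("Non-finite likelihood term in log_posterior.")
    lp <- lp + ll
  }
  if (!is.null(variance)) {
    Sigma <- as.matrix(variance$Sigma)
    s <- nrow(Sigma)
    U <- cbind(
      if (!is.null(random$a)) random$a else rep(0, m),
      if (s > 1) {
        if (!is.null(random$b)) as.matrix(random$b) else matrix(0, m, s - 1)
      }
    )
    Sinv <- solve(Sigma)
    ldSig <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
    re_sp <- -0.5 * sum((U %*% Sinv) * U) - 0.5 * m * ldSig -
      0.5 * m * s * log(2 * pi)
    if (!is.finite(re_sp)) abort("Non-finite species random-effect term.")
    lp <- lp + re_sp
    lp <- lp + dinvwishart_log(Sigma, priors$species_cov_df,
                               diag(priors$species_cov_scale, s))
    if (!is.null(variance$sigma_site)) {
      cc <- if (!is.null(random$c)) random$c else rep(0, n)
      s2 <- variance$sigma_site^2
      re_site <- -0.5 * sum(cc^2) / s2 - 0.5 * n * log(2 * pi * s2)
      if (!is.finite(re_site)) abort("Non-finite site random-effect term.")
      lp <- lp + re_site +
        dinvgamma_log(s2, priors$site_shape, priors$site_scale)
    }
  }
  theta <- c(fixed$alpha, fixed$beta1, fixed$beta12)
  lp <- lp + sum(dnorm(theta, 0, priors$fixed_sd, log = TRUE))
  if (!is.finite(lp)) abort("Non-finite prior term in log_posterior.")
  lp
}

#' Occurrence probability from the fitted model
#'
#' Inverse-logit of the linear predictor. With `include_random = FALSE`
#' only the fixed effects are used (a population-level prediction for a
#' species with the given traits at the given conditions).
#'
#' @param fit A `te_fit` object.
#' @param X,Z Standardized environment and trait matrices; default to the
#'   fitted design (in-sample prediction).
#' @param include_random Use the estimated random-effect modes? Only
#'   available for in-sample prediction (the modes belong to the fitted
#'   plots and species).
#' @return An n x m matrix of probabilities in (0, 1).
#' @export
predict_probability <- function(fit, X = NULL, Z = NULL,
                                include_random = FALSE) {
  stopifnot(inherits(fit, "te_fit"))
  insample <- is.null(X) && is.null(Z)
  if (include_random && !insample) {
    abort("Random-effect modes apply only to the fitted plots and species.")
  }
  if (is.null(X)) X <- as.matrix(fit$design$X[, -1])
  if (is.null(Z)) Z <- as.matrix(fit$design$Z[, -1])
  random <- if (include_random) fit$random_modes_list else NULL
  stats::plogis(linear_predictor(fit$fixed_list, X, Z, random))
}

#' Evaluate the Laplace-approximated marginal log posterior
#'
#' The quantity [fit_trait_env()] maximizes, evaluated at user-supplied
#' fixed effects and variance components: Bernoulli-logit likelihood with
#' the species (and optionally site) random effects integrated out by a
#' Laplace approximation at their joint conditional mode, plus the
#' [te_priors()] log densities. Useful for profiling, diagnostics, and
#' for checking the approximation against direct numerical integration on
#' small instances.
#'
#' @inheritParams linear_predictor
#' @param Y Binary n x m occurrence matrix.
#' @param Sigma Species random-effect covariance; a 1 x 1 matrix gives an
#'   intercept-only species effect, a (1 + n_env) square matrix adds
#'   environmental slopes (order: intercept, then environments).
#' @param sigma_site Site-intercept SD, or `NULL` to omit site effects.
#' @param priors A [te_priors()] specification.
#' @param control A [te_control()] specification (inner Newton settings).
#' @return A list with `value` (the marginal log posterior), `mode` (the
#'   random-effect mode), `logdet_H`, and `converged`.
#' @export
log_marginal_posterior <- function(fixed, X, Z, Y, Sigma,
                                   sigma_site = NULL,
                                   priors = te_priors(),
                                   control = te_control()) {
  X <- as.matrix(X); Z <- as.matrix(Z); Y <- as.matrix(Y)
  Sigma <- as.matrix(Sigma)
  s <- nrow(Sigma)
  n_env <- ncol(X)
  if (!s %in% c(1L, 1L + n_env)) {
    abort("Sigma must be 1 x 1 or (1 + n_env) x (1 + n_env).")
  }
  Lc <- t(chol(Sigma))
  theta <- numeric(0)
  for (col in seq_len(s)) {
    for (row in col:s) {
      theta <- c(theta, if (row == col) log(Lc[row, col]) else Lc[row, col])
    }
  }
  par <- c(fixed$alpha, fixed$beta1, fixed$beta12, theta,
           if (!is.null(sigma_site)) log(sigma_site))
  r <- te_laplace_cpp(
    par, X, Z, Y, s > 1, !is.null(sigma_site),
    priors$species_cov_df, priors$species_cov_scale,
    priors$site_shape, priors$site_scale, priors$fixed_sd,
    numeric(0), control$inner_maxit, control$inner_tol, FALSE
  )
  list(value = r$value, mode = r$mode, logdet_H = r$logdet_H,
       converged = isTRUE(r$inner_ok))
}
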