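#' Prior specification for the occurrence model
#'
#' Weakly informative priors for approximate Bayesian maximum-posterior
#' estimation: an inverse-Wishart prior on the species random-effect
#' covariance (scale matrix `species_cov_scale * I`), an inverse-gamma
#' prior on the site-intercept variance, and independent normal priors on
#' every fixed effect. The defaults are the analysis' reference
#' specification: inverse-Wishart with 8 degrees of freedom and diagonal
#' scale 2 on the 4 x 4 species covariance, inverse-gamma(0.5, 100) on
#' the site variance, and normal(0, 1) on each fixed effect.
#'
#' @param species_cov_df Inverse-Wishart degrees of freedom (must exceed
#'   the species random-effect dimension + 1 for the prior mean to exist).
#' @param species_cov_scale Diagonal value of the inverse-Wishart scale
#'   matrix.
#' @param site_shape,site_scale Shape and scale of the inverse-gamma
#'   prior on the site-intercept variance.
#' @param fixed_sd SD of the zero-mean normal prior on each fixed effect.
#' @return A list of class `te_priors`.
#' @export
te_priors <- function(species_cov_df = 8, species_cov_scale = 2,
                      site_shape = 0.5, site_scale = 100, fixed_sd = 1) {
  stopifnot(species_cov_df > 0, species_cov_scale > 0, site_shape > 0,
            site_scale > 0, fixed_sd > 0)
  structure(
    list(species_cov_df = species_cov_df,
         species_cov_scale = species_cov_scale,
         site_shape = site_shape, site_scale = site_scale,
         fixed_sd = fixed_sd),
    class = "te_priors"
  )
}

#' Optimizer settings for [fit_trait_env()]
#'
#' @param maxit Maximum outer L-BFGS-B iterations.
#' @param pgtol Projected-gradient tolerance of the outer optimizer
#'   (the convergence criterion: iteration stops once the projected
#'   gradient norm falls below it).
#' @param factr Relative-reduction stopping factor of L-BFGS-B; kept
#'   small so that `pgtol` is the operative criterion.
#' @param inner_maxit,inner_tol Newton iteration cap and gradient-norm
#'   tolerance for the inner random-effect mode search.
#' @param se Compute fixed-effect standard errors (finite-difference
#'   curvature of the approximated log posterior at the mode)?
#' @param hessian_step Step size for the SE curvature evaluation.
#' @return A list of class `te_control`.
#' @export
te_control <- function(maxit = 500, pgtol = 1e-5, factr = 10,
                       inner_maxit = 200, inner_tol = 1e-7, se = TRUE,
                       hessian_step = 5e-4) {
  structure(
    list(maxit = maxit, pgtol = pgtol, factr = factr,
         inner_maxit = inner_maxit, inner_tol = inner_tol, se = se,
         hessian_step = hessian_step),
    class = "te_control"
  )
}

#' Coerce an occurrence table to a plot-by-species binary matrix
#'
#' Accepts a wide table (`plot_id` plus one 0/1 column per species), a
#' long table (`plot_id`, `species_id`, `present`), or an already-binary
#' matrix with dimnames, and aligns it to the requested plot and species
#' ordering.
#'
#' @param occurrence Occurrence data in any of the accepted shapes.
#' @param plot_ids,species_ids Orderings to align to.
#' @return Binary matrix with `plot_ids` rows and `species_ids` columns.
#' @export
occurrence_matrix <- function(occurrence, plot_ids, species_ids) {
  if (is.matrix(occurrence)) {
    Y <- occurrence
    if (!is.null(rownames(Y))) Y <- Y[as.character(plot_ids), , drop = FALSE]
    if (!is.null(colnames(Y))) Y <- Y[, as.character(species_ids), drop = FALSE]
  } else {
    occurrence <- as.data.frame(occurrence)
    if (all(c("plot_id", "species_id", "present") %in% names(occurrence))) {
      occurrence <- tidyr::pivot_wider(
        occurrence, id_cols = "plot_id", names_from = "species_id",
        values_from = "present"
      )
    }
    if (!"plot_id" %in% names(occurrence)) {
      abort("Occurrence table must carry a `plot_id` column.")
    }
    missing_p <- setdiff(as.character(plot_ids), as.character(occurrence$plot_id))
    if (length(missing_p)) {
      abort(paste("Occurrence table lacks plot(s):",
                  paste(utils::head(missing_p, 5), collapse = ", ")))
    }
    missing_s <- setdiff(as.character(species_ids), names(occurrence))
    if (length(missing_s)) {
      abort(paste("Occurrence table lacks species column(s):",
                  paste(utils::head(missing_s, 5), collapse = ", ")))
    }
    idx <- match(as.character(plot_ids), as.character(occurrence$plot_id))
    Y <- as.matrix(occurrence[idx, as.character(species_ids), drop = FALSE])
    rownames(Y) <- as.character(plot_ids)
  }
  storage.mode(Y) <- "double"
  if (anyNA(Y) || !all(Y %in% c(0, 1))) {
    abort("Occurrence values must be binary 0/1 with no missing cells.")
  }
  Y
}

# Assemble the outer parameter vector: fixed effects, log-Cholesky of the
# species covariance (column-major lower triangle, log diagonal), and log
# site SD.
te_par_init <- function(n_env, n_traits, s, re_site) {
  nfix <- 1 + n_env + n_env * n_traits
  c(rep(0, nfix), rep(0, s * (s + 1) / 2), if (re_site) 0)
}

te_chol_to_sigma <- function(theta, s) {
  L <- matrix(0, s, s)
  k <- 1
  for (col in seq_len(s)) {
    for (row in col:s) {
      L[row, col] <- if (row == col) exp(theta[k]) else theta[k]
      k <- k + 1
    }
  }
  L %*% t(L)
}

#' Fit the trait-environment occurrence model
#'
#' Maximum-posterior estimation of the hierarchical logistic model
#' `logit(p_ij) = alpha + a_j + (beta1 + b_j) . X_i + beta12 . (X_i x Z_j)
#' + c_i` with species random intercepts and environmental slopes
#' `(a_j, b_j) ~ N(0, Sigma)` and site intercepts `c_i ~ N(0,
#' sigma_site^2)`. The random effects are integrated out by a Laplace
#' approximation at their joint conditional mode (inner damped Newton);
#' the outer quasi-Newton (L-BFGS-B) maximizes the approximated marginal
#' posterior over the 16 fixed effects, the log-Cholesky factor of
#' `Sigma`, and the log site SD, under the [te_priors()] penalties.
#'
#' Species observed in no plot (or in all plots) of a dataset are
#' retained -- the priors regularize them -- but listed in the
#' `flagged_species` field of the result.
#'
#' @param occurrence Occurrence data accepted by [occurrence_matrix()].
#' @param design A `te_design` from [build_design()].
#' @param priors A [te_priors()] specification.
#' @param control A [te_control()] specification.
#' @param re_species_slopes Include species random slopes on the
#'   environments (default) or a species random intercept only?
#' @param re_site Include the site random intercept?
#' @return An object of class `te_fit`; see [tidy.te_fit()],
#'   [glance.te_fit()], [conditional_r2()], [predict_probability()],
#'   [trait_response_profile()].
#' @examples
#' sc <- make_scenario(m_species = 8, seed = 3)
#' dat <- simulate_community(sc)
#' des <- build_design(dat$plots[dat$plots$set_id == "scattered", ],
#'                     dat$traits)
#' \donttest{
#' fit <- fit_trait_env(dat$occurrence, des)
#' tidy(fit)
#' }
#' @export
fit_trait_env <- function(occurrence, design, priors = te_priors(),
                          control = te_control(),
                          re_species_slopes = TRUE, re_site = TRUE) {
  stopifnot(inherits(design, "te_design"))
  X <- as.matrix(design$X[, setdiff(names(design$X), "plot_id")])
  Z <- as.matrix(design$Z[, setdiff(names(design$Z), "species_id")])
  n <- nrow(X); m <- nrow(Z)
  if (n < 2 || m < 2) abort("Need at least 2 plots and 2 species.")
  Y <- occurrence_matrix(occurrence, design$X$plot_id, design$Z$species_id)

  n_env <- ncol(X); n_traits <- ncol(Z)
  s <- if (re_species_slopes) 1 + n_env else 1
  nfix <- 1 + n_env + n_env * n_traits
  ncov <- s * (s + 1) / 2

  state <- new.env(parent = emptyenv())
  state$mode <- numeric(0)
  state$best <- -Inf
  state$best_par <- NULL
  state$grad_par <- NULL
  state$grad <- NULL

  lap <- function(par, grad = FALSE) {
    r <- te_laplace_cpp(
      par, X, Z, Y, re_species_slopes, re_site,
      priors$species_cov_df, priors$species_cov_scale,
      priors$site_shape, priors$site_scale, priors$fixed_sd,
      state$mode, control$inner_maxit, control$inner_tol, grad
    )
    if (isTRUE(r$inner_ok)) {
      state$mode <- r$mode
      if (r$value > state$best) {
        state$best <- r$value
        state$best_par <- par
      }
      if (grad) {
        state$grad_par <- par
        state$grad <- r$gradient
      }
    }
    r
  }
  negobj <- function(par) {
    r <- lap(par)
    if (!isTRUE(r$inner_ok) || !is.finite(r$value)) return(1e10)
    -r$value
  }
  neggrad <- function(par) {
    if (is.null(state$grad_par) || !identical(par, state$grad_par)) {
      r <- lap(par, grad = TRUE)
      if (!isTRUE(r$inner_ok)) return(numeric(length(par)))
    }
    -state$grad
  }

  par0 <- te_par_init(n_env, n_traits, s, re_site)
  npar <- length(par0)
  # fixed effects are shrunk by the normal prior; variance parameters are
  # boxed to SDs in roughly [0.02, 50] to keep the inner problem
  # well-conditioned
  lower <- c(rep(-15, nfix), rep(-4, npar - nfix))
  upper <- c(rep(15, nfix), rep(4, npar - nfix))

  opt <- tryCatch(
    optim(par0, negobj, neggrad, method = "L-BFGS-B",
          lower = lower, upper = upper,
          control = list(maxit = control$maxit, pgtol = control$pgtol,
                         factr = control$factr)),
    error = function(e) NULL
  )
  converged <- !is.null(opt) && opt$convergence == 0
  par_hat <- if (!is.null(state$best_par)) state$best_par else par0

  final <- lap(par_hat, grad = TRUE)
  Sigma <- final$Sigma
  sigma_site <- if (re_site) final$sigma_site else NA_real_
  grad_norm <- if (isTRUE(final$inner_ok)) max(abs(final$gradient)) else Inf

  # SEs: curvature of the approximated log posterior in the fixed effects,
  # holding the variance parameters at their estimates (finite differences
  # of the analytic gradient)
  vcov_fixed <- matrix(NA_real_, nfix, nfix)
  se_ok <- FALSE
  if (isTRUE(control$se)) {
    h <- control$hessian_step
    Hf <- matrix(NA_real_, nfix, nfix)
    for (i in seq_len(nfix)) {
      ei <- replace(numeric(npar), i, h)
      gp <- lap(par_hat + ei, grad = TRUE)$gradient[seq_len(nfix)]
      gm <- lap(par_hat - ei, grad = TRUE)$gradient[seq_len(nfix)]
      Hf[i, ] <- -(gp - gm) / (2 * h)
    }
    Hf <- (Hf + t(Hf)) / 2
    vc <- tryCatch(solve(Hf), error = function(e) NULL)
    if (!is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)) {
      vcov_fixed <- vc
      se_ok <- TRUE
    } else {
      warn("Singular curvature at the mode; standard errors undefined.")
    }
  }

  est_fixed <- par_hat[seq_len(nfix)]
  se_fixed <- if (se_ok) sqrt(diag(vcov_fixed)) else rep(NA_real_, nfix)
  zval <- est_fixed / se_fixed
  fixed <- tibble(
    term = design$terms[seq_len(nfix)],
    estimate = est_fixed,
    std_error = se_fixed,
    statistic = zval,
    p_value = 2 * pnorm(-abs(zval))
  )

  env_labels <- unname(te_env_labels()[colnames(X)])
  env_labels[is.na(env_labels)] <- colnames(X)[is.na(env_labels)]
  sp_sd_names <- c("Species (Intercept)",
                   if (re_species_slopes) paste0("Species (", env_labels, ")"))
  random_sd <- tibble(
    term = c(if (re_site) "Site (Intercept)", sp_sd_names),
    sd = c(if (re_site) sigma_site, sqrt(diag(Sigma)))
  )

  mode <- final$mode
  U <- matrix(mode[seq_len(m * s)], nrow = m, ncol = s, byrow = TRUE)
  cvec <- if (re_site) mode[m * s + seq_len(n)] else rep(0, n)
  random_modes_list <- list(
    a = U[, 1],
    b = if (re_species_slopes) U[, -1, drop = FALSE] else matrix(0, m, n_env),
    c = cvec
  )

  fixed_list <- te_fixed(
    alpha = est_fixed[1],
    beta1 = est_fixed[1 + seq_len(n_env)],
    beta12 = est_fixed[1 + n_env + seq_len(n_env * n_traits)]
  )

  zero_pres <- design$Z$species_id[colSums(Y) == 0]
  zero_abs <- design$Z$species_id[colSums(Y) == n]

  out <- list(
    fixed = fixed,
    fixed_list = fixed_list,
    random_sd = random_sd,
    Sigma = Sigma,
    sigma_site = sigma_site,
    random_modes_list = random_modes_list,
    random_modes = list(
      species = tibble(species_id = design$Z$species_id) %>%
        dplyr::bind_cols(stats::setNames(
          as.data.frame(U),
          c("intercept", if (re_species_slopes) colnames(X))
        )),
      site = tibble(plot_id = design$X$plot_id, intercept = cvec)
    ),
    vcov_fixed = vcov_fixed,
    log_posterior = final$value,
    converged = converged && isTRUE(final$inner_ok),
    grad_norm = grad_norm,
    optim = if (!is.null(opt)) opt[c("convergence", "counts", "message")],
    n_sites = n, m_species = m,
    re_species_slopes = re_species_slopes, re_site = re_site,
    flagged_species = tibble(
      species_id = c(zero_pres, zero_abs),
      issue = c(rep("no presences", length(zero_pres)),
                rep("no absences", length(zero_abs)))
    ),
    design = design, Y = Y, priors = priors, control = control
  )
  class(out) <- "te_fit"
  out
}

#' @export
print.te_fit <- function(x, ...) {
  cat("<te_fit> trait-environment occurrence model\n")
  cat("  ", x$n_sites, " plots x ", x$m_species, " species; ",
      nrow(x$fixed), " fixed effects; converged: ", x$converged, "\n",
      sep = "")
  cat("  log posterior:", format(x$log_posterior, digits = 6), "\n")
  print(x$fixed, n = nrow(x$fixed))
  cat("Random-effect SDs:\n")
  print(x$random_sd)
  invisible(x)
}
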