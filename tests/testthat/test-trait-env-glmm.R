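test_that("the MAP matches exact integration on a tiny instance", {
  # 2 species x 4 plots, species intercept only, site effect disabled:
  # random effects integrable by adaptive quadrature
  X <- matrix(c(-0.6, -0.2, 0.3, 0.5), 4, 1)
  Z <- matrix(c(-0.45, 0.55), 2, 1)
  Y <- matrix(c(0, 1, 1, 1, 0, 0, 1, 0), 4, 2,
              dimnames = list(paste0("p", 1:4), c("s1", "s2")))
  des <- manual_design(X, Z)
  fit <- fit_trait_env(Y, des, re_species_slopes = FALSE, re_site = FALSE)
  expect_true(fit$converged)

  quad_lp <- function(p4) {
    v <- exp(2 * p4[4])
    eta0 <- p4[1] + X[, 1] * p4[2] + outer(X[, 1], Z[, 1]) * p4[3]
    oracle_quad_marginal(eta0, Y, v, p4[1:3])
  }
  oq <- optim(c(0, 0, 0, 0), function(p) -quad_lp(p), method = "BFGS",
              control = list(reltol = 1e-14, maxit = 2000))
  expect_lt(max(abs(fit$fixed$estimate - oq$par[1:3])), 1e-3)
})

test_that("with zero observations the MAP sits at the prior modes", {
  X0 <- matrix(numeric(0), 0, 3)
  Z0 <- matrix(rnorm(8, 0, 0.5), 2, 4)
  Y0 <- matrix(numeric(0), 0, 2)
  negobj <- function(par) {
    -traitenv:::te_laplace_cpp(par, X0, Z0, Y0, TRUE, TRUE, 8, 2, 0.5, 100,
                               1, numeric(0), 200, 1e-9, FALSE)$value
  }
  gr <- function(par) {
    -traitenv:::te_laplace_cpp(par, X0, Z0, Y0, TRUE, TRUE, 8, 2, 0.5, 100,
                               1, numeric(0), 200, 1e-9, TRUE)$gradient
  }
  opt <- optim(c(rep(0, 16), rep(0, 10), 0), negobj, gr, method = "L-BFGS-B",
               lower = c(rep(-15, 16), rep(-4, 11)),
               upper = c(rep(15, 16), rep(4, 11)),
               control = list(factr = 10, pgtol = 1e-8))
  Sig <- traitenv:::te_chol_to_sigma(opt$par[17:26], 4)

  # fixed effects at the normal-prior mode (exactly 0: the optimizer is
  # seeded there and the gradient vanishes)
  expect_identical(opt$par[1:16], rep(0, 16))
  # species covariance at the inverse-Wishart mode scale/(df + dim + 1)
  expect_equal(diag(Sig), rep(2 / 13, 4), tolerance = 1e-6)
  expect_lt(max(abs(Sig[upper.tri(Sig)])), 1e-6)
  # site variance at the inverse-gamma mode scale/(shape + 1)
  expect_equal(exp(2 * opt$par[27]), 100 / 1.5, tolerance = 1e-6)
})

test_that("the Laplace objective and fit are invariant to species order", {
  sc <- make_scenario(m_species = 6, n_sets = 0, n_scattered = 25, seed = 9)
  dat <- simulate_community(sc)
  des <- build_design(dat$plots, dat$traits)
  X <- as.matrix(des$X[, -1]); Z <- as.matrix(des$Z[, -1])
  Y <- occurrence_matrix(dat$occurrence, des$X$plot_id, des$Z$species_id)

  fx <- te_fixed(alpha = -1, beta1 = c(0.3, -0.1, 0.2),
                 beta12 = rep(0.1, 12))
  Sigma <- diag(c(1, 0.5, 0.4, 0.3))
  perm <- c(4, 1, 6, 2, 5, 3)
  v1 <- log_marginal_posterior(fx, X, Z, Y, Sigma, sigma_site = 0.8)
  v2 <- log_marginal_posterior(fx, X, Z[perm, ], Y[, perm], Sigma,
                               sigma_site = 0.8)
  expect_equal(v1$value, v2$value, tolerance = 1e-8)

  f1 <- fit_trait_env(Y, des)
  des_p <- des
  des_p$Z <- des$Z[perm, ]
  f2 <- fit_trait_env(Y[, perm], des_p)
  expect_equal(f1$fixed$estimate, f2$fixed$estimate, tolerance = 1e-6)
  # species modes follow the permutation
  m1 <- f1$random_modes$species
  m2 <- f2$random_modes$species
  expect_equal(m2$intercept,
               m1$intercept[match(m2$species_id, m1$species_id)],
               tolerance = 1e-4)
})

test_that("completely separable data stay bounded under the prior", {
  X <- matrix(c(seq(-0.75, 0.75, length.out = 12), rep(0, 24)), 12, 3)
  colnames(X) <- c("elevation", "slope", "aspect")
  Z <- matrix(c(-0.5, 0.5), 2, 4)
  Y <- cbind(as.numeric(X[, 1] > 0), as.numeric(X[, 1] <= 0))
  dimnames(Y) <- list(paste0("p", 1:12), c("s1", "s2"))
  des <- manual_design(X, Z, species_ids = c("s1", "s2"))
  fit <- fit_trait_env(Y, des, re_site = FALSE)
  expect_true(all(is.finite(fit$fixed$estimate)))
  expect_lt(max(abs(fit$fixed$estimate)), 5)
})

test_that("fit summaries expose coefficients, SEs and Wald tests", {
  fit <- tiny_real_fit()
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic",
                     "p.value"))
  expect_equal(nrow(td), 16)
  expect_true(all(td$std.error > 0))
  expect_equal(td$statistic, td$estimate / td$std.error)
  expect_equal(td$p.value, 2 * pnorm(-abs(td$statistic)))

  rp <- tidy(fit, effects = "ran_pars")
  expect_equal(nrow(rp), 5)
  expect_true(all(rp$estimate > 0))
  expect_equal(rp$term[1], "Site (Intercept)")

  gl <- glance(fit)
  expect_true(gl$converged)
  expect_lt(gl$grad_norm, 1e-4)
  expect_gte(gl$conditional_r2, 0)
  expect_lte(gl$conditional_r2, 1)

  sm <- summarize_fixed_effects(fit)
  expect_true(all(sm$signif[sm$p.value >= 0.05] == ""))
  expect_true(all(sm$signif[sm$p.value < 0.05] != ""))
})

test_that("significance stars use strict conventional thresholds", {
  expect_equal(significance_stars(c(0.0009, 0.004, 0.03, 0.05, 0.31, NA)),
               c("***", "**", "*", "", "", ""))
})

test_that("conditional R2 follows the latent-scale formula", {
  est <- c(0.4, 1, 0, 0, rep(0, 12))
  fit <- fake_fit(est, Sigma = diag(c(0.6, 0.4, 0.2, 0.3)),
                  sigma_site = 0.7)
  eta <- 0.4 + rep(fit$design$X$elevation, nrow(fit$design$Z))
  v_f <- var(eta)
  v_r <- 0.6 + 0.4 + 0.2 + 0.3 + 0.49
  expect_equal(conditional_r2(fit),
               (v_f + v_r) / (v_f + v_r + pi^2 / 3))

  # all variances zero and constant predictor: no explained variance
  fit0 <- fake_fit(c(0.4, rep(0, 15)), Sigma = diag(0, 4), sigma_site = 0)
  expect_equal(conditional_r2(fit0), 0)

  # adding a variance component strictly increases the value
  fit_lo <- fake_fit(est, Sigma = diag(c(0.6, 0.4, 0.2, 0.3)),
                     sigma_site = 0)
  expect_gt(conditional_r2(fit), conditional_r2(fit_lo))
})

test_that("trait response profiles are centred lines with species points", {
  est <- c(-2.23, 0.27, -0.15, 0.34, rep(0, 12))
  est[4 + 10] <- -0.32 # MH x elevation
  b <- matrix(0, 3, 3)
  b[, 1] <- c(0.2, 0, -0.2) # species elevation deviations
  fit <- fake_fit(est, std_errors = rep(0.15, 16), b = b)

  pr <- trait_response_profile(fit, "max_height", "elevation")
  expect_s3_class(pr, "te_profile")
  expect_equal(pr$coefficient, -0.32)
  expect_equal(pr$line$response, -0.32 * pr$line$z)
  expect_equal(pr$line$response[which.min(abs(pr$line$z))], 0,
               tolerance = 1e-6)
  expect_true(all(pr$line$upper >= pr$line$response))
  # species responses are centred across species
  expect_equal(mean(pr$species$response), 0)
  expect_equal(pr$species$response, c(0.2, 0, -0.2) + 0.27 - 0.27)

  # a zero interaction gives a flat line
  pr0 <- trait_response_profile(fit, "sla", "slope")
  expect_true(all(pr0$line$response == 0))

  expect_error(trait_response_profile(fit, "leafiness", "elevation"),
               "Unknown trait")

  # the mean response crosses zero at -beta1/beta12
  expect_equal(response_zero_crossing(fit, "MH", "elevation"),
               -0.27 / -0.32)
  raw <- response_zero_crossing(fit, "MH", "elevation", scale = "raw")
  rec <- fit$design$records[fit$design$records$name == "max_height", ]
  expect_equal(raw, invert_standardization(0.27 / 0.32, rec))
})

test_that("species without presences are flagged but fitted", {
  sc <- make_scenario(m_species = 5, n_sets = 0, n_scattered = 20, seed = 4)
  dat <- simulate_community(sc)
  des <- build_design(dat$plots, dat$traits)
  occ <- dat$occurrence
  occ$sp02 <- 0 # force an all-absent species
  fit <- fit_trait_env(occ, des)
  expect_true("sp02" %in% fit$flagged_species$species_id)
  expect_true(all(is.finite(fit$fixed$estimate)))
})

test_that("hitting the iteration cap reports rather than raises", {
  sc <- make_scenario(m_species = 4, n_sets = 0, n_scattered = 15, seed = 6)
  dat <- simulate_community(sc)
  des <- build_design(dat$plots, dat$traits)
  ctrl <- te_control(maxit = 1, se = FALSE)
  fit <- fit_trait_env(dat$occurrence, des, control = ctrl)
  expect_s3_class(fit, "te_fit")
  expect_false(fit$converged)
})

test_that("autoplot methods return ggplot objects", {
  fit <- tiny_real_fit()
  expect_s3_class(autoplot(fit), "ggplot")
  pr <- trait_response_profile(fit, "max_height", "elevation")
  expect_s3_class(autoplot(pr), "ggplot")
  expect_s3_class(plot_trait_env_grid(fit), "ggplot")
})
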