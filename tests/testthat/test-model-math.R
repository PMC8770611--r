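test_that("the linear predictor reproduces direct arithmetic", {
  fx0 <- te_fixed(alpha = -2.23)
  eta <- linear_predictor(fx0, X = matrix(0, 1, 3), Z = matrix(0.7, 1, 4))
  expect_equal(drop(eta), -2.23)
  expect_equal(round(plogis(drop(eta)), 4), 0.0971)

  # with beta12 = 0 the predictor is invariant to traits
  fx1 <- te_fixed(alpha = 0.5, beta1 = c(1, -1, 2))
  X <- matrix(rnorm(6), 2, 3)
  e1 <- linear_predictor(fx1, X, Z = matrix(rnorm(4), 1, 4))
  e2 <- linear_predictor(fx1, X, Z = matrix(rnorm(4), 1, 4))
  expect_equal(e1, e2)

  # reference-value arithmetic: alpha + beta1[elev] + beta12[MH, elev]
  b12 <- numeric(12)
  b12[10] <- -0.32 # MH x elevation in trait-major order
  fx2 <- te_fixed(alpha = -2.23, beta1 = c(0.27, -0.15, 0.34), beta12 = b12)
  eta2 <- linear_predictor(fx2, X = matrix(c(1, 0, 0), 1, 3),
                           Z = matrix(c(0, 0, 0, 1), 1, 4))
  expect_equal(drop(eta2), -2.23 + 0.27 - 0.32)

  expect_error(linear_predictor(fx2, X = matrix(0, 1, 2),
                                Z = matrix(0, 1, 4)), "Dimension")
})

test_that("random effects enter the predictor additively", {
  fx <- te_fixed(alpha = 0, beta1 = c(1, 0, 0))
  X <- matrix(c(0.5, 0, 0), 1, 3)
  Z <- matrix(0, 2, 4)
  eta <- linear_predictor(fx, X, Z, random = list(
    a = c(1, -1), b = matrix(c(2, 0, 0, 0, 0, 0), 2, 3), c = 0.25
  ))
  expect_equal(drop(eta), c(0.5 + 1 + 1 + 0.25, 0.5 - 1 + 0.25))
})

test_that("the joint log posterior matches a term-by-term oracle", {
  set.seed(8)
  n <- 3; m <- 2
  X <- matrix(rnorm(n * 3, 0, 0.5), n, 3)
  Z <- matrix(rnorm(m * 4, 0, 0.5), m, 4)
  Y <- matrix(c(1, 0, 1, 0, 0, 1), n, m)
  fx <- te_fixed(alpha = -0.4, beta1 = c(0.2, -0.1, 0.3),
                 beta12 = seq(-0.3, 0.25, length.out = 12))
  a <- c(0.3, -0.2)
  b <- matrix(rnorm(m * 3, 0, 0.3), m, 3)
  cc <- rnorm(n, 0, 0.2)
  Sigma <- diag(c(0.8, 0.5, 0.4, 0.3)) + 0.05
  sigma_site <- 0.9
  pr <- te_priors()

  got <- log_posterior(fx, X, Z, Y, random = list(a = a, b = b, c = cc),
                       variance = list(Sigma = Sigma,
                                       sigma_site = sigma_site))

  # independent oracle: every term summed explicitly
  want <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      eta_ij <- fx$alpha + a[j] +
        sum((fx$beta1 + b[j, ]) * X[i, ]) +
        sum(outer(X[i, ], Z[j, ]) * fx$B) + cc[i]
      want <- want + dbinom(Y[i, j], 1, plogis(eta_ij), log = TRUE)
    }
  }
  Sinv <- solve(Sigma)
  for (j in seq_len(m)) {
    u <- c(a[j], b[j, ])
    want <- want - 0.5 * drop(t(u) %*% Sinv %*% u) -
      0.5 * determinant(Sigma)$modulus - 2 * log(2 * pi)
  }
  want <- want + sum(dnorm(cc, 0, sigma_site, log = TRUE))
  # inverse-Wishart(8, 2 I4) density, coded from its formula
  p <- 4; nu <- 8; Psi <- diag(2, 4)
  lmvg <- p * (p - 1) / 4 * log(pi) + sum(lgamma(nu / 2 + (1 - 1:p) / 2))
  want <- want + 0.5 * nu * determinant(Psi)$modulus -
    0.5 * nu * p * log(2) - lmvg -
    0.5 * (nu + p + 1) * determinant(Sigma)$modulus -
    0.5 * sum(diag(solve(Sigma) %*% Psi))
  # inverse-gamma(0.5, 100) on the site variance
  s2 <- sigma_site^2
  want <- want + 0.5 * log(100) - lgamma(0.5) - 1.5 * log(s2) - 100 / s2
  want <- want + sum(dnorm(c(fx$alpha, fx$beta1, fx$beta12), 0, 1,
                           log = TRUE))

  expect_equal(got, as.numeric(want), tolerance = 1e-10)
})

test_that("with no data the posterior is the prior", {
  X0 <- matrix(numeric(0), 0, 1)
  Z0 <- matrix(0, 1, 1)
  base <- log_posterior(te_fixed(0, 0, 0), X0, Z0, Y = matrix(numeric(0), 0, 1))
  moved <- log_posterior(te_fixed(0, 1, 0), X0, Z0,
                         Y = matrix(numeric(0), 0, 1))
  expect_equal(base - moved, 0.5) # the N(0,1) penalty of moving one
                                  # coefficient from 0 to 1
})

test_that("a single Bernoulli cell at eta = 0 contributes ln(1/2)", {
  fx <- te_fixed(0, 0, 0)
  lp1 <- log_posterior(fx, matrix(0, 1, 1), matrix(0, 1, 1),
                       Y = matrix(1, 1, 1))
  lp_prior <- log_posterior(fx, matrix(numeric(0), 0, 1), matrix(0, 1, 1),
                            Y = matrix(numeric(0), 0, 1))
  expect_equal(lp1 - lp_prior, log(0.5))
})

test_that("predicted probabilities are proper and monotone in eta", {
  fit <- tiny_real_fit()
  p <- predict_probability(fit, include_random = TRUE)
  expect_true(all(p > 0 & p < 1))

  p0 <- predict_probability(fit, X = matrix(0, 1, 3), Z = matrix(0, 1, 4))
  a <- fit$fixed$estimate[1]
  expect_equal(drop(p0), plogis(a))

  xs <- seq(-1, 1, length.out = 11)
  ps <- vapply(xs, function(x) {
    drop(predict_probability(fit, X = matrix(c(x, 0, 0), 1, 3),
                             Z = matrix(0, 1, 4)))
  }, numeric(1))
  if (fit$fixed$estimate[2] > 0) {
    expect_true(all(diff(ps) > 0))
  } else {
    expect_true(all(diff(ps) < 0))
  }

  expect_error(predict_probability(fit, X = matrix(0, 1, 3),
                                   include_random = TRUE), "fitted plots")
})
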