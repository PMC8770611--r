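// Laplace-approximated log posterior for the trait-environment occurrence
// model. The latent vector stacks m species random-effect vectors (intercept
// plus optional environmental slopes) and n site intercepts; its mode is
// found by damped Newton and the marginal posterior uses the Gaussian
// (Laplace) approximation at that mode. The Newton system is solved via the
// Schur complement on the diagonal site block, so the factorization cost is
// driven by the m*s species coordinates, not by the site count. Priors:
// normal on fixed effects, inverse-Wishart on the species covariance,
// inverse-gamma on the site variance.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline double softplus(double x) {
  // log(1 + exp(x)) without overflow
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

static double lmvgamma(int p, double a) {
  double r = 0.25 * p * (p - 1) * std::log(M_PI);
  for (int i = 1; i <= p; ++i) r += std::lgamma(a + 0.5 * (1.0 - i));
  return r;
}

// Bernoulli-logit log likelihood plus Gaussian random-effect densities at
// latent values (U, c); all normalizing constants included.
static double penalized_obj(const mat& eta, const mat& Y, const mat& U,
                            const vec& c, const mat& Siginv, double ldSig,
                            bool re_site, double s2c) {
  double ll = 0.0;
  const double* e = eta.memptr();
  const double* y = Y.memptr();
  const uword N = eta.n_elem;
  for (uword k = 0; k < N; ++k) ll += y[k] * e[k] - softplus(e[k]);
  const double m = U.n_rows, s = U.n_cols;
  ll += -0.5 * accu((U * Siginv) % U) - 0.5 * m * ldSig -
        0.5 * m * s * std::log(2.0 * M_PI);
  if (re_site) {
    double n = c.n_elem;
    ll += -0.5 * dot(c, c) / s2c - 0.5 * n * std::log(2.0 * M_PI * s2c);
  }
  return ll;
}

// [[Rcpp::export]]
Rcpp::List te_laplace_cpp(const arma::vec& par, const arma::mat& X,
                          const arma::mat& Z, const arma::mat& Y,
                          bool re_slopes, bool re_site, double iw_df,
                          double iw_scale_diag, double ig_shape,
                          double ig_scale, double fixed_sd,
                          const arma::vec& u_init, int max_inner,
                          double inner_tol, bool want_grad = false) {
  const int n = X.n_rows, pe = X.n_cols, pt = Z.n_cols, m = Z.n_rows;
  const int s = re_slopes ? 1 + pe : 1;
  const int nfix = 1 + pe + pt * pe;
  const int ncov = s * (s + 1) / 2;
  const int ms = m * s;
  const int qlat = ms + (re_site ? n : 0);

  const double alpha = par(0);
  const vec beta1 = par.subvec(1, pe);
  mat B(pe, pt); // B(e, t) = beta12 for trait t x environment e (trait-major)
  for (int t = 0; t < pt; ++t)
    for (int e = 0; e < pe; ++e) B(e, t) = par(1 + pe + t * pe + e);

  // species covariance from log-Cholesky parameters
  mat L(s, s, fill::zeros);
  {
    int k = nfix;
    for (int col = 0; col < s; ++col)
      for (int row = col; row < s; ++row, ++k)
        L(row, col) = (row == col) ? std::exp(par(k)) : par(k);
  }
  const mat Sigma = L * L.t();
  const mat Linv = inv(trimatl(L));
  const mat Siginv = Linv.t() * Linv;
  double ldSig = 0.0;
  for (int i = 0; i < s; ++i) ldSig += 2.0 * std::log(L(i, i));
  double s2c = 1.0;
  if (re_site) s2c = std::exp(2.0 * par(nfix + ncov));

  // fixed part of the linear predictor
  mat eta0(n, m);
  if (n > 0) {
    const vec xb = alpha + X * beta1;
    const mat inter = X * B * Z.t(); // n x m
    for (int j = 0; j < m; ++j) eta0.col(j) = xb + inter.col(j);
  }

  mat A(n, s, fill::ones);
  if (re_slopes && n > 0) A.cols(1, pe) = X;

  mat U(m, s, fill::zeros);
  vec c(re_site ? n : 0, fill::zeros);

  auto eta_at = [&](const mat& Uv, const vec& cv) {
    mat eta = eta0 + A * Uv.t();
    if (re_site) eta.each_col() += cv;
    return eta;
  };

  // warm start from a previous mode, but only if it beats the zero start
  // (a stale mode from a distant parameter point must never hurt)
  bool warm_used = false;
  if ((int)u_init.n_elem == qlat && qlat > 0) {
    mat Uw(m, s);
    vec cw(re_site ? n : 0);
    for (int j = 0; j < m; ++j)
      Uw.row(j) = u_init.subvec(j * s, j * s + s - 1).t();
    if (re_site) cw = u_init.subvec(ms, qlat - 1);
    double f_warm = penalized_obj(eta_at(Uw, cw), Y, Uw, cw, Siginv, ldSig,
                                  re_site, s2c);
    double f_zero = penalized_obj(eta_at(U, c), Y, U, c, Siginv, ldSig,
                                  re_site, s2c);
    if (std::isfinite(f_warm) && f_warm > f_zero) {
      U = Uw; c = cw; warm_used = true;
    }
  }

  mat eta = eta_at(U, c);
  double f = penalized_obj(eta, Y, U, c, Siginv, ldSig, re_site, s2c);

  int iter = 0;
  double gnorm = (qlat > 0) ? datum::inf : 0.0;
  bool inner_ok = true;

  // Assemble the Newton system pieces at the current eta. Returns false if
  // the (Schur) factorization fails.
  mat Smat(ms, ms);     // species-block part of the negative Hessian
  vec dsite;            // site diagonal
  mat Cmat;             // n x ms cross block
  auto assemble = [&](const mat& W) {
    Smat.zeros();
    for (int j = 0; j < m; ++j)
      Smat.submat(j * s, j * s, j * s + s - 1, j * s + s - 1) =
        A.t() * (A.each_col() % W.col(j)) + Siginv;
    if (re_site) {
      dsite = sum(W, 1) + 1.0 / s2c;
      Cmat.set_size(n, ms);
      for (int j = 0; j < m; ++j)
        Cmat.cols(j * s, j * s + s - 1) = A.each_col() % W.col(j);
    }
  };
  // Schur complement of the site block: S - C' D^{-1} C
  auto schur = [&]() {
    if (!re_site) return Smat;
    mat Cs = Cmat.each_col() / sqrt(dsite);
    return mat(Smat - Cs.t() * Cs);
  };

  for (int attempt = 0; attempt < 2; ++attempt) {
    if (attempt == 1) { // cold retry after a failed warm-started search
      U.zeros();
      if (re_site) c.zeros();
      eta = eta_at(U, c);
      f = penalized_obj(eta, Y, U, c, Siginv, ldSig, re_site, s2c);
      inner_ok = true;
    }
    if (n == 0) gnorm = 0.0; // no data: the zero latent vector is the mode
    for (iter = 0; iter < max_inner && qlat > 0 && n > 0; ++iter) {
      const mat P = 1.0 / (1.0 + exp(-eta));
      const mat W = P % (1.0 - P);
      const mat R = Y - P;

      vec gU(ms);
      for (int j = 0; j < m; ++j)
        gU.subvec(j * s, j * s + s - 1) = A.t() * R.col(j) - Siginv * U.row(j).t();
      vec gc;
      if (re_site) gc = sum(R, 1) - c / s2c;

      gnorm = norm(gU, "inf");
      if (re_site && n > 0) gnorm = std::max(gnorm, norm(gc, "inf"));
      if (gnorm < inner_tol) break;

      assemble(W);
      mat Ss = schur();
      mat Rchol;
      if (!chol(Rchol, Ss)) {
        Ss.diag() += 1e-8;
        if (!chol(Rchol, Ss)) { inner_ok = false; break; }
      }
      vec rhs = gU;
      if (re_site) rhs -= Cmat.t() * (gc / dsite);
      const vec stepU = solve(trimatu(Rchol), solve(trimatl(Rchol.t()), rhs));
      vec stepc;
      if (re_site) stepc = (gc - Cmat * stepU) / dsite;

      double t = 1.0;
      bool improved = false;
      for (int h = 0; h < 30; ++h) {
        mat Ut = U;
        vec ct = c;
        for (int j = 0; j < m; ++j)
          Ut.row(j) += t * stepU.subvec(j * s, j * s + s - 1).t();
        if (re_site) ct += t * stepc;
        mat etat = eta_at(Ut, ct);
        double ft = penalized_obj(etat, Y, Ut, ct, Siginv, ldSig, re_site, s2c);
        if (std::isfinite(ft) && ft >= f - 1e-12) {
          U = Ut; c = ct; eta = std::move(etat); f = ft; improved = true;
          break;
        }
        t *= 0.5;
      }
      if (!improved) break; // stagnated at numerical precision
    }
    // a stale warm start must never yield a spurious non-mode: retry cold
    bool at_mode = (qlat == 0) || gnorm < std::max(inner_tol * 1e4, 1e-4);
    if (at_mode || !warm_used) break;
  }
  if (qlat > 0 && gnorm >= std::max(inner_tol * 1e4, 1e-4)) inner_ok = false;

  // log-determinant of the negative Hessian at the mode:
  // log|H| = sum(log d_i) + log|S - C' D^{-1} C|
  double ldH = 0.0;
  vec grad; // analytic gradient of the Laplace objective in par
  mat P, W;
  bool have_schur = false;
  mat Ss;
  if (qlat > 0 && n > 0) {
    P = 1.0 / (1.0 + exp(-eta));
    W = P % (1.0 - P);
    assemble(W);
    Ss = schur();
    mat Rchol;
    if (!chol(Rchol, Ss)) {
      inner_ok = false;
    } else {
      have_schur = true;
      ldH = 2.0 * accu(log(Rchol.diag()));
      if (re_site) ldH += accu(log(dsite));
    }
  } else if (qlat > 0) {
    // no observations: H is block-diagonal Sigma^{-1}, and the Laplace
    // integral over the species effects is exact
    ldH = -m * ldSig;
  }

  if (want_grad && inner_ok) {
    grad.zeros(par.n_elem);
    if (qlat > 0 && n == 0) {
      // prior-only gradients: normal on fixed effects, inverse-Wishart on
      // the (exactly marginalized) species covariance, inverse-gamma on the
      // site variance
      for (int k = 0; k < nfix; ++k)
        grad(k) = -par(k) / (fixed_sd * fixed_sd);
      int k = nfix;
      for (int col = 0; col < s; ++col) {
        for (int row = col; row < s; ++row, ++k) {
          mat dL(s, s, fill::zeros);
          dL(row, col) = (row == col) ? L(row, col) : 1.0;
          const mat Sd = dL * L.t() + L * dL.t();
          const double trSd = trace(Siginv * Sd);
          grad(k) = -0.5 * (iw_df + s + 1.0) * trSd +
                    0.5 * iw_scale_diag * trace(Siginv * Sd * Siginv);
        }
      }
      if (re_site)
        grad(nfix + ncov) =
          -2.0 * (ig_shape + 1.0) + 2.0 * ig_scale / s2c;
    } else if (qlat > 0 && have_schur) {
      const mat R = Y - P;
      const mat g3 = W % (1.0 - 2.0 * P); // third derivative of softplus
      const mat Q = inv_sympd(Ss);        // species block of H^{-1}
      mat M;                              // C Q, n x ms
      if (re_site) M = Cmat * Q;

      // G(i,j) = d_o' H^{-1} d_o for observation o = (i, j)
      mat G(n, m);
      vec site_diag; // H^{-1} site-block diagonal (needed for d/dtheta_site)
      if (re_site) {
        site_diag = 1.0 / dsite + sum(Cmat % M, 1) / square(dsite);
      }
      for (int j = 0; j < m; ++j) {
        const mat Qjj = Q.submat(j * s, j * s, j * s + s - 1, j * s + s - 1);
        vec qsp = sum((A * Qjj) % A, 1);
        if (re_site) {
          vec cross = -2.0 *
            sum(M.cols(j * s, j * s + s - 1) % A, 1) / dsite;
          G.col(j) = qsp + cross + site_diag;
        } else {
          G.col(j) = qsp;
        }
      }

      // v = d(logdet H)/du assembled over observations; w = H^{-1} v
      const mat vmat = g3 % G;
      mat vU(m, s);
      for (int j = 0; j < m; ++j) vU.row(j) = (A.t() * vmat.col(j)).t();
      vec vc, wc;
      mat wU(m, s);
      {
        vec vUf(ms);
        for (int j = 0; j < m; ++j)
          vUf.subvec(j * s, j * s + s - 1) = vU.row(j).t();
        vec rhs = vUf;
        if (re_site) {
          vc = sum(vmat, 1);
          rhs -= Cmat.t() * (vc / dsite);
        }
        vec xU = Q * rhs;
        for (int j = 0; j < m; ++j)
          wU.row(j) = xU.subvec(j * s, j * s + s - 1).t();
        if (re_site) wc = (vc - Cmat * xU) / dsite;
      }
      mat wexp = A * wU.t(); // n x m expansion of w to observation space
      if (re_site) wexp.each_col() += wc;

      // observation-space weight combining the envelope, direct log-det and
      // implicit (mode-shift) terms
      const mat coef = R - 0.5 * (g3 % G) + 0.5 * (W % wexp);

      // fixed effects
      grad(0) = accu(coef) - alpha / (fixed_sd * fixed_sd);
      const vec ce = sum(coef, 1); // per-plot sums
      for (int e = 0; e < pe; ++e)
        grad(1 + e) = dot(X.col(e), ce) - beta1(e) / (fixed_sd * fixed_sd);
      const mat T = X.t() * coef * Z; // pe x pt
      for (int t = 0; t < pt; ++t)
        for (int e = 0; e < pe; ++e)
          grad(1 + pe + t * pe + e) =
            T(e, t) - par(1 + pe + t * pe + e) / (fixed_sd * fixed_sd);

      // species covariance (log-Cholesky parameters)
      {
        // per-block pieces reused for every parameter
        mat sumQjj(s, s, fill::zeros), sumUU(s, s, fill::zeros),
            sumWU(s, s, fill::zeros);
        for (int j = 0; j < m; ++j) {
          sumQjj += Q.submat(j * s, j * s, j * s + s - 1, j * s + s - 1);
          sumUU += U.row(j).t() * U.row(j);
          sumWU += wU.row(j).t() * U.row(j);
        }
        int k = nfix;
        for (int col = 0; col < s; ++col) {
          for (int row = col; row < s; ++row, ++k) {
            mat dL(s, s, fill::zeros);
            dL(row, col) = (row == col) ? L(row, col) : 1.0;
            const mat Sd = dL * L.t() + L * dL.t();
            const mat K = -Siginv * Sd * Siginv; // d(Sigma^{-1})
            const double trSd = trace(Siginv * Sd);
            double g =
              -0.5 * accu(K % sumUU) - 0.5 * m * trSd  // penalized part
              - 0.5 * accu(K % sumQjj)                 // direct log-det
              + 0.5 * accu(K % sumWU);                 // implicit (mode shift)
            // inverse-Wishart prior
            g += -0.5 * (iw_df + s + 1.0) * trSd +
                 0.5 * iw_scale_diag * trace(Siginv * Sd * Siginv);
            grad(k) = g;
          }
        }
      }

      // site variance (log-SD parameter)
      if (re_site) {
        double g = dot(c, c) / s2c - n;                       // penalized
        g += accu(site_diag) / s2c;                           // direct log-det
        g += -dot(wc, c) / s2c;                               // implicit
        g += -2.0 * (ig_shape + 1.0) + 2.0 * ig_scale / s2c;  // prior
        grad(nfix + ncov) = g;
      }
    } else {
      // no latent structure: prior-only gradients
      for (int k = 0; k < nfix; ++k)
        grad(k) = -par(k) / (fixed_sd * fixed_sd);
    }
  }

  double lp = f + 0.5 * qlat * std::log(2.0 * M_PI) - 0.5 * ldH;

  // priors on fixed effects (normal, sd = fixed_sd)
  for (int k = 0; k < nfix; ++k)
    lp += -0.5 * std::log(2.0 * M_PI) - std::log(fixed_sd) -
          0.5 * par(k) * par(k) / (fixed_sd * fixed_sd);

  // inverse-Wishart prior on the species covariance, scale matrix
  // iw_scale_diag * I_s
  {
    const double nu = iw_df, p = s;
    lp += 0.5 * nu * p * std::log(iw_scale_diag) -
          0.5 * nu * p * std::log(2.0) - lmvgamma(s, 0.5 * nu) -
          0.5 * (nu + p + 1.0) * ldSig - 0.5 * iw_scale_diag * trace(Siginv);
  }

  // inverse-gamma prior on the site variance
  if (re_site) {
    lp += ig_shape * std::log(ig_scale) - std::lgamma(ig_shape) -
          (ig_shape + 1.0) * std::log(s2c) - ig_scale / s2c;
  }

  vec mode(qlat);
  for (int j = 0; j < m; ++j) mode.subvec(j * s, j * s + s - 1) = U.row(j).t();
  if (re_site && n > 0) mode.subvec(ms, qlat - 1) = c;

  return Rcpp::List::create(
    Rcpp::Named("value") = lp, Rcpp::Named("mode") = mode,
    Rcpp::Named("penalized") = f, Rcpp::Named("logdet_H") = ldH,
    Rcpp::Named("inner_iter") = iter, Rcpp::Named("inner_grad") = gnorm,
    Rcpp::Named("inner_ok") = inner_ok && std::isfinite(lp),
    Rcpp::Named("warm_used") = warm_used, Rcpp::Named("gradient") = grad,
    Rcpp::Named("Sigma") = Sigma, Rcpp::Named("sigma_site") = std::sqrt(s2c));
}
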