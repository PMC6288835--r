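// Core numerical engine: single-locus DGLM fits, genome scans, and the
// structured-permutation loops. Everything here is plain maximum likelihood
// so that likelihood-ratio statistics from different fits are coherent.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);
// fitted sigma^2 is floored at 1e-12; hitting the floor flags the fit
static const double LV_FLOOR = std::log(1e-12);

struct Fit {
  vec beta;   // mean-submodel coefficients
  vec phi;    // log-variance (log sigma^2) coefficients
  vec m;      // fitted means
  vec lv;     // fitted log sigma^2
  double ll;
  int iter;
  bool converged;
  bool degenerate;
  bool ok;    // false on rank deficiency / numerical failure
};

// X' diag(w) X and X' diag(w) y by direct accumulation: for the small
// column counts used here this avoids BLAS call overhead entirely.
static void weighted_xtx(const mat& X, const vec& y, const vec& w,
                         mat& A, vec& b) {
  const uword n = X.n_rows, p = X.n_cols;
  A.zeros(p, p);
  b.zeros(p);
  for (uword i = 0; i < n; ++i) {
    const double wi = w(i), wy = wi * y(i);
    for (uword j = 0; j < p; ++j) {
      const double xij = X(i, j), wx = wi * xij;
      b(j) += wy * xij;
      for (uword k = j; k < p; ++k) A(j, k) += wx * X(i, k);
    }
  }
  A = symmatu(A);
}

// Cholesky solve of a small SPD system without LAPACK call overhead;
// returns false when the matrix is numerically rank deficient.
static bool chol_solve_small(mat A, vec b, vec& x) {
  const uword p = A.n_cols;
  const double tol = 1e-10 * (A.diag().max() + 1e-300);
  for (uword j = 0; j < p; ++j) {
    double d = A(j, j);
    for (uword k = 0; k < j; ++k) d -= A(j, k) * A(j, k);
    if (d <= tol) return false;
    d = std::sqrt(d);
    A(j, j) = d;
    for (uword i = j + 1; i < p; ++i) {
      double v = A(i, j);
      for (uword k = 0; k < j; ++k) v -= A(i, k) * A(j, k);
      A(i, j) = v / d;
    }
  }
  // forward then backward substitution on the lower factor
  for (uword i = 0; i < p; ++i) {
    double v = b(i);
    for (uword k = 0; k < i; ++k) v -= A(i, k) * b(k);
    b(i) = v / A(i, i);
  }
  x.set_size(p);
  for (uword ii = p; ii-- > 0;) {
    double v = b(ii);
    for (uword k = ii + 1; k < p; ++k) v -= A(k, ii) * x(k);
    x(ii) = v / A(ii, ii);
  }
  return true;
}

static bool wls(const mat& X, const vec& y, const vec& w, vec& coef) {
  mat A;
  vec b;
  weighted_xtx(X, y, w, A, b);
  return chol_solve_small(A, b, coef);
}

static double gauss_ll(const vec& r2, const vec& lv) {
  return -0.5 * accu(LOG2PI + lv + r2 % exp(-lv));
}

// Exact block maximization over phi given the squared residuals r2:
// g(phi) = -0.5 * sum(eta + r2 * exp(-eta)), eta = Z phi, is concave, so
// damped Newton with the observed information converges in a handful of
// steps (this is the gamma-GLM score system for a log-linear dispersion
// model, solved to convergence). Returns false on numerical failure.
static bool var_block_update(const mat& Z, const vec& r2, vec& phi, vec& lv) {
  vec eta = Z * phi;
  double g = -0.5 * accu(eta + r2 % exp(-eta));
  for (int j = 0; j < 30; ++j) {
    vec s = r2 % exp(-eta);
    const uword n = Z.n_rows, p = Z.n_cols;
    mat H(p, p, fill::zeros);
    vec grad(p, fill::zeros);
    for (uword i = 0; i < n; ++i) {
      const double wi = 0.5 * s(i), gi = 0.5 * (s(i) - 1.0);
      for (uword j = 0; j < p; ++j) {
        const double zij = Z(i, j);
        grad(j) += gi * zij;
        const double wz = wi * zij;
        for (uword k = j; k < p; ++k) H(j, k) += wz * Z(i, k);
      }
    }
    H = symmatu(H);
    vec step;
    if (!chol_solve_small(H, grad, step)) return false;
    double t = 1.0;
    vec phi_new, eta_new;
    double g_new = -datum::inf;
    for (int k = 0; k < 12; ++k) {
      phi_new = phi + t * step;
      eta_new = Z * phi_new;
      g_new = -0.5 * accu(eta_new + r2 % exp(-eta_new));
      if (std::isfinite(g_new) && g_new >= g - 1e-14) break;
      t *= 0.5;
    }
    if (!std::isfinite(g_new)) return false;
    double delta = t * abs(step).max();
    phi = phi_new;
    eta = eta_new;
    g = g_new;
    if (delta < 1e-11) break;
  }
  lv = clamp(eta, LV_FLOOR, 700.0);
  return true;
}

// Alternating maximum-likelihood fit of the Gaussian DGLM:
//   y_i ~ N(x_i'beta, exp(z_i'phi))
// Block updates: (1) WLS for beta with weights exp(-lv); (2) the gamma-GLM
// (log link, dispersion 2) score system on squared residuals for phi,
// solved exactly by var_block_update. Each block solves its score
// equations, so the log-likelihood is non-decreasing across iterations.
// Z must carry an intercept in column 0.
static Fit dglm_fit(const vec& y, const mat& X, const mat& Z,
                    double tol, int maxit,
                    const vec* phi_init = nullptr) {
  Fit f;
  f.ok = true; f.converged = false; f.degenerate = false; f.iter = 0;
  const uword n = y.n_elem;
  vec unit(n, fill::ones);

  if (!wls(X, y, unit, f.beta)) { f.ok = false; return f; }
  f.m = X * f.beta;
  vec r2 = square(y - f.m);
  double s2 = accu(r2) / n;
  if (s2 < 1e-12) { s2 = 1e-12; f.degenerate = true; }
  if (phi_init != nullptr && phi_init->n_elem == Z.n_cols) {
    // warm start (e.g. from the previous permutation's fit at this locus);
    // block ascent still converges to a stationary point from any start
    f.phi = *phi_init;
  } else {
    f.phi = zeros<vec>(Z.n_cols);
    f.phi(0) = std::log(s2);
  }
  f.lv = Z * f.phi;
  double ll = gauss_ll(r2, f.lv);

  for (int it = 1; it <= maxit; ++it) {
    f.iter = it;
    vec w = exp(-f.lv);
    vec beta_new;
    if (!wls(X, y, w, beta_new)) { f.ok = false; return f; }
    f.beta = beta_new;
    f.m = X * f.beta;
    r2 = square(y - f.m);

    if (!var_block_update(Z, r2, f.phi, f.lv)) { f.ok = false; return f; }

    double ll_new = gauss_ll(r2, f.lv);
    if (std::abs(ll_new - ll) < tol) { ll = ll_new; f.converged = true; break; }
    ll = ll_new;
  }
  f.ll = ll;
  if (f.lv.min() <= LV_FLOOR + 1e-9) f.degenerate = true;
  return f;
}

// [[Rcpp::export]]
Rcpp::List cpp_dglm_fit(const arma::vec& y, const arma::mat& X,
                        const arma::mat& Z, double tol = 1e-10,
                        int maxit = 50) {
  Fit f = dglm_fit(y, X, Z, tol, maxit);
  if (!f.ok) Rcpp::stop("rank-deficient design in DGLM fit");
  vec w = exp(-f.lv);
  mat Xw = X.each_col() % w;
  mat info_beta = Xw.t() * X;
  mat info_phi = 0.5 * (Z.t() * Z);
  vec se_beta(X.n_cols), se_phi(Z.n_cols);
  mat cb, cp;
  bool okb = inv_sympd(cb, info_beta);
  bool okp = inv_sympd(cp, info_phi);
  se_beta = okb ? sqrt(cb.diag()) : vec(X.n_cols, fill::value(datum::nan));
  se_phi = okp ? sqrt(cp.diag()) : vec(Z.n_cols, fill::value(datum::nan));
  return Rcpp::List::create(
    Rcpp::Named("beta") = f.beta,
    Rcpp::Named("phi") = f.phi,
    Rcpp::Named("se_beta") = se_beta,
    Rcpp::Named("se_phi") = se_phi,
    Rcpp::Named("fitted_mean") = f.m,
    Rcpp::Named("fitted_logvar") = f.lv,
    Rcpp::Named("loglik") = f.ll,
    Rcpp::Named("iterations") = f.iter,
    Rcpp::Named("converged") = f.converged,
    Rcpp::Named("degenerate") = f.degenerate);
}

// Gaussian ML fit with a single residual variance (sigma2_hat = RSS/n).
// [[Rcpp::export]]
Rcpp::List cpp_slm_fit(const arma::vec& y, const arma::mat& X) {
  vec coef;
  vec unit(y.n_elem, fill::ones);
  if (!wls(X, y, unit, coef)) Rcpp::stop("rank-deficient design in SLM fit");
  const double n = (double)y.n_elem;
  vec resid = y - X * coef;
  double rss = accu(square(resid));
  bool degenerate = rss / n < 1e-12;
  double s2 = std::max(rss / n, 1e-12);
  double ll = -0.5 * n * (LOG2PI + std::log(s2) + 1.0);
  return Rcpp::List::create(
    Rcpp::Named("coef") = coef,
    Rcpp::Named("rss") = rss,
    Rcpp::Named("sigma2") = s2,
    Rcpp::Named("loglik") = ll,
    Rcpp::Named("degenerate") = degenerate);
}

static double slm_ll(double rss, double n) {
  double s2 = std::max(rss / n, 1e-12);
  return -0.5 * n * (LOG2PI + std::log(s2) + 1.0);
}

static double lr_from(double ll_full, double ll_null, bool& valid) {
  double lr = 2.0 * (ll_full - ll_null);
  if (lr < -1e-3) { valid = false; return NA_REAL; }
  return lr < 0 ? 0.0 : lr;
}

// Genome scan: at each locus l the expected-additive column A.col(l) and
// expected-dominance column D.col(l) are appended to the covariate designs.
// tests: logical length 4 in order (slm, mqtl, vqtl, mvqtl).
// [[Rcpp::export]]
Rcpp::List cpp_scan(const arma::vec& y, const arma::mat& Xc,
                    const arma::mat& Zc, const arma::mat& A,
                    const arma::mat& D,
                    const Rcpp::LogicalVector& tests,
                    double tol = 1e-10, int maxit = 50) {
  const uword L = A.n_cols;
  const double n = (double)y.n_elem;
  bool do_slm = tests[0], do_m = tests[1], do_v = tests[2], do_mv = tests[3];
  bool need_dglm_full = do_m || do_v || do_mv;

  vec lod(L, fill::value(NA_REAL)), lr_m(L, fill::value(NA_REAL)),
      lr_v(L, fill::value(NA_REAL)), lr_mv(L, fill::value(NA_REAL));
  umat valid(L, 4, fill::zeros);

  double rss0 = NA_REAL;
  vec coef0, unit(y.n_elem, fill::ones);
  bool slm0_ok = false;
  if (do_slm) {
    slm0_ok = wls(Xc, y, unit, coef0);
    if (slm0_ok) rss0 = accu(square(y - Xc * coef0));
  }
  Fit null_mv;
  bool mv0_ok = false;
  if (do_mv) {
    null_mv = dglm_fit(y, Xc, Zc, tol, maxit);
    mv0_ok = null_mv.ok && !null_mv.degenerate;
  }

  for (uword l = 0; l < L; ++l) {
    mat Xf = join_rows(Xc, A.col(l), D.col(l));
    mat Zf = join_rows(Zc, A.col(l), D.col(l));

    if (do_slm && slm0_ok) {
      vec coef1;
      if (wls(Xf, y, unit, coef1)) {
        double rss1 = accu(square(y - Xf * coef1));
        if (rss1 / n > 1e-12) {
          lod(l) = 0.5 * n * std::log10(rss0 / rss1);
          if (lod(l) < 0) lod(l) = 0.0;
          valid(l, 0) = 1;
        }
      }
    }

    if (need_dglm_full) {
      Fit full = dglm_fit(y, Xf, Zf, tol, maxit);
      if (full.ok && !full.degenerate) {
        if (do_m) {
          Fit nm = dglm_fit(y, Xc, Zf, tol, maxit);
          if (nm.ok && !nm.degenerate) {
            bool v = true;
            lr_m(l) = lr_from(full.ll, nm.ll, v);
            valid(l, 1) = v ? 1 : 0;
          }
        }
        if (do_v) {
          Fit nv = dglm_fit(y, Xf, Zc, tol, maxit);
          if (nv.ok && !nv.degenerate) {
            bool v = true;
            lr_v(l) = lr_from(full.ll, nv.ll, v);
            valid(l, 2) = v ? 1 : 0;
          }
        }
        if (do_mv && mv0_ok) {
          bool v = true;
          lr_mv(l) = lr_from(full.ll, null_mv.ll, v);
          valid(l, 3) = v ? 1 : 0;
        }
      }
    }
  }
  return Rcpp::List::create(
    Rcpp::Named("lod_slm") = lod,
    Rcpp::Named("lr_mqtl") = lr_m,
    Rcpp::Named("lr_vqtl") = lr_v,
    Rcpp::Named("lr_mvqtl") = lr_mv,
    Rcpp::Named("valid") = valid);
}

// Structured permutations. One relabeling per permutation, applied to the
// whole-genome genotype information: perms is an n x P matrix of 0-based
// row indices. Phenotype and covariates are never permuted. test codes:
// 0 = slm, 1 = mqtl (relabel mean-submodel locus terms only),
// 2 = vqtl (relabel variance-submodel locus terms only), 3 = mvqtl.
// Returns the genome-wide maximum statistic per permutation (LOD for slm,
// LR otherwise); invalid locus fits are excluded from the maxima.
// [[Rcpp::export]]
arma::vec cpp_perm_max(const arma::vec& y, const arma::mat& Xc,
                       const arma::mat& Zc, const arma::mat& A,
                       const arma::mat& D, const arma::umat& perms,
                       int test, double tol = 1e-10, int maxit = 50) {
  const uword L = A.n_cols, P = perms.n_cols;
  const double n = (double)y.n_elem;
  vec unit(y.n_elem, fill::ones);
  vec maxima(P, fill::value(-datum::inf));

  double rss0 = NA_REAL;
  if (test == 0) {
    vec coef0;
    if (!wls(Xc, y, unit, coef0)) Rcpp::stop("rank-deficient null design");
    rss0 = accu(square(y - Xc * coef0));
  }

  Fit null_mv;
  if (test == 3) {
    null_mv = dglm_fit(y, Xc, Zc, tol, maxit);
    if (!null_mv.ok || null_mv.degenerate)
      Rcpp::stop("null model fit failed in permutation scan");
  }

  // Loci outer, permutations inner: the locus designs are allocated once
  // and only their genotype columns are overwritten per permutation, and
  // each permutation's full fit warm-starts from the previous one at the
  // same locus. Null fits that involve no permuted genotype terms are
  // computed once per locus and reused across all permutations.
  maxima.fill(-datum::inf);
  const uword pc = Xc.n_cols, qc = Zc.n_cols;

  for (uword l = 0; l < L; ++l) {
    vec a = A.col(l), d = D.col(l);
    mat Xf = join_rows(Xc, a, d);
    mat Zf = join_rows(Zc, a, d);

    double null_ll = NA_REAL;
    if (test == 1) {
      Fit nf = dglm_fit(y, Xc, Zf, tol, maxit);
      if (nf.ok && !nf.degenerate) null_ll = nf.ll;
      if (!std::isfinite(null_ll)) continue;
    } else if (test == 2) {
      Fit nf = dglm_fit(y, Xf, Zc, tol, maxit);
      if (nf.ok && !nf.degenerate) null_ll = nf.ll;
      if (!std::isfinite(null_ll)) continue;
    } else if (test == 3) {
      null_ll = null_mv.ll;
    }

    vec phi_warm;
    bool have_warm = false;
    for (uword p = 0; p < P; ++p) {
      uvec idx = perms.col(p);
      vec ap = a.elem(idx), dp = d.elem(idx);
      double stat = NA_REAL;
      if (test == 0) {
        Xf.col(pc) = ap;
        Xf.col(pc + 1) = dp;
        vec coef1;
        if (wls(Xf, y, unit, coef1)) {
          double rss1 = accu(square(y - Xf * coef1));
          if (rss1 / n > 1e-12) {
            stat = 0.5 * n * std::log10(rss0 / rss1);
            if (stat < 0) stat = 0.0;
          }
        }
      } else {
        if (test == 1 || test == 3) {
          Xf.col(pc) = ap;
          Xf.col(pc + 1) = dp;
        }
        if (test == 2 || test == 3) {
          Zf.col(qc) = ap;
          Zf.col(qc + 1) = dp;
        }
        Fit full = dglm_fit(y, Xf, Zf, tol, maxit,
                            have_warm ? &phi_warm : nullptr);
        if (full.ok && !full.degenerate) {
          bool v = true;
          stat = lr_from(full.ll, null_ll, v);
          if (!v) stat = NA_REAL;
          phi_warm = full.phi;
          have_warm = true;
        } else {
          have_warm = false;
        }
      }
      if (std::isfinite(stat) && stat > maxima(p)) maxima(p) = stat;
    }
    Rcpp::checkUserInterrupt();
  }
  return maxima;
}

// Bootstrap localization: for each resample (0-based row indices), rescan
// one chromosome and record the position of the maximal statistic.
// test codes as in cpp_perm_max.
// [[Rcpp::export]]
arma::vec cpp_boot_peak(const arma::vec& y, const arma::mat& Xc,
                        const arma::mat& Zc, const arma::mat& A,
                        const arma::mat& D, const arma::vec& pos,
                        const arma::umat& boots, int test,
                        double tol = 1e-10, int maxit = 50) {
  const uword B = boots.n_cols;
  Rcpp::LogicalVector tests(4);
  tests[0] = test == 0; tests[1] = test == 1;
  tests[2] = test == 2; tests[3] = test == 3;
  vec peaks(B, fill::value(NA_REAL));
  for (uword b = 0; b < B; ++b) {
    uvec idx = boots.col(b);
    Rcpp::List sc = cpp_scan(y.elem(idx), Xc.rows(idx), Zc.rows(idx),
                             A.rows(idx), D.rows(idx), tests, tol, maxit);
    vec stat;
    if (test == 0) stat = Rcpp::as<vec>(sc["lod_slm"]);
    else if (test == 1) stat = Rcpp::as<vec>(sc["lr_mqtl"]);
    else if (test == 2) stat = Rcpp::as<vec>(sc["lr_vqtl"]);
    else stat = Rcpp::as<vec>(sc["lr_mvqtl"]);
    stat.replace(datum::nan, -datum::inf);
    if (stat.max() > -datum::inf) peaks(b) = pos(stat.index_max());
    if (b % 32 == 0) Rcpp::checkUserInterrupt();
  }
  return peaks;
}
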