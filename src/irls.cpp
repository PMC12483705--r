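// IRLS M-regression core: weighted least-squares iterations, MAD scale,
// nonparametric tau^2 curves, data-driven tuning-constant selection, and a
// case bootstrap of the indirect effect. Kept in C++ because simulation
// studies re-fit the three mediation equations hundreds of thousands of
// times inside bootstrap loops; the bootstrap path uses a "light" mode
// (single OLS start, warm-started refit, no objective bookkeeping).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double MAD_CONST = 1.4826022185056018;   // 1 / qnorm(0.75)
static const double MEANABS_CONST = 1.2533141373155003; // sqrt(pi / 2)
static const double LAD_WEIGHT_CAP = 1e6;

enum LossCode { LOSS_LS = 0, LOSS_HUBER = 1, LOSS_LAD = 2 };

static double mad_scale_arma(const arma::vec& r) {
  const double med = arma::median(r);
  return MAD_CONST * arma::median(arma::abs(r - med));
}

// [[Rcpp::export]]
double cpp_mad_scale(const arma::vec& r) {
  return mad_scale_arma(r);
}

static double rho_val(double u, int loss, double k) {
  const double au = std::fabs(u);
  switch (loss) {
  case LOSS_LS: return 0.5 * u * u;
  case LOSS_LAD: return au;
  default: return (au <= k) ? 0.5 * u * u : k * au - 0.5 * k * k;
  }
}

static double weight_val(double u, int loss, double k) {
  const double au = std::fabs(u);
  switch (loss) {
  case LOSS_LS: return 1.0;
  case LOSS_LAD: return (au < 1.0 / LAD_WEIGHT_CAP) ? LAD_WEIGHT_CAP : 1.0 / au;
  default: return (au <= k) ? 1.0 : k / au;
  }
}

static double objective_val(const arma::vec& r, double s, int loss, double k) {
  double obj = 0.0;
  for (arma::uword i = 0; i < r.n_elem; ++i) obj += rho_val(r(i) / s, loss, k);
  return obj;
}

static bool wls_solve(const arma::mat& X, const arma::vec& y,
                      const arma::vec& w, arma::vec& beta) {
  const arma::vec sw = arma::sqrt(w);
  const arma::mat Xw = X.each_col() % sw;
  const arma::vec yw = y % sw;
  return arma::solve(beta, Xw.t() * Xw, Xw.t() * yw,
                     arma::solve_opts::no_approx);
}

struct FitResult {
  arma::vec beta;
  arma::vec resid;
  double scale;
  double objective;
  int n_iter;
  bool converged;
  int obj_violations;
  int start_index;
  bool ok;
};

// One IRLS run from a single start. fixed_scale > 0 freezes the scale;
// otherwise the MAD scale is re-estimated from the residuals at every
// iteration. light mode skips the objective-monotonicity bookkeeping.
static FitResult irls_single(const arma::mat& X, const arma::vec& y,
                             int loss, double k, arma::vec beta,
                             double tol, int max_iter, double fixed_scale,
                             bool light) {
  FitResult out;
  out.ok = true;
  out.obj_violations = 0;
  out.converged = false;
  out.start_index = 0;
  const double ytol = 1e-10 * std::max(1.0, arma::max(arma::abs(y)));

  arma::vec r = y - X * beta;
  arma::vec w(r.n_elem), beta_new;
  int iter = 0;
  double s = 1.0;
  for (iter = 1; iter <= max_iter; ++iter) {
    if (fixed_scale > 0.0) {
      s = fixed_scale;
    } else {
      s = mad_scale_arma(r);
      if (s <= 0.0) {
        if (arma::max(arma::abs(r)) < ytol) {
          // exact interpolation: any loss with rho(0)=0 is minimized here
          out.beta = beta; out.resid = r; out.scale = 0.0;
          out.objective = 0.0; out.n_iter = iter; out.converged = true;
          return out;
        }
        s = MEANABS_CONST * arma::mean(arma::abs(r));
        if (s <= 0.0) { out.ok = false; return out; }
      }
    }
    double obj_before = 0.0;
    if (!light) obj_before = objective_val(r, s, loss, k);
    for (arma::uword i = 0; i < r.n_elem; ++i)
      w(i) = weight_val(r(i) / s, loss, k);
    if (!wls_solve(X, y, w, beta_new)) { out.ok = false; return out; }
    r = y - X * beta_new;
    if (!light) {
      const double obj_after = objective_val(r, s, loss, k);
      if (obj_after > obj_before + 1e-10 * (1.0 + std::fabs(obj_before)))
        ++out.obj_violations;
    }
    const double denom = std::max(1.0, arma::max(arma::abs(beta)));
    const double delta = arma::max(arma::abs(beta_new - beta)) / denom;
    beta = beta_new;
    if (delta < tol) { out.converged = true; break; }
  }
  if (fixed_scale > 0.0) {
    s = fixed_scale;
  } else {
    s = mad_scale_arma(r);
    if (s <= 0.0) {
      if (arma::max(arma::abs(r)) < ytol) {
        out.beta = beta; out.resid = r; out.scale = 0.0;
        out.objective = 0.0; out.n_iter = iter; out.converged = true;
        return out;
      }
      s = MEANABS_CONST * arma::mean(arma::abs(r));
    }
  }
  out.beta = beta;
  out.resid = r;
  out.scale = s;
  out.objective = objective_val(r, s, loss, k);
  out.n_iter = std::min(iter, max_iter);
  return out;
}

static bool ols_solve(const arma::mat& X, const arma::vec& y, arma::vec& beta) {
  return arma::solve(beta, X.t() * X, X.t() * y, arma::solve_opts::no_approx);
}

// Default starting points: OLS, plus (unless light) an LAD approximation
// reached by a short IRLS run with LAD weights from the OLS start.
static bool default_starts(const arma::mat& X, const arma::vec& y,
                           arma::mat& starts, bool light) {
  arma::vec ols;
  if (!ols_solve(X, y, ols)) return false;
  if (light) {
    starts.set_size(X.n_cols, 1);
    starts.col(0) = ols;
    return true;
  }
  FitResult lad = irls_single(X, y, LOSS_LAD, 0.0, ols, 1e-6, 25, -1.0, true);
  starts.set_size(X.n_cols, lad.ok ? 2 : 1);
  starts.col(0) = ols;
  if (lad.ok) starts.col(1) = lad.beta;
  return true;
}

// Best-of-starts fit; S with zero columns requests the default starts.
static FitResult fit_core(const arma::mat& X, const arma::vec& y, int loss,
                          double k, const arma::mat& S_in, double tol,
                          int max_iter, double fixed_scale, bool light) {
  FitResult best;
  best.ok = false;

  if (loss == LOSS_LS) {
    arma::vec beta;
    if (!ols_solve(X, y, beta)) return best;
    best.beta = beta;
    best.resid = y - X * beta;
    best.scale = mad_scale_arma(best.resid);
    if (best.scale <= 0.0 && arma::max(arma::abs(best.resid)) > 1e-10)
      best.scale = MEANABS_CONST * arma::mean(arma::abs(best.resid));
    best.objective = best.scale > 0.0 ?
      objective_val(best.resid, best.scale, loss, k) : 0.0;
    best.n_iter = 1;
    best.converged = true;
    best.obj_violations = 0;
    best.start_index = 0;
    best.ok = true;
    return best;
  }

  arma::mat S = S_in;
  if (S.n_cols == 0 && !default_starts(X, y, S, light)) return best;

  for (arma::uword j = 0; j < S.n_cols; ++j) {
    FitResult fit = irls_single(X, y, loss, k, S.col(j), tol, max_iter,
                                fixed_scale, light);
    if (!fit.ok) continue;
    if (!best.ok || fit.objective < best.objective) {
      best = fit;
      best.start_index = static_cast<int>(j);
    }
  }
  return best;
}

static List fit_to_list(const FitResult& best) {
  return List::create(
    _["coefficients"] = NumericVector(best.beta.begin(), best.beta.end()),
    _["residuals"] = NumericVector(best.resid.begin(), best.resid.end()),
    _["scale"] = best.scale,
    _["objective"] = best.objective,
    _["n_iter"] = best.n_iter,
    _["converged"] = best.converged,
    _["start_index"] = best.start_index,
    _["obj_violations"] = best.obj_violations);
}

// starts: p x S matrix of initial coefficient vectors; S = 0 requests the
// default starts. fixed_scale <= 0 means the scale is iterated.
// [[Rcpp::export]]
List cpp_irls_fit(const arma::mat& X, const arma::vec& y, int loss, double k,
                  const arma::mat& starts, double tol, int max_iter,
                  double fixed_scale) {
  if (X.n_rows != y.n_elem) stop("design and response dimensions disagree");
  if (X.n_rows <= X.n_cols) stop("need more observations than coefficients");
  if (starts.n_cols > 0 && starts.n_rows != X.n_cols)
    stop("starting values have the wrong length");
  FitResult best = fit_core(X, y, loss, k, starts, tol, max_iter,
                            fixed_scale, false);
  if (!best.ok)
    stop(loss == LOSS_LS ? "design matrix is rank deficient" :
           "IRLS failed from every starting point (degenerate fit)");
  return fit_to_list(best);
}

// tau^2(k) over a sorted |u| with prefix sums; NaN where fewer than
// min_inside values satisfy |u| <= k (the denominator is then missing or
// too noisy to minimize over).
static void tau2_curve_core(const arma::vec& u, const arma::vec& grid,
                            arma::vec& out, arma::uword min_inside) {
  const arma::uword n = u.n_elem;
  arma::vec a = arma::sort(arma::abs(u));
  arma::vec prefix(n + 1);
  prefix(0) = 0.0;
  for (arma::uword i = 0; i < n; ++i) prefix(i + 1) = prefix(i) + a(i) * a(i);
  out.set_size(grid.n_elem);
  for (arma::uword g = 0; g < grid.n_elem; ++g) {
    const double k = grid(g);
    const arma::uword idx = std::upper_bound(a.begin(), a.end(), k) - a.begin();
    if (idx < std::max<arma::uword>(min_inside, 1)) {
      out(g) = arma::datum::nan;
      continue;
    }
    const double epsi2 = (prefix(idx) + k * k * (n - idx)) / n;
    const double epsip = static_cast<double>(idx) / n;
    out(g) = epsi2 / (epsip * epsip);
  }
}

// Nonparametric tau^2(k) curve from standardized residuals u:
// mean(psi(u,k)^2) / mean(1{|u| <= k})^2, NA where no |u| <= k.
// [[Rcpp::export]]
NumericVector cpp_tau2_curve(const arma::vec& u, const arma::vec& grid,
                             int min_inside = 1) {
  arma::vec out;
  tau2_curve_core(u, grid, out, std::max(min_inside, 1));
  NumericVector res(out.n_elem);
  for (arma::uword g = 0; g < out.n_elem; ++g)
    res[g] = std::isnan(out(g)) ? NA_REAL : out(g);
  return res;
}

// Largest grid index attaining the minimum of the finite curve values;
// -1 when fewer than min_finite finite values exist.
static int curve_argmin(const arma::vec& curve, int min_finite) {
  int n_finite = 0, best = -1;
  double best_val = 0.0;
  for (arma::uword g = 0; g < curve.n_elem; ++g) {
    if (!std::isfinite(curve(g))) continue;
    ++n_finite;
    if (best < 0 || curve(g) <= best_val) {
      best = static_cast<int>(g);
      best_val = curve(g);
    }
  }
  if (n_finite < min_finite) return -1;
  return best;
}

struct AutoResult {
  FitResult fit;
  double k_hat;
  double tau2_hat;
  bool fallback;
  arma::vec curve;
};

// Data-driven Huber fit of one equation: initial fit at k_init, tuning
// constant selected by minimizing the nonparametric tau^2 curve on the
// standardized residuals, then a refit at the selected k (warm-started
// from the initial fit in light mode).
static AutoResult auto_core(const arma::mat& X, const arma::vec& y,
                            double k_init, const arma::vec& grid, int min_n,
                            double fallback_k, double min_prop_inside,
                            double tol, int max_iter, int refine_rounds,
                            bool light, bool keep_curve) {
  AutoResult out;
  out.k_hat = fallback_k;
  out.tau2_hat = arma::datum::nan;
  out.fallback = false;

  const arma::mat no_starts(X.n_cols, 0);
  out.fit = fit_core(X, y, LOSS_HUBER, k_init, no_starts, tol, max_iter,
                     -1.0, light);
  if (!out.fit.ok) return out;

  const int n = static_cast<int>(X.n_rows);
  const arma::uword min_inside = std::max<arma::uword>(
    2, static_cast<arma::uword>(std::ceil(min_prop_inside * n)));
  arma::vec curve;
  for (int round = 0; round < refine_rounds; ++round) {
    if (out.fit.scale <= 0.0 || n < min_n) { out.fallback = true; break; }
    tau2_curve_core(out.fit.resid / out.fit.scale, grid, curve, min_inside);
    const int best = curve_argmin(curve, 2);
    if (keep_curve) out.curve = curve;
    if (best < 0) { out.fallback = true; break; }
    out.k_hat = grid(best);
    out.tau2_hat = curve(best);
    arma::mat warm = light ?
      arma::mat(out.fit.beta) : arma::mat(X.n_cols, 0);
    FitResult refit = fit_core(X, y, LOSS_HUBER, out.k_hat, warm, tol,
                               max_iter, -1.0, light);
    if (!refit.ok) break;
    out.fit = refit;
  }
  if (out.fallback) {
    out.k_hat = fallback_k;
    out.tau2_hat = arma::datum::nan;
    if (std::fabs(k_init - fallback_k) > 1e-12) {
      FitResult refit = fit_core(X, y, LOSS_HUBER, fallback_k, no_starts,
                                 tol, max_iter, -1.0, light);
      if (refit.ok) out.fit = refit;
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_fit_eq_auto(const arma::mat& X, const arma::vec& y, double k_init,
                     const arma::vec& grid, int min_n, double fallback_k,
                     double min_prop_inside, double tol, int max_iter,
                     int refine_rounds, bool return_curve) {
  if (X.n_rows != y.n_elem) stop("design and response dimensions disagree");
  if (X.n_rows <= X.n_cols) stop("need more observations than coefficients");
  AutoResult res = auto_core(X, y, k_init, grid, min_n, fallback_k,
                             min_prop_inside, tol, max_iter, refine_rounds,
                             false, return_curve);
  if (!res.fit.ok)
    stop("IRLS failed from every starting point (degenerate fit)");
  NumericVector curve(0);
  if (return_curve && res.curve.n_elem == grid.n_elem) {
    curve = NumericVector(grid.n_elem);
    for (arma::uword g = 0; g < grid.n_elem; ++g)
      curve[g] = std::isnan(res.curve(g)) ? NA_REAL : res.curve(g);
  }
  return List::create(_["fit"] = fit_to_list(res.fit),
                      _["k_hat"] = res.k_hat,
                      _["tau2_hat"] = std::isnan(res.tau2_hat) ?
                        NA_REAL : res.tau2_hat,
                      _["fallback_used"] = res.fallback,
                      _["curve"] = curve);
}

// Case bootstrap of the indirect effect. Each resample refits the mediator
// and outcome equations (and the total-effect equation when want_diff) with
// the requested loss; k_fixed < 0 requests per-resample data-driven
// selection. Uses the R RNG so results are governed by set.seed().
// [[Rcpp::export]]
List cpp_boot_ab(const arma::vec& x, const arma::vec& m, const arma::vec& y,
                 const arma::mat& covariates, int B, int loss, double k_fixed,
                 const arma::vec& grid, int min_n, double fallback_k,
                 double min_prop_inside, double tol, int max_iter,
                 bool want_diff) {
  const arma::uword n = x.n_elem;
  const arma::uword q = covariates.n_cols;
  RNGScope scope;

  NumericVector ab(B), cdiff(want_diff ? B : 0);
  int redraws = 0;
  const int max_redraws = static_cast<int>(std::ceil(0.1 * B)) + 10;
  const bool auto_k = (loss == LOSS_HUBER && k_fixed < 0.0);

  arma::mat Xm(n, 2 + q), Xy(n, 3 + q), Xt(n, 2 + q);
  arma::vec mm(n), yy(n);

  for (int b = 0; b < B; ++b) {
    bool ok = false;
    while (!ok) {
      for (arma::uword i = 0; i < n; ++i) {
        const arma::uword j =
          std::min<arma::uword>(n - 1,
                                static_cast<arma::uword>(unif_rand() * n));
        Xm(i, 0) = 1.0; Xm(i, 1) = x(j);
        Xy(i, 0) = 1.0; Xy(i, 1) = x(j); Xy(i, 2) = m(j);
        for (arma::uword c = 0; c < q; ++c) {
          Xm(i, 2 + c) = covariates(j, c);
          Xy(i, 3 + c) = covariates(j, c);
        }
        mm(i) = m(j);
        yy(i) = y(j);
      }
      double a_hat, b_hat, cp_hat;
      bool fit_ok = true;
      if (auto_k) {
        AutoResult fa = auto_core(Xm, mm, fallback_k, grid, min_n,
                                  fallback_k, min_prop_inside, tol, max_iter,
                                  1, true, false);
        AutoResult fb = auto_core(Xy, yy, fallback_k, grid, min_n,
                                  fallback_k, min_prop_inside, tol, max_iter,
                                  1, true, false);
        fit_ok = fa.fit.ok && fb.fit.ok;
        if (fit_ok) {
          a_hat = fa.fit.beta(1);
          b_hat = fb.fit.beta(2);
          cp_hat = fb.fit.beta(1);
        }
      } else {
        const arma::mat ns_m(Xm.n_cols, 0), ns_y(Xy.n_cols, 0);
        FitResult fa = fit_core(Xm, mm, loss, k_fixed, ns_m, tol, max_iter,
                                -1.0, true);
        FitResult fb = fit_core(Xy, yy, loss, k_fixed, ns_y, tol, max_iter,
                                -1.0, true);
        fit_ok = fa.ok && fb.ok;
        if (fit_ok) {
          a_hat = fa.beta(1);
          b_hat = fb.beta(2);
          cp_hat = fb.beta(1);
        }
      }
      double c_hat = 0.0;
      if (fit_ok && want_diff) {
        Xt.col(0) = Xm.col(0);
        Xt.col(1) = Xm.col(1);
        if (q > 0) Xt.cols(2, 1 + q) = Xm.cols(2, 1 + q);
        if (auto_k) {
          AutoResult fc = auto_core(Xt, yy, fallback_k, grid, min_n,
                                    fallback_k, min_prop_inside, tol,
                                    max_iter, 1, true, false);
          fit_ok = fc.fit.ok;
          if (fit_ok) c_hat = fc.fit.beta(1);
        } else {
          const arma::mat ns_t(Xt.n_cols, 0);
          FitResult fc = fit_core(Xt, yy, loss, k_fixed, ns_t, tol, max_iter,
                                  -1.0, true);
          fit_ok = fc.ok;
          if (fit_ok) c_hat = fc.beta(1);
        }
      }
      if (!fit_ok) {
        ++redraws;
        if (redraws > max_redraws)
          stop("too many rank-deficient bootstrap resamples (%d redraws)",
               redraws);
        continue;
      }
      ab[b] = a_hat * b_hat;
      if (want_diff) cdiff[b] = c_hat - cp_hat;
      ok = true;
    }
  }
  return List::create(_["ab"] = ab, _["cdiff"] = cdiff,
                      _["redraws"] = redraws);
}
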