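// Hot loop for AFS feasibility tests.
//
// A candidate AFS point x (s = 3) is feasible when some completion W of the
// transform matrix T = [1 x; 1 W] yields factors C = U*Sigma*inv(T),
// S = V*T' whose columns are nonnegative up to the relative tolerance eps.
// The inner minimization over the four entries of W is a plain Nelder-Mead
// with a multi-start schedule supplied from R.  This file exists because the
// boundary tracing and the grid oracle evaluate this inner problem tens of
// thousands of times.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double SINGULAR_SENTINEL = 1e12;

// Sum of squared relative-negativity shortfalls over the columns of M.
// shortfall(col) = max(0, -min(col)/max(abs(col)) - eps)
static double shortfall_sq(const arma::mat& M, double eps) {
  double tot = 0.0;
  for (arma::uword j = 0; j < M.n_cols; ++j) {
    double mn = M.col(j).min();
    double mx = arma::abs(M.col(j)).max();
    if (mx <= 0.0) continue;           // all-zero profile: no violation
    double sh = -mn / mx - eps;
    if (sh > 0.0) tot += sh * sh;
  }
  return tot;
}

static double violation_T(const arma::mat& US, const arma::mat& V,
                          const arma::mat& T, double eps) {
  arma::mat Tinv;
  bool ok = arma::inv(Tinv, T);
  if (!ok) return SINGULAR_SENTINEL;
  double nrm = arma::norm(Tinv, "fro");
  if (!std::isfinite(nrm) || nrm > 1e14) return SINGULAR_SENTINEL;
  arma::mat C = US * Tinv;
  arma::mat S = V * T.t();
  return shortfall_sq(C, eps) + shortfall_sq(S, eps);
}

// [[Rcpp::export(name = ".cpp_violation")]]
double cpp_violation(const arma::mat& US, const arma::mat& V,
                     const arma::mat& T, double eps) {
  return violation_T(US, V, T, eps);
}

// Specialized s = 3 violation with a closed-form 3x3 inverse and on-the-fly
// column min/max; avoids all heap allocation (this is the innermost loop).
static double viol3(const double* US, int k, const double* V, int n,
                    const double T[3][3], double eps) {
  // adjugate / determinant inverse of T
  double a = T[0][0], b = T[0][1], c = T[0][2];
  double d = T[1][0], e = T[1][1], f = T[1][2];
  double g = T[2][0], h = T[2][1], i = T[2][2];
  double A = e * i - f * h, B = c * h - b * i, C = b * f - c * e;
  double D = f * g - d * i, E = a * i - c * g, F = c * d - a * f;
  double G = d * h - e * g, H = b * g - a * h, I = a * e - b * d;
  double det = a * A + d * B + g * C;
  double scale = std::abs(a) + std::abs(b) + std::abs(c) + std::abs(e) +
                 std::abs(f) + std::abs(h) + std::abs(i);
  if (std::abs(det) <= 1e-14 * scale * scale * scale + 1e-300)
    return SINGULAR_SENTINEL;
  double Ti[3][3] = {{A / det, B / det, C / det},
                     {D / det, E / det, F / det},
                     {G / det, H / det, I / det}};
  double tot = 0.0;
  // columns of C = US * inv(T)
  for (int j = 0; j < 3; ++j) {
    double t0 = Ti[0][j], t1 = Ti[1][j], t2 = Ti[2][j];
    double mn = R_PosInf, mx = 0.0;
    for (int r = 0; r < k; ++r) {
      double v = US[r] * t0 + US[r + k] * t1 + US[r + 2 * k] * t2;
      if (v < mn) mn = v;
      double av = std::abs(v);
      if (av > mx) mx = av;
    }
    if (mx > 0.0) {
      double sh = -mn / mx - eps;
      if (sh > 0.0) tot += sh * sh;
    }
  }
  // columns of S = V * T' (column j is V times row j of T)
  for (int j = 0; j < 3; ++j) {
    double t0 = T[j][0], t1 = T[j][1], t2 = T[j][2];
    double mn = R_PosInf, mx = 0.0;
    for (int r = 0; r < n; ++r) {
      double v = V[r] * t0 + V[r + n] * t1 + V[r + 2 * n] * t2;
      if (v < mn) mn = v;
      double av = std::abs(v);
      if (av > mx) mx = av;
    }
    if (mx > 0.0) {
      double sh = -mn / mx - eps;
      if (sh > 0.0) tot += sh * sh;
    }
  }
  return tot;
}

// Objective in the four W entries for a fixed first row (1, x).
static double obj_w(const arma::mat& US, const arma::mat& V,
                    const arma::vec& x, const arma::vec& w, double eps) {
  double T[3][3] = {{1.0, x(0), x(1)},
                    {1.0, w(0), w(1)},
                    {1.0, w(2), w(3)}};
  return viol3(US.memptr(), US.n_rows, V.memptr(), V.n_rows, T, eps);
}

// Nelder-Mead on f(w), w in R^4, early exit when best <= target.
static double nelder_mead(const arma::mat& US, const arma::mat& V,
                          const arma::vec& x, arma::vec& w, double eps,
                          double target, int maxit) {
  const int n = 4;
  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sigma = 0.5;
  arma::mat simplex(n, n + 1);
  arma::vec fval(n + 1);
  simplex.col(0) = w;
  fval(0) = obj_w(US, V, x, w, eps);
  for (int i = 0; i < n; ++i) {
    arma::vec p = w;
    double step = 0.25 * (1.0 + std::abs(p(i)));
    p(i) += step;
    simplex.col(i + 1) = p;
    fval(i + 1) = obj_w(US, V, x, p, eps);
  }
  for (int it = 0; it < maxit; ++it) {
    arma::uvec ord = arma::sort_index(fval);
    simplex = simplex.cols(ord);
    fval = fval(ord);
    if (fval(0) <= target) break;
    if (fval(n) - fval(0) <= 1e-14 * (1.0 + std::abs(fval(0)))) break;

    arma::vec centroid = arma::mean(simplex.cols(0, n - 1), 1);
    arma::vec xr = centroid + alpha * (centroid - simplex.col(n));
    double fr = obj_w(US, V, x, xr, eps);
    if (fr < fval(0)) {
      arma::vec xe = centroid + gamma * (xr - centroid);
      double fe = obj_w(US, V, x, xe, eps);
      if (fe < fr) { simplex.col(n) = xe; fval(n) = fe; }
      else         { simplex.col(n) = xr; fval(n) = fr; }
    } else if (fr < fval(n - 1)) {
      simplex.col(n) = xr; fval(n) = fr;
    } else {
      arma::vec xc = centroid + rho * (simplex.col(n) - centroid);
      double fc = obj_w(US, V, x, xc, eps);
      if (fc < fval(n)) { simplex.col(n) = xc; fval(n) = fc; }
      else {
        for (int i = 1; i <= n; ++i) {
          simplex.col(i) = simplex.col(0) + sigma * (simplex.col(i) - simplex.col(0));
          fval(i) = obj_w(US, V, x, simplex.col(i), eps);
        }
      }
    }
  }
  arma::uword ib = fval.index_min();
  w = simplex.col(ib);
  return fval(ib);
}

// Lower bound on the violation that is independent of W: the first spectrum
// S(:,1) = V * (1, x)' is fixed by x alone, and its shortfall term appears
// in every completion's violation.
static double lower_bound_x(const arma::mat& V, const arma::vec& x,
                            double eps) {
  arma::vec s1 = V.col(0) + x(0) * V.col(1) + x(1) * V.col(2);
  double mn = s1.min();
  double mx = arma::abs(s1).max();
  if (mx <= 0.0) return 0.0;
  double sh = -mn / mx - eps;
  return (sh > 0.0) ? sh * sh : 0.0;
}

// Multi-start inner minimization for one point.  starts: 4 x m matrix of W
// start vectors (column-major W entries); warm (length 4) is tried first
// when has_warm is true.
// [[Rcpp::export(name = ".cpp_point_feasible")]]
List cpp_point_feasible(const arma::mat& US, const arma::mat& V,
                        const arma::vec& x, double eps, double delta,
                        const arma::mat& starts,
                        const arma::vec& warm, bool has_warm,
                        int maxit) {
  double target = delta * delta;
  double lb = lower_bound_x(V, x, eps);
  if (lb > target) {
    return List::create(_["feasible"] = false, _["value"] = lb,
                        _["w"] = R_NilValue, _["pruned"] = true);
  }
  double best = R_PosInf;
  arma::vec wbest(4, arma::fill::zeros);
  int m = starts.n_cols;
  for (int k = -1; k < m; ++k) {
    arma::vec w;
    if (k < 0) {
      if (!has_warm) continue;
      w = warm;
    } else {
      w = starts.col(k);
    }
    double f = nelder_mead(US, V, x, w, eps, target, maxit);
    if (f < best) { best = f; wbest = w; }
    if (best <= target) break;
  }
  return List::create(_["feasible"] = (best <= target), _["value"] = best,
                      _["w"] = wbest, _["pruned"] = false);
}

// Batch version for grid scans; chains the last successful W as a warm
// start for the next point (grid neighbours have similar completions).
// [[Rcpp::export(name = ".cpp_points_feasible")]]
List cpp_points_feasible(const arma::mat& US, const arma::mat& V,
                         const arma::mat& X, double eps, double delta,
                         const arma::mat& starts, int maxit) {
  int npt = X.n_rows;
  double target = delta * delta;
  LogicalVector feas(npt);
  NumericVector val(npt);
  arma::vec warm(4, arma::fill::zeros);
  bool has_warm = false;
  int m = starts.n_cols;
  for (int i = 0; i < npt; ++i) {
    arma::vec x = X.row(i).t();
    double lb = lower_bound_x(V, x, eps);
    if (lb > target) { feas[i] = false; val[i] = lb; continue; }
    double best = R_PosInf;
    arma::vec wbest(4, arma::fill::zeros);
    for (int k = -1; k < m; ++k) {
      arma::vec w;
      if (k < 0) {
        if (!has_warm) continue;
        w = warm;
      } else {
        w = starts.col(k);
      }
      double f = nelder_mead(US, V, x, w, eps, target, maxit);
      if (f < best) { best = f; wbest = w; }
      if (best <= target) break;
    }
    feas[i] = (best <= target);
    val[i] = best;
    if (feas[i]) { warm = wbest; has_warm = true; }
  }
  return List::create(_["feasible"] = feas, _["value"] = val);
}
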