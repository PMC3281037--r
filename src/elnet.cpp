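// Elastic-net residualization backend.
//
// Per feature: coordinate-descent elastic net of y on a shared design X
// (top-K expression PCs + covariates), objective
//   (1/2n) ||yc - Xc b||^2 + lambda1 ||b||_1 + (lambda2/2) ||b||^2
// on centered data (intercept handled by centering). lambda2 runs over a
// discrete grid, lambda1 over a log-spaced path; the pair is chosen by
// cross-validated squared prediction error (leave-one-out by default).
// The final fit is a relaxed refit: OLS (ridge epsilon-free) on the
// support selected by the chosen elastic net, so that exact linear
// dependence on the design yields exactly zero residuals.
//
// All fold computations use downdated Gram sums, so cost per fold is
// O(p^2 * path) regardless of n.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double soft(double z, double g) {
  if (z > g) return z - g;
  if (z < -g) return z + g;
  return 0.0;
}

// coordinate descent on centered Gram sums:
// Gc (p x p), Xyc (p), n_tr; beta updated in place
static void cd_solve(const std::vector<double>& Gc,
                     const std::vector<double>& Xyc,
                     int p, double n_tr, double lambda1, double lambda2,
                     std::vector<double>& beta, int maxit, double tol) {
  for (int it = 0; it < maxit; ++it) {
    double maxd = 0.0;
    for (int j = 0; j < p; ++j) {
      double gj = 0.0;
      for (int k = 0; k < p; ++k) gj += Gc[j * p + k] * beta[k];
      double cj = (Xyc[j] - gj + Gc[j * p + j] * beta[j]) / n_tr;
      double denom = Gc[j * p + j] / n_tr + lambda2;
      double bnew = denom > 0 ? soft(cj, lambda1) / denom : 0.0;
      double d = std::fabs(bnew - beta[j]);
      if (d > maxd) maxd = d;
      beta[j] = bnew;
    }
    if (maxd < tol) break;
  }
}

// OLS on the support of beta via Gauss elimination on the centered Gram.
// ws_* are caller-provided workspaces of size >= p*p / p.
static void relaxed_refit(const std::vector<double>& Gc,
                          const std::vector<double>& Xyc,
                          int p, const std::vector<double>& beta_en,
                          std::vector<double>& beta_out,
                          std::vector<double>& A, std::vector<double>& b,
                          std::vector<double>& x, std::vector<int>& sup) {
  sup.clear();
  for (int j = 0; j < p; ++j) if (beta_en[j] != 0.0) sup.push_back(j);
  std::fill(beta_out.begin(), beta_out.end(), 0.0);
  int s = (int)sup.size();
  if (s == 0) return;
  for (int a = 0; a < s; ++a) {
    b[a] = Xyc[sup[a]];
    for (int c = 0; c < s; ++c) A[a * s + c] = Gc[sup[a] * p + sup[c]];
  }
  // Gaussian elimination with partial pivoting; tiny ridge for singularity
  for (int a = 0; a < s; ++a) A[a * s + a] += 1e-10;
  for (int col = 0; col < s; ++col) {
    int piv = col;
    for (int r = col + 1; r < s; ++r)
      if (std::fabs(A[r * s + col]) > std::fabs(A[piv * s + col])) piv = r;
    if (piv != col) {
      for (int c = 0; c < s; ++c) std::swap(A[col * s + c], A[piv * s + c]);
      std::swap(b[col], b[piv]);
    }
    double d = A[col * s + col];
    if (std::fabs(d) < 1e-300) continue;
    for (int r = col + 1; r < s; ++r) {
      double f = A[r * s + col] / d;
      for (int c = col; c < s; ++c) A[r * s + c] -= f * A[col * s + c];
      b[r] -= f * b[col];
    }
  }
  std::fill(x.begin(), x.begin() + s, 0.0);
  for (int col = s - 1; col >= 0; --col) {
    double acc = b[col];
    for (int c = col + 1; c < s; ++c) acc -= A[col * s + c] * x[c];
    double d = A[col * s + col];
    x[col] = (std::fabs(d) > 1e-300) ? acc / d : 0.0;
  }
  for (int a = 0; a < s; ++a) beta_out[sup[a]] = x[a];
}

// [[Rcpp::export]]
List elnet_fit_cpp(NumericMatrix X, NumericVector y, double lambda1,
                   double lambda2, int maxit = 1000, double tol = 1e-9) {
  int n = X.nrow(), p = X.ncol();
  std::vector<double> mx(p, 0.0);
  double my = 0.0;
  for (int i = 0; i < n; ++i) my += y[i];
  my /= n;
  for (int j = 0; j < p; ++j) {
    for (int i = 0; i < n; ++i) mx[j] += X(i, j);
    mx[j] /= n;
  }
  std::vector<double> Gc(p * p, 0.0), Xyc(p, 0.0);
  for (int j = 0; j < p; ++j) {
    for (int k = 0; k <= j; ++k) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += (X(i, j) - mx[j]) * (X(i, k) - mx[k]);
      Gc[j * p + k] = s; Gc[k * p + j] = s;
    }
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += (X(i, j) - mx[j]) * (y[i] - my);
    Xyc[j] = s;
  }
  std::vector<double> beta(p, 0.0);
  cd_solve(Gc, Xyc, p, (double)n, lambda1, lambda2, beta, maxit, tol);
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["intercept"] = my);
}

// [[Rcpp::export]]
List elnet_residualize_cpp(NumericMatrix X, NumericMatrix Y,
                           NumericVector lambda2_grid, int n_lambda1,
                           double lambda1_min_ratio, IntegerVector foldid,
                           int maxit, double tol) {
  int n = X.nrow(), p = X.ncol(), m = Y.ncol();
  int L2 = lambda2_grid.size();
  int nfold = 0;
  for (int i = 0; i < n; ++i) if (foldid[i] + 1 > nfold) nfold = foldid[i] + 1;

  // full-data uncentered sums of X
  std::vector<double> Sxx(p * p, 0.0), Sx(p, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) {
      Sx[j] += X(i, j);
      for (int k = 0; k <= j; ++k) {
        Sxx[j * p + k] += X(i, j) * X(i, k);
      }
    }
  for (int j = 0; j < p; ++j)
    for (int k = j + 1; k < p; ++k) Sxx[j * p + k] = Sxx[k * p + j];

  NumericMatrix resid(n, m);
  IntegerVector l2_idx(m);
  NumericVector l1_chosen(m);

  std::vector<double> Gc(p * p), Xyc(p), Gc_tr(p * p), Xyc_tr(p);
  std::vector<double> beta(p), beta_warm(p), beta_fit(p);
  std::vector<double> wsA(p * p), wsb(p), wsx(p);
  std::vector<int> ws_sup; ws_sup.reserve(p);
  std::vector<double> Sx_tr(p), Sxx_tr(p * p), Sxy_tr(p);
  std::vector<int> held; held.reserve(n);

  for (int f = 0; f < m; ++f) {
    // full-data sums for this feature
    double Sy = 0.0;
    std::vector<double> Sxy(p, 0.0);
    for (int i = 0; i < n; ++i) {
      double yi = Y(i, f);
      Sy += yi;
      for (int j = 0; j < p; ++j) Sxy[j] += X(i, j) * yi;
    }
    double my = Sy / n;
    for (int j = 0; j < p; ++j) {
      double mxj = Sx[j] / n;
      Xyc[j] = Sxy[j] - mxj * Sy;
      for (int k = 0; k < p; ++k)
        Gc[j * p + k] = Sxx[j * p + k] - Sx[j] * Sx[k] / n;
    }
    // lambda1 path from the full data
    double lmax = 0.0;
    for (int j = 0; j < p; ++j) {
      double a = std::fabs(Xyc[j]) / n;
      if (a > lmax) lmax = a;
    }
    if (lmax <= 0) lmax = 1e-12;
    std::vector<double> path(n_lambda1);
    for (int t = 0; t < n_lambda1; ++t)
      path[t] = lmax * std::pow(lambda1_min_ratio,
                                (double)t / (double)(n_lambda1 - 1));
    path.push_back(0.0);  // unpenalized endpoint
    int T = (int)path.size();

    std::vector<double> cverr(L2 * T, 0.0);

    for (int fold = 0; fold < nfold; ++fold) {
      // training sums by downdating the full-data raw sums
      double Sy_tr = Sy; double n_tr = n;
      std::copy(Sx.begin(), Sx.end(), Sx_tr.begin());
      std::copy(Sxx.begin(), Sxx.end(), Sxx_tr.begin());
      std::copy(Sxy.begin(), Sxy.end(), Sxy_tr.begin());
      held.clear();
      for (int i = 0; i < n; ++i) if (foldid[i] == fold) held.push_back(i);
      if (held.empty()) continue;
      for (size_t h = 0; h < held.size(); ++h) {
        int i = held[h];
        double yi = Y(i, f);
        Sy_tr -= yi; n_tr -= 1.0;
        for (int j = 0; j < p; ++j) {
          Sx_tr[j] -= X(i, j);
          Sxy_tr[j] -= X(i, j) * yi;
          for (int k = 0; k < p; ++k) Sxx_tr[j * p + k] -= X(i, j) * X(i, k);
        }
      }
      if (n_tr < 2) continue;
      double my_tr = Sy_tr / n_tr;
      for (int j = 0; j < p; ++j) {
        Xyc_tr[j] = Sxy_tr[j] - (Sx_tr[j] / n_tr) * Sy_tr;
        for (int k = 0; k < p; ++k)
          Gc_tr[j * p + k] = Sxx_tr[j * p + k] - Sx_tr[j] * Sx_tr[k] / n_tr;
      }
      for (int l2 = 0; l2 < L2; ++l2) {
        std::fill(beta_warm.begin(), beta_warm.end(), 0.0);
        unsigned prev_support = 0xffffffffu;
        double fold_err = 0.0;
        for (int t = 0; t < T; ++t) {
          cd_solve(Gc_tr, Xyc_tr, p, n_tr, path[t], lambda2_grid[l2],
                   beta_warm, maxit, tol);
          // active-set bitmask; for p > 31 always refit
          unsigned support = 0;
          if (p < 32) {
            for (int j = 0; j < p; ++j)
              if (beta_warm[j] != 0.0) support |= (1u << j);
          } else {
            support = prev_support + 1u;
          }
          if (support != prev_support) {
            // relaxed refit + held-out error only when the active set moves
            relaxed_refit(Gc_tr, Xyc_tr, p, beta_warm, beta_fit,
                          wsA, wsb, wsx, ws_sup);
            fold_err = 0.0;
            for (size_t h = 0; h < held.size(); ++h) {
              int i = held[h];
              double pred = my_tr;
              for (int j = 0; j < p; ++j)
                pred += beta_fit[j] * (X(i, j) - Sx_tr[j] / n_tr);
              double e = Y(i, f) - pred;
              fold_err += e * e;
            }
            prev_support = support;
          }
          cverr[l2 * T + t] += fold_err;
        }
      }
    }
    // choose (lambda2, lambda1) minimizing CV error; prefer larger penalty
    int best_l2 = 0, best_t = 0;
    double best = R_PosInf;
    for (int l2 = 0; l2 < L2; ++l2)
      for (int t = 0; t < T; ++t)
        if (cverr[l2 * T + t] < best - 1e-12) {
          best = cverr[l2 * T + t]; best_l2 = l2; best_t = t;
        }
    // final fit on the full data with the chosen penalties, relaxed refit
    std::fill(beta.begin(), beta.end(), 0.0);
    for (int t = 0; t <= best_t; ++t)   // warm-started path down to chosen
      cd_solve(Gc, Xyc, p, (double)n, path[t], lambda2_grid[best_l2],
               beta, maxit, tol);
    relaxed_refit(Gc, Xyc, p, beta, beta_fit, wsA, wsb, wsx, ws_sup);
    for (int i = 0; i < n; ++i) {
      double fitv = 0.0;
      for (int j = 0; j < p; ++j) fitv += beta_fit[j] * (X(i, j) - Sx[j] / n);
      resid(i, f) = (Y(i, f) - my) - fitv;
    }
    l2_idx[f] = best_l2;
    l1_chosen[f] = path[best_t];
  }
  return List::create(_["residuals"] = resid,
                      _["lambda2_index"] = l2_idx,
                      _["lambda1"] = l1_chosen);
}
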