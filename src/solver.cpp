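#include <Rcpp.h>
using namespace Rcpp;

// Sparse kernels for the steady transport solves. Matrices arrive in CSR form
// (row pointers rp, sorted column indices ci, values val), 0-based.

static void matvec(const IntegerVector& rp, const IntegerVector& ci,
                   const NumericVector& v, const std::vector<double>& x,
                   std::vector<double>& y) {
  int n = rp.size() - 1;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = rp[i]; k < rp[i + 1]; ++k) s += v[k] * x[ci[k]];
    y[i] = s;
  }
}

// ILU(0): incomplete LU restricted to the sparsity pattern of A. Requires a
// structurally present diagonal in every row.
// [[Rcpp::export]]
List ilu0_factor(IntegerVector rp, IntegerVector ci, NumericVector val) {
  int n = rp.size() - 1;
  NumericVector lu = clone(val);
  IntegerVector diag_ptr(n, -1);
  std::vector<int> pos(n, -1);
  for (int i = 0; i < n; ++i) {
    for (int k = rp[i]; k < rp[i + 1]; ++k) pos[ci[k]] = k;
    for (int k = rp[i]; k < rp[i + 1]; ++k) {
      int c = ci[k];
      if (c >= i) break;
      int dk = diag_ptr[c];
      if (dk < 0 || lu[dk] == 0.0) stop("ILU(0): zero pivot at row %d", c + 1);
      double f = lu[k] / lu[dk];
      lu[k] = f;
      for (int kk = dk + 1; kk < rp[c + 1]; ++kk) {
        int p = pos[ci[kk]];
        if (p >= 0) lu[p] -= f * lu[kk];
      }
    }
    for (int k = rp[i]; k < rp[i + 1]; ++k) {
      if (ci[k] == i) diag_ptr[i] = k;
      pos[ci[k]] = -1;
    }
    if (diag_ptr[i] < 0) stop("ILU(0): missing diagonal entry in row %d", i + 1);
    if (lu[diag_ptr[i]] == 0.0) stop("ILU(0): zero pivot at row %d", i + 1);
  }
  return List::create(_["lu"] = lu, _["diag_ptr"] = diag_ptr);
}

static void ilu_solve(const IntegerVector& rp, const IntegerVector& ci,
                      const NumericVector& lu, const IntegerVector& dp,
                      const std::vector<double>& r, std::vector<double>& z) {
  int n = rp.size() - 1;
  for (int i = 0; i < n; ++i) {  // L z = r, unit lower triangle
    double s = r[i];
    for (int k = rp[i]; k < dp[i]; ++k) s -= lu[k] * z[ci[k]];
    z[i] = s;
  }
  for (int i = n - 1; i >= 0; --i) {  // U z = z
    double s = z[i];
    for (int k = dp[i] + 1; k < rp[i + 1]; ++k) s -= lu[k] * z[ci[k]];
    z[i] = s / lu[dp[i]];
  }
}

// Right-preconditioned BiCGSTAB (van der Vorst). Residual tolerance is
// relative to ||b||_2.
// [[Rcpp::export]]
List bicgstab_ilu(IntegerVector rp, IntegerVector ci, NumericVector val,
                  NumericVector lu, IntegerVector dp, NumericVector b_,
                  NumericVector x0_, double tol, int maxit) {
  int n = rp.size() - 1;
  std::vector<double> x(x0_.begin(), x0_.end()), r(n), r0(n), p(n), v(n),
      s(n), t(n), ph(n), sh(n), tmp(n);
  matvec(rp, ci, val, x, tmp);
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) {
    r[i] = b_[i] - tmp[i];
    r0[i] = r[i];
    bnorm += b_[i] * b_[i];
  }
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;
  double rho = 1.0, alpha = 1.0, omega = 1.0;
  std::fill(p.begin(), p.end(), 0.0);
  std::fill(v.begin(), v.end(), 0.0);
  int it = 0;
  bool conv = false;
  {
    double rn = 0.0;
    for (int i = 0; i < n; ++i) rn += r[i] * r[i];
    if (std::sqrt(rn) / bnorm < tol) conv = true;
  }
  for (it = 0; it < maxit && !conv; ++it) {
    double rho1 = 0.0;
    for (int i = 0; i < n; ++i) rho1 += r0[i] * r[i];
    if (rho1 == 0.0) break;
    if (it > 0) {
      double beta = (rho1 / rho) * (alpha / omega);
      for (int i = 0; i < n; ++i) p[i] = r[i] + beta * (p[i] - omega * v[i]);
    } else {
      std::copy(r.begin(), r.end(), p.begin());
    }
    rho = rho1;
    ilu_solve(rp, ci, lu, dp, p, ph);
    matvec(rp, ci, val, ph, v);
    double r0v = 0.0;
    for (int i = 0; i < n; ++i) r0v += r0[i] * v[i];
    if (r0v == 0.0) break;
    alpha = rho / r0v;
    double snorm = 0.0;
    for (int i = 0; i < n; ++i) {
      s[i] = r[i] - alpha * v[i];
      snorm += s[i] * s[i];
    }
    if (std::sqrt(snorm) / bnorm < tol) {
      for (int i = 0; i < n; ++i) x[i] += alpha * ph[i];
      conv = true;
      ++it;
      break;
    }
    ilu_solve(rp, ci, lu, dp, s, sh);
    matvec(rp, ci, val, sh, t);
    double tt = 0.0, ts = 0.0;
    for (int i = 0; i < n; ++i) {
      tt += t[i] * t[i];
      ts += t[i] * s[i];
    }
    if (tt == 0.0) break;
    omega = ts / tt;
    double rnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * ph[i] + omega * sh[i];
      r[i] = s[i] - omega * t[i];
      rnorm += r[i] * r[i];
    }
    if (std::sqrt(rnorm) / bnorm < tol) {
      conv = true;
      ++it;
      break;
    }
    if (omega == 0.0) break;
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["iterations"] = it, _["converged"] = conv);
}
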