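// ML-DFA candidate-model fitting.
//
// Each candidate curve f is fitted to the scaled fluctuation plot
// (x = log10 window size, y = scaled log10 F in [0, 100]) by maximising
// the pseudo-log-likelihood  sum_i y_i * log p_i  with
// p_i = |f(x_i)| / sum_j |f(x_j)|.  The objective is non-quadratic, so a
// multi-start Nelder-Mead search is used; starts are supplied from R.
//
// Model codes: 1 polynomial (order = K, params a0..aK)
//              2 root       (order = K, f = a1*(x+a2)^(1/K) + a3)
//              3 logarithmic(f = a1*log(x+a2) + a3)
//              4 exponential(f = a1*exp(a2*x) + a3)
//              5 spline     (order = M linear segments: intercept,
//                            M slopes, M-1 interior breakpoints)

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double HARD = 1e12;   // domain violation
static const double NEG_PEN = 1e3; // soft push away from f(x) < 0

// Evaluate the candidate model at all design points. Returns false on a
// hard domain violation (e.g. log of a non-positive number, disordered
// breakpoints), in which case 'viol' holds a measure of the violation
// that lets the simplex retreat.
static bool eval_model(int model, int order, const double* p,
                       const std::vector<double>& x, std::vector<double>& f,
                       double gap, double& viol) {
  const int n = (int)x.size();
  viol = 0.0;
  switch (model) {
  case 1: { // polynomial, coefficients a0..aK
    for (int i = 0; i < n; ++i) {
      double v = p[order];
      for (int j = order - 1; j >= 0; --j) v = v * x[i] + p[j];
      f[i] = v;
    }
    return true;
  }
  case 2: { // root
    for (int i = 0; i < n; ++i) {
      double u = x[i] + p[1];
      if (u <= 0.0) { viol += 1.0 - u; }
    }
    if (viol > 0.0) return false;
    for (int i = 0; i < n; ++i)
      f[i] = p[0] * std::pow(x[i] + p[1], 1.0 / order) + p[2];
    return true;
  }
  case 3: { // logarithmic
    for (int i = 0; i < n; ++i) {
      double u = x[i] + p[1];
      if (u <= 0.0) { viol += 1.0 - u; }
    }
    if (viol > 0.0) return false;
    for (int i = 0; i < n; ++i)
      f[i] = p[0] * std::log(x[i] + p[1]) + p[2];
    return true;
  }
  case 4: { // exponential
    for (int i = 0; i < n; ++i) {
      double e = p[1] * x[i];
      if (e > 50.0) { viol += e - 50.0; }
    }
    if (viol > 0.0) return false;
    for (int i = 0; i < n; ++i)
      f[i] = p[0] * std::exp(p[1] * x[i]) + p[2];
    return true;
  }
  case 5: { // continuous piecewise-linear spline with 'order' segments
    const int M = order;
    const double xmin = x[0], xmax = x[n - 1];
    // breakpoints p[M+1] .. p[2M-1]; require interior placement with a
    // minimum separation of one inter-point gap
    double prev = xmin;
    for (int b = 0; b < M - 1; ++b) {
      double bk = p[M + 1 + b];
      if (bk < prev + gap) viol += (prev + gap - bk);
      prev = bk;
    }
    if (prev > xmax - gap) viol += (prev - (xmax - gap));
    if (viol > 0.0) return false;
    for (int i = 0; i < n; ++i) {
      double v = p[0] + p[1] * (x[i] - xmin);
      for (int b = 0; b < M - 1; ++b) {
        double bk = p[M + 1 + b];
        if (x[i] > bk) v += (p[2 + b] - p[1 + b]) * (x[i] - bk);
      }
      f[i] = v;
    }
    return true;
  }
  }
  return false;
}

// Pseudo-log-likelihood sum_i y_i log(|f_i| / sum_j |f_j|); 0*log(.) = 0.
static double loglik_from_f(const std::vector<double>& f,
                            const std::vector<double>& y) {
  const int n = (int)f.size();
  double S = 0.0;
  for (int i = 0; i < n; ++i) S += std::fabs(f[i]);
  if (S <= 0.0 || !std::isfinite(S)) return -HARD;
  double ll = 0.0;
  const double logS = std::log(S);
  for (int i = 0; i < n; ++i) {
    if (y[i] > 0.0) {
      double a = std::fabs(f[i]);
      if (a <= 0.0) return -HARD;
      ll += y[i] * (std::log(a) - logS);
    }
  }
  return ll;
}

// Objective minimised by Nelder-Mead: -loglik plus a soft penalty for
// negative fitted values (such fits are marked infeasible afterwards).
static double objective(int model, int order, const double* p,
                        const std::vector<double>& x,
                        const std::vector<double>& y,
                        double gap, std::vector<double>& f) {
  double viol;
  if (!eval_model(model, order, p, x, f, gap, viol))
    return HARD * (1.0 + viol);
  double neg = 0.0;
  for (size_t i = 0; i < f.size(); ++i) if (f[i] < 0.0) neg -= f[i];
  double ll = loglik_from_f(f, y);
  if (ll <= -HARD) return HARD;
  return -ll + NEG_PEN * neg;
}

// Plain Nelder-Mead (reflection 1, expansion 2, contraction 0.5,
// shrink 0.5) on a d-dimensional simplex.
static double nelder_mead(int model, int order, std::vector<double>& par,
                          const std::vector<double>& x,
                          const std::vector<double>& y,
                          double gap, int maxit, double tol) {
  const int d = (int)par.size();
  std::vector<double> f((int)x.size());
  std::vector<std::vector<double>> S(d + 1, par);
  std::vector<double> fv(d + 1);
  for (int j = 0; j < d; ++j) {
    double step = 0.05 * (std::fabs(par[j]) + 0.5);
    S[j + 1][j] += step;
  }
  for (int j = 0; j <= d; ++j)
    fv[j] = objective(model, order, S[j].data(), x, y, gap, f);

  std::vector<double> cen(d), xr(d), xe(d), xc(d);
  int it = 0;
  while (it++ < maxit) {
    // order the simplex
    std::vector<int> idx(d + 1);
    for (int j = 0; j <= d; ++j) idx[j] = j;
    std::sort(idx.begin(), idx.end(),
              [&](int a, int b) { return fv[a] < fv[b]; });
    int lo = idx[0], hi = idx[d], nh = idx[d - 1];
    if (std::fabs(fv[hi] - fv[lo]) <= tol * (std::fabs(fv[lo]) + tol)) break;
    for (int k = 0; k < d; ++k) {
      double c = 0.0;
      for (int j = 0; j <= d; ++j) if (j != hi) c += S[j][k];
      cen[k] = c / d;
    }
    for (int k = 0; k < d; ++k) xr[k] = cen[k] + (cen[k] - S[hi][k]);
    double fr = objective(model, order, xr.data(), x, y, gap, f);
    if (fr < fv[lo]) {
      for (int k = 0; k < d; ++k) xe[k] = cen[k] + 2.0 * (cen[k] - S[hi][k]);
      double fe = objective(model, order, xe.data(), x, y, gap, f);
      if (fe < fr) { S[hi] = xe; fv[hi] = fe; }
      else { S[hi] = xr; fv[hi] = fr; }
    } else if (fr < fv[nh]) {
      S[hi] = xr; fv[hi] = fr;
    } else {
      for (int k = 0; k < d; ++k) xc[k] = cen[k] + 0.5 * (S[hi][k] - cen[k]);
      double fc = objective(model, order, xc.data(), x, y, gap, f);
      if (fc < fv[hi]) { S[hi] = xc; fv[hi] = fc; }
      else { // shrink toward the best vertex
        for (int j = 0; j <= d; ++j) {
          if (j == lo) continue;
          for (int k = 0; k < d; ++k)
            S[j][k] = S[lo][k] + 0.5 * (S[j][k] - S[lo][k]);
          fv[j] = objective(model, order, S[j].data(), x, y, gap, f);
        }
      }
    }
  }
  int best = 0;
  for (int j = 1; j <= d; ++j) if (fv[j] < fv[best]) best = j;
  par = S[best];
  return fv[best];
}

// [[Rcpp::export]]
List mldfa_fit_model(int model, int order, NumericVector x, NumericVector y,
                     NumericMatrix inits, int maxit, double tol) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
  const double gap = (xv[n - 1] - xv[0]) / (n - 1);
  const int d = inits.ncol();
  std::vector<double> best_par(d);
  double best_obj = R_PosInf;
  // exploration pass: bounded iterations per start, then a full polish
  // of the best start at the requested tolerance
  const int explore_it = std::min(maxit, 100 + 80 * d);
  for (int s = 0; s < inits.nrow(); ++s) {
    std::vector<double> par(d);
    for (int k = 0; k < d; ++k) par[k] = inits(s, k);
    double v = nelder_mead(model, order, par, xv, yv, gap, explore_it,
                           tol * 100.0);
    if (v < best_obj) { best_obj = v; best_par = par; }
  }
  best_obj = nelder_mead(model, order, best_par, xv, yv, gap, maxit, tol);
  // evaluate feasibility and the clean log-likelihood at the optimum
  std::vector<double> f(n);
  double viol;
  bool ok = eval_model(model, order, best_par.data(), xv, f, gap, viol);
  double ll = ok ? loglik_from_f(f, yv) : -HARD;
  double fmax = 0.0, fmin = 0.0;
  if (ok) {
    fmin = *std::min_element(f.begin(), f.end());
    for (int i = 0; i < n; ++i) fmax = std::max(fmax, std::fabs(f[i]));
  }
  bool feasible = ok && ll > -HARD &&
    fmin >= -1e-6 * (1.0 + fmax);   // reject fits that fall below zero
  return List::create(_["par"] = NumericVector(best_par.begin(), best_par.end()),
                      _["loglik"] = ll,
                      _["feasible"] = feasible,
                      _["fitted"] = NumericVector(f.begin(), f.end()));
}

// Clean pseudo-log-likelihood at given parameters (used by tests as an
// independent hook for grid-search cross-checks).
// [[Rcpp::export]]
double mldfa_loglik_cpp(int model, int order, NumericVector par,
                        NumericVector x, NumericVector y) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end()), f(n);
  const double gap = (xv[n - 1] - xv[0]) / (n - 1);
  std::vector<double> p(par.begin(), par.end());
  double viol;
  if (!eval_model(model, order, p.data(), xv, f, gap, viol)) return R_NegInf;
  double ll = loglik_from_f(f, yv);
  return ll <= -HARD ? R_NegInf : ll;
}
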