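#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Signal model families shared by the fitting engine.
//   code 1: T1 recovery, magnitude  S(t) = |A (1 - B exp(-t/tau))|
//   code 2: T1 recovery, signed     S(t) =  A (1 - B exp(-t/tau))
//   code 3: T2 decay                S(t) =  A exp(-t/tau) + B
// For code 3 with a free offset the constraint B >= 0 is imposed by
// evaluating |B| inside the model (constraint by reparameterization).
// An "anchor" sample (saturation-recovery image appended to a T2-prepared
// series) is predicted as the asymptote B regardless of its nominal time.

static inline double model_predict(int code, double A, double B, double tau,
                                   double t, bool anchor, bool abs_offset) {
  double Beff = abs_offset ? std::fabs(B) : B;
  if (code == 3) {
    if (anchor) return Beff;
    return A * std::exp(-t / tau) + Beff;
  }
  double s = A * (1.0 - B * std::exp(-t / tau));
  if (code == 1) s = std::fabs(s);
  return s;
}

static double objective(int code, double A, double B, double tau,
                        const NumericVector& values, const NumericVector& times,
                        const LogicalVector& anchor, bool abs_offset,
                        bool sum_abs) {
  // tau must stay positive; steer the simplex back with a sloped penalty
  if (tau <= 0.0) return 1e12 * (1.0 - tau);
  double acc = 0.0;
  int n = values.size();
  for (int i = 0; i < n; ++i) {
    double r = model_predict(code, A, B, tau, times[i], anchor[i], abs_offset) - values[i];
    acc += sum_abs ? std::fabs(r) : r * r;
  }
  return acc;
}

// [[Rcpp::export(name = ".nm_refine_cpp")]]
List nm_refine_cpp(NumericVector values, NumericVector times, LogicalVector anchor,
                   int model_code, int n_params, double A0, double B0, double tau0,
                   bool b_fixed, bool abs_offset, bool sum_abs,
                   double tol, int max_iter, bool keep_trace) {
  const double rho = 1.0, chi = 2.0, gamma = 0.5, sigma = 0.5;
  int n = n_params;  // 2: (A, tau) with B fixed; 3: (A, B, tau)

  // free-parameter vector x -> (A, B, tau)
  std::vector<std::vector<double> > simplex(n + 1, std::vector<double>(n));
  std::vector<double> x0(n);
  if (n == 2) { x0[0] = A0; x0[1] = tau0; }
  else        { x0[0] = A0; x0[1] = B0; x0[2] = tau0; }
  int tau_idx = n - 1;

  // fminsearch-style initial simplex: 5 % per-coordinate perturbation,
  // absolute steps for zero coordinates (5 ms for tau)
  for (int j = 0; j <= n; ++j) simplex[j] = x0;
  for (int j = 0; j < n; ++j) {
    double step;
    if (x0[j] != 0.0) step = 0.05 * x0[j];
    else step = (j == tau_idx) ? 5.0 : 0.00025;
    simplex[j + 1][j] += step;
  }

  double Afix = A0, Bfix = B0;
  std::vector<double> fv(n + 1);
  int n_eval = 0;
  std::vector<double> trace;
  auto feval = [&](const std::vector<double>& x) {
    double A = x[0], B, tau;
    if (n == 2) { B = Bfix; tau = x[1]; }
    else        { B = x[1]; tau = x[2]; }
    (void)Afix;
    ++n_eval;
    return objective(model_code, A, B, tau, values, times, anchor, abs_offset, sum_abs);
  };
  for (int j = 0; j <= n; ++j) fv[j] = feval(simplex[j]);

  bool converged = false, monotone = true;
  int iter = 0;
  double prev_best = std::numeric_limits<double>::infinity();

  // index sort of fv
  auto order = [&]() {
    std::vector<int> idx(n + 1);
    for (int j = 0; j <= n; ++j) idx[j] = j;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) { return fv[a] < fv[b]; });
    std::vector<std::vector<double> > s2(n + 1);
    std::vector<double> f2(n + 1);
    for (int j = 0; j <= n; ++j) { s2[j] = simplex[idx[j]]; f2[j] = fv[idx[j]]; }
    simplex = s2; fv = f2;
  };
  order();

  while (iter < max_iter) {
    ++iter;
    std::vector<double> tau_prev(n + 1);
    for (int j = 0; j <= n; ++j) tau_prev[j] = simplex[j][tau_idx];

    // centroid of all but worst
    std::vector<double> xbar(n, 0.0);
    for (int j = 0; j < n; ++j)
      for (int k = 0; k < n; ++k) xbar[k] += simplex[j][k] / n;

    std::vector<double> xr(n), xe(n), xc(n);
    for (int k = 0; k < n; ++k) xr[k] = xbar[k] + rho * (xbar[k] - simplex[n][k]);
    double fr = feval(xr);

    if (fr < fv[0]) {
      for (int k = 0; k < n; ++k) xe[k] = xbar[k] + chi * (xr[k] - xbar[k]);
      double fe = feval(xe);
      if (fe < fr) { simplex[n] = xe; fv[n] = fe; }
      else         { simplex[n] = xr; fv[n] = fr; }
    } else if (fr < fv[n - 1]) {
      simplex[n] = xr; fv[n] = fr;
    } else {
      bool shrink = false;
      if (fr < fv[n]) {  // outside contraction
        for (int k = 0; k < n; ++k) xc[k] = xbar[k] + gamma * (xr[k] - xbar[k]);
        double fc = feval(xc);
        if (fc <= fr) { simplex[n] = xc; fv[n] = fc; } else shrink = true;
      } else {           // inside contraction
        for (int k = 0; k < n; ++k) xc[k] = xbar[k] - gamma * (xbar[k] - simplex[n][k]);
        double fc = feval(xc);
        if (fc < fv[n]) { simplex[n] = xc; fv[n] = fc; } else shrink = true;
      }
      if (shrink) {
        for (int j = 1; j <= n; ++j) {
          for (int k = 0; k < n; ++k)
            simplex[j][k] = simplex[0][k] + sigma * (simplex[j][k] - simplex[0][k]);
          fv[j] = feval(simplex[j]);
        }
      }
    }
    order();

    if (fv[0] > prev_best + 1e-12 * std::max(1.0, std::fabs(prev_best))) monotone = false;
    prev_best = fv[0];
    if (keep_trace) trace.push_back(fv[0]);

    // convergence: maximum absolute tau difference between the two
    // consecutive simplexes, taken over all vertex pairs (this bounds both
    // the per-vertex motion and the within-simplex tau spread, so a single
    // vertex update that leaves tau untouched cannot stop the search early)
    double dmax = 0.0;
    for (int j = 0; j <= n; ++j) {
      for (int k = 0; k <= n; ++k) {
        double d = std::fabs(simplex[j][tau_idx] - tau_prev[k]);
        if (d > dmax) dmax = d;
      }
    }
    if (dmax < tol) { converged = true; break; }
  }

  double A = simplex[0][0], B, tau;
  if (n == 2) { B = Bfix; tau = simplex[0][1]; }
  else        { B = simplex[0][1]; tau = simplex[0][2]; }
  if (abs_offset && !b_fixed) B = std::fabs(B);

  return List::create(
    _["A"] = A, _["B"] = B, _["tau"] = tau,
    _["value"] = fv[0], _["n_iterations"] = iter, _["n_evaluations"] = n_eval,
    _["converged"] = converged, _["monotone"] = monotone,
    _["trace"] = keep_trace ? NumericVector(trace.begin(), trace.end())
                            : NumericVector(0));
}

// [[Rcpp::export(name = ".model_predict_cpp")]]
NumericVector model_predict_cpp(int code, double A, double B, double tau,
                                NumericVector t, LogicalVector anchor,
                                bool abs_offset) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = model_predict(code, A, B, tau, t[i], anchor[i], abs_offset);
  return out;
}
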