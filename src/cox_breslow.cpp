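#include <Rcpp.h>
using namespace Rcpp;

// Log partial likelihood, score vector and observed information for a Cox
// proportional-hazards model under the Breslow tie convention.
//
// Rows must be sorted by follow-up time in DECREASING order so the risk set
// grows monotonically as rows are scanned; tied times must be adjacent (any
// within-tie order is fine: the whole tie group joins the risk set before
// any of its events is scored, which is exactly Breslow's convention).
//
// exp() is taken on eta - max(eta) to avoid overflow; the shift cancels in
// eta_i - log(S0) so the returned log-likelihood is on the unshifted scale.
//
// The weighted outer products stream into a flat upper-triangle buffer with
// one running index, keeping the hot loop contiguous in memory.
// [[Rcpp::export(name = ".cox_breslow_deriv")]]
List cox_breslow_deriv(const NumericMatrix& X, const NumericVector& time,
                       const IntegerVector& event, const NumericVector& beta) {
  const int n = X.nrow(), p = X.ncol();
  if (time.size() != n || event.size() != n || beta.size() != p)
    stop("dimension mismatch in cox_breslow_deriv");
  const size_t ntri = static_cast<size_t>(p) * (p + 1) / 2;

  // row-major copy of X: cache-friendly row access in the scan below
  std::vector<double> Xr(static_cast<size_t>(n) * p);
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i)
      Xr[static_cast<size_t>(i) * p + j] = X(i, j);

  std::vector<double> eta(n);
  double eta_max = R_NegInf;
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    const double* xi = &Xr[static_cast<size_t>(i) * p];
    for (int j = 0; j < p; ++j) e += xi[j] * beta[j];
    if (!R_finite(e)) stop("non-finite linear predictor for row %d", i + 1);
    eta[i] = e;
    if (e > eta_max) eta_max = e;
  }

  double s0 = 0.0, ll = 0.0;
  std::vector<double> s1(p, 0.0), s2(ntri, 0.0), wx(p), info_tri(ntri, 0.0);
  NumericVector grad(p);

  int i = 0;
  while (i < n) {
    int g_end = i;
    while (g_end + 1 < n && time[g_end + 1] == time[i]) ++g_end;
    for (int k = i; k <= g_end; ++k) {
      const double w = std::exp(eta[k] - eta_max);
      const double* xk = &Xr[static_cast<size_t>(k) * p];
      s0 += w;
      for (int j = 0; j < p; ++j) {
        wx[j] = w * xk[j];
        s1[j] += wx[j];
      }
      size_t idx = 0;
      for (int j = 0; j < p; ++j) {
        const double wxj = wx[j];
        double* s2j = &s2[idx];
        for (int l = j; l < p; ++l) s2j[l - j] += wxj * xk[l];
        idx += p - j;
      }
    }
    for (int k = i; k <= g_end; ++k) {
      if (event[k] != 1) continue;
      const double* xk = &Xr[static_cast<size_t>(k) * p];
      ll += (eta[k] - eta_max) - std::log(s0);
      const double inv_s0 = 1.0 / s0;
      size_t idx = 0;
      for (int j = 0; j < p; ++j) {
        const double m1j = s1[j] * inv_s0;
        grad[j] += xk[j] - m1j;
        for (int l = j; l < p; ++l) {
          info_tri[idx] += s2[idx] * inv_s0 - m1j * (s1[l] * inv_s0);
          ++idx;
        }
      }
    }
    i = g_end + 1;
  }

  NumericMatrix info(p, p);
  size_t idx = 0;
  for (int j = 0; j < p; ++j)
    for (int l = j; l < p; ++l) {
      info(j, l) = info_tri[idx];
      info(l, j) = info_tri[idx];
      ++idx;
    }
  return List::create(_["loglik"] = ll, _["gradient"] = grad,
                      _["information"] = info);
}

// Log partial likelihood only (no derivatives): the cheap evaluation used
// inside the Newton-Raphson line search. Same ordering contract as above.
// [[Rcpp::export(name = ".cox_breslow_loglik")]]
double cox_breslow_loglik(const NumericMatrix& X, const NumericVector& time,
                          const IntegerVector& event,
                          const NumericVector& beta) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<double> eta(n);
  double eta_max = R_NegInf;
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    if (!R_finite(e)) stop("non-finite linear predictor for row %d", i + 1);
    eta[i] = e;
    if (e > eta_max) eta_max = e;
  }
  double s0 = 0.0, ll = 0.0;
  int i = 0;
  while (i < n) {
    int g_end = i;
    while (g_end + 1 < n && time[g_end + 1] == time[i]) ++g_end;
    for (int k = i; k <= g_end; ++k) s0 += std::exp(eta[k] - eta_max);
    for (int k = i; k <= g_end; ++k)
      if (event[k] == 1) ll += (eta[k] - eta_max) - std::log(s0);
    i = g_end + 1;
  }
  return ll;
}
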