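#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Self-consistent solver for the transition-based reweighting analysis
// method (TRAM).  Combines transition counts from K thermodynamic ensembles
// with per-frame reduced bias energies b^k(x) (evaluated for every ensemble
// at every pooled frame) into per-ensemble, per-state reduced free energies
// f_i^k and Lagrange multipliers nu_i^k.  The fixed point satisfies
//   p_ij^k = (c_ij^k + c_ji^k) e^{-f_j^k} / (nu_i^k e^{-f_j^k} + nu_j^k e^{-f_i^k})
//   sum_j p_ij^k = 1
//   e^{-f_i^k}  = sum_{x in X_i} mu(x) e^{-b^k(x)}
//   mu(x)       = 1 / sum_l R_{s(x)}^l e^{f_{s(x)}^l - b^l(x)}
//   R_i^k       = N_i^k + sum_j c_ij^k - nu_i^k
// where X_i pools the frames of all ensembles assigned to Markov state i and
// N_i^k counts the frames of ensemble k in state i.  All energies in kT.

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// streaming log-sum-exp accumulator
struct LseAcc {
  double m = R_NegInf, s = 0.0;
  void add(double v) {
    if (v == R_NegInf) return;
    if (v <= m) { s += std::exp(v - m); return; }
    s = s * std::exp(m - v) + 1.0;
    m = v;
  }
  double value() const { return (s == 0.0) ? R_NegInf : m + std::log(s); }
};

// [[Rcpp::export(name = ".tram_solve_cpp")]]
List tram_solve_cpp(List count_mats, IntegerMatrix N,  // K x n state counts
                    IntegerVector frame_state,         // 0-based, pooled frames
                    NumericMatrix frame_bias,          // n_frames x K
                    NumericVector frame_mult,          // multiplicities
                    int unbiased, int maxiter, double tol) {
  const int K = count_mats.size();
  const int n = N.ncol();
  const int nf = frame_state.size();
  std::vector<NumericMatrix> C(K);
  for (int k = 0; k < K; ++k) C[k] = as<NumericMatrix>(count_mats[k]);

  NumericMatrix csum(K, n);   // outgoing counts per ensemble
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += C[k](i, j);
      csum(k, i) = s;
    }

  NumericMatrix log_nu(K, n), f(K, n);
  for (int k = 0; k < K; ++k)
    for (int i = 0; i < n; ++i) {
      double sym = csum(k, i);
      for (int j = 0; j < n; ++j) sym += C[k](j, i);
      log_nu(k, i) = sym > 0 ? std::log(0.5 * sym) : R_NegInf;
      f(k, i) = 0.0;
    }

  std::vector<double> history;
  NumericMatrix new_log_nu(K, n), logR(K, n), new_f(K, n);
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= maxiter; ++iter) {
    // (1) Lagrange multiplier update (normalization of p^k rows)
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < n; ++i) {
        if (log_nu(k, i) == R_NegInf) { new_log_nu(k, i) = R_NegInf; continue; }
        LseAcc acc;
        for (int j = 0; j < n; ++j) {
          double csym = C[k](i, j) + C[k](j, i);
          if (csym <= 0) continue;
          double den = lse2(log_nu(k, i) - f(k, j), log_nu(k, j) - f(k, i));
          acc.add(std::log(csym) + log_nu(k, i) - f(k, j) - den);
        }
        new_log_nu(k, i) = acc.value();
      }
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < n; ++i) log_nu(k, i) = new_log_nu(k, i);

    // (2) visitation weights R_i^k = N_i^k + c_i^k(out) - nu_i^k
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < n; ++i) {
        double nu = (log_nu(k, i) == R_NegInf) ? 0.0 : std::exp(log_nu(k, i));
        double R = N(k, i) + csum(k, i) - nu;
        logR(k, i) = R > 0 ? std::log(R) : R_NegInf;
      }

    // (3) free-energy update through the pooled-frame weights mu(x)
    std::vector<LseAcc> acc((size_t)K * n);
    for (int x = 0; x < nf; ++x) {
      int i = frame_state[x];
      double lm = std::log(frame_mult[x]);
      LseAcc den;
      for (int l = 0; l < K; ++l)
        den.add(logR(l, i) + f(l, i) - frame_bias(x, l));
      double d = den.value();
      for (int k = 0; k < K; ++k)
        acc[(size_t)k * n + i].add(lm - frame_bias(x, k) - d);
    }
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < n; ++i) {
        double v = acc[(size_t)k * n + i].value();
        new_f(k, i) = (v == R_NegInf) ? R_PosInf : -v;
      }

    // gauge: unbiased-ensemble state weights sum to one
    LseAcc z;
    for (int i = 0; i < n; ++i)
      if (std::isfinite(new_f(unbiased, i))) z.add(-new_f(unbiased, i));
    double shift = z.value();
    double delta = 0.0;
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < n; ++i) {
        double v = new_f(k, i) + shift;
        if (std::isfinite(v) && std::isfinite(f(k, i))) {
          double dd = std::fabs(v - f(k, i));
          if (dd > delta) delta = dd;
        }
        f(k, i) = v;
      }
    history.push_back(delta);
    if (delta < tol) { converged = true; break; }
    if (iter % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["f"] = f, _["log_nu"] = log_nu,
                      _["n_iter"] = std::min(iter, maxiter),
                      _["converged"] = converged,
                      _["history"] = NumericVector(history.begin(), history.end()));
}
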