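#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Single-flip Metropolis walk over binary states of a pairwise model.
//
// States are stored as their convention values (off/on), so the same kernel
// serves both the {-1,+1} and {0,1} parameterizations.  Local fields
// f_i = h_i + sum_j J_ij sigma_j are maintained incrementally (O(N) per
// step), as is the energy.  RNG draw order per step is fixed and documented:
// (1) proposal site k ~ uniform over N, (2) acceptance uniform u (always
// drawn, even when the move is downhill), so chains are bit-reproducible for
// a given R seed.
//
// n_steps counts post-burn-in steps; every thin-th of them is recorded.
// [[Rcpp::export]]
List metropolis_walk_cpp(NumericVector h, NumericMatrix J, NumericVector state0,
                         double off, double on, double temperature,
                         double n_steps, double burn_in, double thin) {
  const int N = h.size();
  std::vector<double> sigma(state0.begin(), state0.end());
  std::vector<double> f(N);
  double E = 0.0;
  for (int i = 0; i < N; ++i) {
    double s = h[i];
    for (int j = 0; j < N; ++j) s += J(i, j) * sigma[j];
    f[i] = s;
    E -= h[i] * sigma[i];
    for (int j = i + 1; j < N; ++j) E -= J(i, j) * sigma[i] * sigma[j];
  }
  double M = 0.0;
  for (int i = 0; i < N; ++i) M += sigma[i];

  const long long post = (long long) n_steps;
  const long long burn = (long long) burn_in;
  const long long th = (long long) thin;
  const long long total = post + burn;
  const long long n_keep = post > 0 ? post / th : 0;
  IntegerVector idx_out((R_xlen_t) n_keep);
  NumericVector e_out((R_xlen_t) n_keep), m_out((R_xlen_t) n_keep);
  long long kept = 0;
  double n_acc = 0.0;

  for (long long step = 1; step <= total; ++step) {
    int k = (int) (unif_rand() * N);
    if (k == N) k = N - 1;
    const double snew = (sigma[k] == on) ? off : on;
    const double dsig = snew - sigma[k];
    const double dE = -dsig * f[k];  // J has zero diagonal
    const double u = unif_rand();
    if (dE <= 0.0 || u < std::exp(-dE / temperature)) {
      sigma[k] = snew;
      for (int j = 0; j < N; ++j) f[j] += J(j, k) * dsig;
      E += dE;
      M += dsig;
      n_acc += 1.0;
    }
    if (step > burn && ((step - burn) % th == 0) && kept < n_keep) {
      double idx = 0.0, pw = 1.0;
      for (int i = 0; i < N; ++i) {
        if (sigma[i] == on) idx += pw;
        pw *= 2.0;
      }
      idx_out[(R_xlen_t) kept] = (int) idx;
      e_out[(R_xlen_t) kept] = E;
      m_out[(R_xlen_t) kept] = M;
      ++kept;
    }
  }
  return List::create(_["states"] = idx_out,
                      _["energy"] = e_out,
                      _["magnetization"] = m_out,
                      _["final_state"] = NumericVector(sigma.begin(), sigma.end()),
                      _["acceptance_rate"] = n_acc / (double) total);
}
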