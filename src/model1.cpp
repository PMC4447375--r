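#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Stochastic binary network with weight-dependent Hebbian plasticity and an
// optional Gaussian LTP bonus. Per step: currents from previous-bin states,
// new states drawn from the adjusted sigmoid (one unif_rand() per neuron, in
// neuron order, so a pure-R loop with runif(N) reproduces the run bit for
// bit), plasticity applied on the new-bin states, then the LTP increment.
// Snapshots every `snapshot_stride` steps; the initial matrix is snapshot 1.
// [[Rcpp::export]]
List sim_model1_cpp(NumericMatrix w, IntegerVector v0,
                    IntegerVector ext_step, IntegerVector ext_unit,
                    int n_steps, double t0,
                    double K_t, double K_s, double w_ie, double dt,
                    double C_p, double C_d, double theta,
                    double w_min, double w_max,
                    int snapshot_stride, bool record_spikes,
                    bool has_ltp, NumericMatrix cieg,
                    double ltp_t_T, double ltp_mu, double ltp_sigma,
                    bool ltp_scaled) {
  const int N = w.nrow();
  if (w.ncol() != N) stop("weight matrix must be square");
  NumericMatrix W = clone(w);
  for (int i = 0; i < N; ++i) W(i, i) = 0.0;

  std::vector<int> v(N), v_new(N);
  for (int i = 0; i < N; ++i) v[i] = v0[i] ? 1 : 0;

  const double inv_nm1 = 1.0 / (N - 1);
  const double e_inv = std::exp(-1.0);
  const double dep_dt = C_d * (0.0 - theta) * dt;   // pre fires, post silent
  const double dep_both = C_d * (1.0 - theta) * dt; // both fire (0 if theta=1)

  const int n_snap = n_steps / snapshot_stride + 1;
  NumericMatrix snaps(N * N, n_snap);
  NumericVector snap_steps(n_snap);
  int snap_k = 0;
  std::copy(W.begin(), W.end(), snaps.begin());
  snap_steps[snap_k++] = 0;

  std::vector<int> sp_step, sp_unit;
  std::vector<double> I(N);
  std::vector<int> ext_now(N), firing;
  firing.reserve(N);

  const double ltp_amp0 =
      (ltp_scaled ? dt : 1.0) / (ltp_sigma * std::sqrt(2.0 * M_PI));
  const double ltp_peak = ltp_t_T + ltp_mu;

  R_xlen_t ep = 0;
  const R_xlen_t n_ext = ext_step.size();

  for (int s = 1; s <= n_steps; ++s) {
    // external input of this bin
    std::fill(ext_now.begin(), ext_now.end(), 0);
    while (ep < n_ext && ext_step[ep] == s) {
      ext_now[ext_unit[ep] - 1] = 1;
      ++ep;
    }
    // currents from previous-bin states
    std::fill(I.begin(), I.end(), 0.0);
    for (int j = 0; j < N; ++j) {
      if (v[j]) {
        const double* col = &W(0, j);
        for (int i = 0; i < N; ++i) I[i] += col[i];
      }
    }
    // new states
    firing.clear();
    for (int i = 0; i < N; ++i) {
      const double Ii = w_ie * ext_now[i] + I[i] * inv_nm1;
      const double p = 1.0 / (1.0 + std::exp(K_t - K_s * Ii));
      v_new[i] = (unif_rand() < p) ? 1 : 0;
      if (v_new[i]) {
        firing.push_back(i);
        if (record_spikes) { sp_step.push_back(s); sp_unit.push_back(i + 1); }
      }
    }
    // plasticity on new-bin states: columns j with v_j = 1
    for (size_t fj = 0; fj < firing.size(); ++fj) {
      const int j = firing[fj];
      double* col = &W(0, j);
      for (int i = 0; i < N; ++i) {
        if (i == j) continue;
        double wij = col[i];
        if (v_new[i]) {
          wij += C_p * (std::exp(-wij) - e_inv) * dt + dep_both;
        } else {
          wij += dep_dt;
        }
        if (wij < w_min) wij = w_min;
        else if (wij > w_max) wij = w_max;
        col[i] = wij;
      }
    }
    // Gaussian LTP bonus, absolute time of this bin's end
    if (has_ltp) {
      const double t_abs = t0 + s * dt;
      if (t_abs >= ltp_t_T) {
        const double z = (t_abs - ltp_peak) / ltp_sigma;
        const double amp = ltp_amp0 * std::exp(-0.5 * z * z);
        if (amp > 1e-16) {
          for (int j = 0; j < N; ++j) {
            double* col = &W(0, j);
            const double* cg = &cieg(0, j);
            for (int i = 0; i < N; ++i) {
              if (i == j) continue;
              double wij = col[i] + cg[i] * amp;
              if (wij < w_min) wij = w_min;
              else if (wij > w_max) wij = w_max;
              col[i] = wij;
            }
          }
        }
      }
    }
    std::swap(v, v_new);
    if (s % snapshot_stride == 0) {
      std::copy(W.begin(), W.end(), snaps.begin() + (R_xlen_t)snap_k * N * N);
      snap_steps[snap_k++] = s;
    }
  }

  IntegerVector v_final(N);
  for (int i = 0; i < N; ++i) v_final[i] = v[i];
  return List::create(
      _["snaps"] = snaps, _["snap_steps"] = snap_steps,
      _["sp_step"] = IntegerVector(sp_step.begin(), sp_step.end()),
      _["sp_unit"] = IntegerVector(sp_unit.begin(), sp_unit.end()),
      _["w_final"] = W, _["v_final"] = v_final);
}
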