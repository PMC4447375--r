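#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Leaky integrate-and-fire layer with plastic input conductances, network
// feedback inhibition, sleep-modulated pairwise STDP, embossing LTP and
// per-step multiplicative row normalization. Runs steps [step_lo, step_hi]
// of a longer simulation; membrane/plasticity state is passed in and
// returned so phases can be chained (the embossing plan needs the weights
// one step before sleep onset). Step s covers t = (s-1)*dt; sleep gating,
// the LTP Gaussian and all spike times use that clock.
// [[Rcpp::export]]
List sim_model2_cpp(NumericMatrix W,
                    IntegerVector ext_step, IntegerVector ext_unit,
                    int step_lo, int step_hi, double dt,
                    double tau_m, double v_rest, double v_th, double v_reset,
                    double t_ref, double tau_syn, double tau_inh,
                    double e_exc, double e_inh, double g_leak,
                    double inh_weight, int inh_delay_steps,
                    double tau_stdp, double c_p, double c_d, double sigma_v,
                    double t_sleep, double t_wake,
                    double gamma_sleep, bool gamma_both,
                    bool has_ltp, NumericMatrix theta, double kappa,
                    double t_peak, double t_std, double ltp_A,
                    double omega,
                    NumericVector V, NumericVector g_e, NumericVector g_i,
                    NumericVector ref_until,
                    NumericVector last_pre, NumericVector last_post,
                    IntegerVector inh_queue, int snapshot_stride) {
  const int n = W.nrow();       // principal neurons
  const int m = W.ncol();       // input units
  NumericMatrix Wc = clone(W);
  NumericMatrix dW(n, m);
  NumericVector Vc = clone(V), gec = clone(g_e), gic = clone(g_i),
      refc = clone(ref_until), lpre = clone(last_pre),
      lpost = clone(last_post);
  std::vector<int> queue(inh_queue.begin(), inh_queue.end());
  const int qlen = queue.size(); // == inh_delay_steps
  if (qlen != inh_delay_steps) stop("inhibition queue length mismatch");

  const double dec_e = std::exp(-dt / tau_syn);
  const double dec_i = std::exp(-dt / tau_inh);
  IntegerVector spike_counts(n);
  std::vector<int> sp_step, sp_unit;

  const int n_steps_here = step_hi - step_lo + 1;
  const int n_snap_max = n_steps_here / snapshot_stride + 2;
  NumericMatrix snaps((R_xlen_t)n * m, n_snap_max);
  NumericVector snap_steps(n_snap_max);
  int snap_k = 0;
  if (step_lo == 1) {  // initial condition counts as the first snapshot
    std::copy(Wc.begin(), Wc.end(), snaps.begin());
    snap_steps[snap_k++] = 0;
  }

  // advance external spike pointer to this phase
  R_xlen_t ep = 0;
  const R_xlen_t n_ext = ext_step.size();
  while (ep < n_ext && ext_step[ep] < step_lo) ++ep;

  std::vector<int> js; js.reserve(16);

  for (int s = step_lo; s <= step_hi; ++s) {
    const double t = (s - 1) * dt;
    const bool sleeping = (t >= t_sleep && t < t_wake);
    const double cp_eff = sleeping ? (gamma_both ? c_p * gamma_sleep
                                                 : c_p / gamma_sleep) : c_p;
    const double cd_eff = sleeping ? c_d * gamma_sleep : c_d;

    // --- input spikes of this step: depression + conductance, then t_pre
    js.clear();
    while (ep < n_ext && ext_step[ep] == s) {
      js.push_back(ext_unit[ep] - 1);
      ++ep;
    }
    for (size_t u = 0; u < js.size(); ++u) {
      const int j = js[u];
      double* wcol = &Wc(0, j);
      double* dcol = &dW(0, j);
      for (int i = 0; i < n; ++i) {
        if (lpost[i] > -1e8) {
          const double dtij = lpost[i] - t;  // <= 0
          const double v = norm_rand() * sigma_v;
          dcol[i] += (-cd_eff + v) * wcol[i] * std::exp(dtij / tau_stdp);
        }
        gec[i] += wcol[i];
      }
      lpre[j] = t;
    }

    // --- membrane integration (conductances in units of g_leak)
    for (int i = 0; i < n; ++i) {
      if (t >= refc[i]) {
        const double dv = (-(Vc[i] - v_rest)
                           - (gec[i] / g_leak) * (Vc[i] - e_exc)
                           - (gic[i] / g_leak) * (Vc[i] - e_inh)) / tau_m;
        Vc[i] += dt * dv;
      }
      gec[i] *= dec_e;
      gic[i] *= dec_i;
    }

    // --- threshold crossing: spikes, potentiation, feedback inhibition
    int n_spikes_now = 0;
    for (int i = 0; i < n; ++i) {
      if (t >= refc[i] && Vc[i] >= v_th) {
        Vc[i] = v_reset;
        refc[i] = t + t_ref;
        ++spike_counts[i];
        ++n_spikes_now;
        sp_step.push_back(s);
        sp_unit.push_back(i + 1);
        for (int j = 0; j < m; ++j) {
          if (lpre[j] > -1e8) {
            const double dtij = t - lpre[j];  // >= 0
            const double v = norm_rand() * sigma_v;
            dW(i, j) += (cp_eff + v * Wc(i, j)) * std::exp(-dtij / tau_stdp);
          }
        }
        lpost[i] = t;
      }
    }
    // ring buffer: read spikes emitted inh_delay_steps ago, write today's
    const int slot = s % qlen;
    if (queue[slot] > 0) {
      const double gq = inh_weight * queue[slot];
      for (int i = 0; i < n; ++i) gic[i] += gq;
    }
    queue[slot] = n_spikes_now;

    // --- embossing LTP (theta already Heaviside-gated by phase start)
    if (has_ltp) {
      const double z = (t - t_peak) / t_std;
      const double amp = kappa * ltp_A * std::exp(-0.5 * z * z) * dt;
      if (amp > 1e-18) {
        const double* th = theta.begin();
        double* d = dW.begin();
        const R_xlen_t nm = (R_xlen_t)n * m;
        for (R_xlen_t q = 0; q < nm; ++q) d[q] += amp * th[q];
      }
    }

    // --- apply increments, clip at 0, normalize each row to mean omega
    for (int i = 0; i < n; ++i) {
      double rs = 0.0;
      for (int j = 0; j < m; ++j) {
        double w = Wc(i, j) + dW(i, j);
        if (w < 0.0) w = 0.0;
        Wc(i, j) = w;
        rs += w;
      }
      if (rs <= 0.0) stop("non-positive row sum at t=%.3f (neuron %d)",
                          t, i + 1);
      const double f = omega * m / rs;
      for (int j = 0; j < m; ++j) Wc(i, j) *= f;
    }
    std::fill(dW.begin(), dW.end(), 0.0);

    if ((s % snapshot_stride == 0 || (s == step_hi && snap_k == 0)) &&
        snap_k < n_snap_max) {
      std::copy(Wc.begin(), Wc.end(),
                snaps.begin() + (R_xlen_t)snap_k * n * m);
      snap_steps[snap_k++] = s;
    }
  }

  return List::create(
      _["W"] = Wc, _["V"] = Vc, _["g_e"] = gec, _["g_i"] = gic,
      _["ref_until"] = refc, _["last_pre"] = lpre, _["last_post"] = lpost,
      _["inh_queue"] = IntegerVector(queue.begin(), queue.end()),
      _["snaps"] = snaps(_, Range(0, std::max(0, snap_k - 1))),
      _["snap_steps"] = snap_steps[Range(0, std::max(0, snap_k - 1))],
      _["spike_counts"] = spike_counts,
      _["sp_step"] = IntegerVector(sp_step.begin(), sp_step.end()),
      _["sp_unit"] = IntegerVector(sp_unit.begin(), sp_unit.end()));
}
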