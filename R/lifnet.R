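#' Configuration of the leaky integrate-and-fire network
#'
#' 45 principal leaky integrate-and-fire neurons, each receiving 200 plastic
#' input synapses (conductances in nS) and no direct connections to other
#' principal cells. Every principal spike recruits, after a fixed delay, an
#' inhibitory conductance delivered to the whole principal layer (network
#' feedback inhibition), which enforces competition between neurons.
#'
#' Membrane and inhibition parameters are package conventions (they are not
#' constrained by the plasticity equations) and are fully configurable. The
#' defaults use a slow integrator membrane (50 ms) with strong, slowly
#' decaying feedback inhibition (30 nS quanta, 60 ms), which makes each
#' 125 ms input window an approximate winner-take-all competition: neurons
#' fire sparsely and almost exclusively in windows of their preferred
#' memory, which is what keeps the learned selectivity pattern stable under
#' the strong pairwise potentiation of the plasticity rule.
#'
#' @param n_neurons principal neuron count (45).
#' @param m_inputs plastic input synapses per neuron (200).
#' @param tau_m membrane time constant (s).
#' @param v_rest,v_thresh,v_reset resting / threshold / reset potentials
#'   (mV); threshold must exceed reset.
#' @param t_ref absolute refractory period (s).
#' @param tau_syn excitatory synaptic conductance time constant (s).
#' @param tau_inh inhibitory conductance time constant (s).
#' @param e_exc,e_inh excitatory / inhibitory reversal potentials (mV).
#' @param g_leak leak conductance (nS).
#' @param inh_weight inhibitory conductance quantum per principal spike (nS),
#'   delivered to every neuron after `inh_delay`.
#' @param inh_delay feedback inhibition delay (s).
#' @param dt simulation step (s).
#' @return object of class `lif_config`.
#' @export
lif_config <- function(n_neurons = 45L, m_inputs = 200L,
                       tau_m = 0.050, v_rest = -70, v_thresh = -55,
                       v_reset = -60, t_ref = 0.002,
                       tau_syn = 0.005, tau_inh = 0.060,
                       e_exc = 0, e_inh = -75, g_leak = 10,
                       inh_weight = 30, inh_delay = 0.002, dt = 0.001) {
  if (v_thresh <= v_reset) stop("threshold must exceed reset", call. = FALSE)
  for (nm in c("tau_m", "tau_syn", "tau_inh", "dt")) {
    .check_positive(get(nm), nm)
  }
  structure(list(n_neurons = as.integer(n_neurons),
                 m_inputs = as.integer(m_inputs),
                 tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
                 v_reset = v_reset, t_ref = t_ref, tau_syn = tau_syn,
                 tau_inh = tau_inh, e_exc = e_exc, e_inh = e_inh,
                 g_leak = g_leak, inh_weight = inh_weight,
                 inh_delay = inh_delay, dt = dt),
            class = "lif_config")
}

#' STDP configuration
#'
#' Pairwise spike-timing dependent plasticity on the input synapses, based
#' on the interval `delta_t = t_post - t_pre` between last spikes. At a
#' postsynaptic spike (`delta_t > 0`) the potentiation is
#' `(C_p + v * W) * exp(-delta_t / tau_stdp)`; at a presynaptic spike
#' (`delta_t < 0`) the depression is
#' `(-C_d + v) * W * exp(delta_t / tau_stdp)`. `v` is a zero-mean Gaussian
#' noise factor drawn fresh per plasticity event.
#'
#' @param tau_stdp STDP time constant (0.020 s).
#' @param c_p potentiation constant (3.2 nS).
#' @param c_d depression multiplier (0.03, unitless).
#' @param sigma_v SD of the stochastic factor v (0.015).
#' @return object of class `stdp_config`.
#' @export
stdp_config <- function(tau_stdp = 0.020, c_p = 3.2, c_d = 0.03,
                        sigma_v = 0.015) {
  .check_positive(tau_stdp, "tau_stdp")
  .check_nonnegative(c_p, "c_p")
  .check_nonnegative(c_d, "c_d")
  structure(list(tau_stdp = tau_stdp, c_p = c_p, c_d = c_d,
                 sigma_v = sigma_v),
            class = "stdp_config")
}

#' STDP potentiation / depression increments
#'
#' Direct evaluation of the pairwise plasticity rules for given spike-time
#' differences; used for unit-level reasoning and as a reference for the
#' simulator.
#'
#' @param delta_t `t_post - t_pre` (s); potentiation expects positive,
#'   depression negative values.
#' @param W synaptic weight(s) in nS.
#' @param cfg an [stdp_config()].
#' @param v stochastic factor (default 0 for the deterministic rule).
#' @return weight increment(s) in nS.
#' @export
stdp_potentiation <- function(delta_t, W, cfg = stdp_config(), v = 0) {
  (cfg$c_p + v * W) * exp(-delta_t / cfg$tau_stdp)
}

#' @rdname stdp_potentiation
#' @export
stdp_depression <- function(delta_t, W, cfg = stdp_config(), v = 0) {
  (-cfg$c_d + v) * W * exp(delta_t / cfg$tau_stdp)
}

#' Sleep schedule for the LIF network
#'
#' Sleep runs from `t_sleep` to `t_wake`; inside it the input rates are
#' halved (by the input generator), STDP constants are modulated by
#' `gamma_sleep`, and the embossing LTP Gaussian peaks at `t_ltp_peak` with
#' SD `t_ltp_std`; the unmodulated Gaussian's time integral equals
#' `ltp_integral` (0.05 nS).
#'
#' @param t_sleep,t_wake sleep bounds (315 s, 585 s).
#' @param t_ltp_peak LTP Gaussian peak time (405 s).
#' @param t_ltp_std LTP Gaussian SD (45 s).
#' @param ltp_integral time integral of the unmodulated Gaussian (nS).
#' @return object of class `sleep_schedule`.
#' @export
sleep_schedule <- function(t_sleep = 315, t_wake = 585, t_ltp_peak = 405,
                           t_ltp_std = 45, ltp_integral = 0.05) {
  if (!(t_sleep < t_ltp_peak && t_ltp_peak < t_wake)) {
    stop("need t_sleep < t_ltp_peak < t_wake", call. = FALSE)
  }
  .check_positive(t_ltp_std, "t_ltp_std")
  structure(list(t_sleep = t_sleep, t_wake = t_wake,
                 t_ltp_peak = t_ltp_peak, t_ltp_std = t_ltp_std,
                 ltp_integral = ltp_integral),
            class = "sleep_schedule")
}

#' Sleep-modulated STDP constants
#'
#' Inside `[t_sleep, t_wake)` the potentiation constant is weakened and the
#' depression constant strengthened: `C_p / gamma` and `C_d * gamma`
#' (default mode). The literal alternative in which both constants are
#' multiplied by gamma is available as `mode = "both_multiplied"`.
#'
#' @param cfg an [stdp_config()].
#' @param gamma_sleep modulation factor (> 0).
#' @param t current time (s).
#' @param schedule a [sleep_schedule()].
#' @param mode `"weaken_potentiation"` (default) or `"both_multiplied"`.
#' @return list with effective `c_p` and `c_d`.
#' @export
sleep_modulated_constants <- function(cfg, gamma_sleep, t, schedule,
                                      mode = c("weaken_potentiation",
                                               "both_multiplied")) {
  mode <- match.arg(mode)
  if (gamma_sleep <= 0) stop("`gamma_sleep` must be positive", call. = FALSE)
  if (t >= schedule$t_sleep && t < schedule$t_wake) {
    if (mode == "weaken_potentiation") {
      list(c_p = cfg$c_p / gamma_sleep, c_d = cfg$c_d * gamma_sleep)
    } else {
      list(c_p = cfg$c_p * gamma_sleep, c_d = cfg$c_d * gamma_sleep)
    }
  } else {
    list(c_p = cfg$c_p, c_d = cfg$c_d)
  }
}

#' Multiplicative weight normalization
#'
#' Applies the plastic increments, clips negative weights to zero, and
#' rescales every neuron's row so its mean input weight is exactly `omega`,
#' preserving within-row proportions.
#'
#' @param W n x m weight matrix (nS).
#' @param dW increment matrix (or 0).
#' @param omega per-neuron mean weight target (0.25 nS).
#' @return normalized weight matrix; error if any row mean is non-positive.
#' @export
normalize_weights <- function(W, dW = 0, omega = 0.25) {
  W2 <- pmax(W + dW, 0)
  rm <- rowMeans(W2)
  if (any(rm <= 0)) stop("non-positive row mean after update", call. = FALSE)
  W2 * (omega / rm)
}

#' Embossing plan: LTP gain pattern from another neuron's weights
#'
#' For each neuron i a reference neuron `k(i) != i` is drawn (a random
#' derangement, so the intended post-sleep selectivity pattern is a
#' permutation of the pre-sleep one), and the gain is the reference row
#' normalized by its mean: `theta_ij = W_k(i),j / mean_x(W_k(i),x)`. The
#' plan is only active from sleep onset (Heaviside gating, applied by the
#' simulator).
#'
#' @param W weight matrix snapshot taken strictly before sleep onset.
#' @param seed optional integer seed.
#' @return object of class `embossing_plan`: list with `k` (reference
#'   indices) and `theta` (gain matrix).
#' @export
build_embossing_plan <- function(W, seed = NULL) {
  .seed_if_given(seed)
  n <- nrow(W)
  if (any(rowMeans(W) <= 0)) stop("all-zero reference row", call. = FALSE)
  k <- .random_derangement(n)
  theta <- W[k, , drop = FALSE] / rowMeans(W)[k]
  structure(list(k = k, theta = theta), class = "embossing_plan")
}

# Rejection-sample a uniform derangement (no fixed points).
.random_derangement <- function(n) {
  if (n < 2L) stop("need at least 2 neurons for a derangement", call. = FALSE)
  repeat {
    p <- sample.int(n)
    if (all(p != seq_len(n))) return(p)
  }
}

#' Embossing LTP increment at a time point
#'
#' `kappa * theta_ij * A * exp(-(t - t_peak)^2 / (2 t_std^2)) * dt`, with
#' `A = ltp_integral / (t_std * sqrt(2*pi))` so the unmodulated Gaussian
#' integrates to `ltp_integral` (0.05 nS) regardless of step size.
#'
#' @param t time (s).
#' @param plan an [build_embossing_plan()] result (or its `theta`).
#' @param kappa_sleep overall LTP gain.
#' @param schedule a [sleep_schedule()].
#' @param dt simulation step (s).
#' @return increment matrix (nS).
#' @export
ltp_bonus_m2 <- function(t, plan, kappa_sleep, schedule, dt = 0.001) {
  theta <- if (inherits(plan, "embossing_plan")) plan$theta else plan
  A <- schedule$ltp_integral / (schedule$t_ltp_std * sqrt(2 * pi))
  z <- (t - schedule$t_ltp_peak) / schedule$t_ltp_std
  gate <- as.numeric(t >= schedule$t_sleep)
  kappa_sleep * theta * A * exp(-0.5 * z * z) * dt * gate
}

#' Run the hippocampo-cortical LIF network through a sleep cycle
#'
#' Simulates wake (pattern formation), sleep (halved input rates, gamma-
#' modulated STDP, embossing LTP) and wake again. The embossing plan is
#' built from the weights at the last step before sleep onset. Weight
#' snapshots and per-neuron memory selectivity are recorded on a fixed
#' stride; selectivity switch (`T_S`) and LTP hit (`T_H`) proportions are
#' computed against the final snapshot together with their surrogate
#' shuffle tests.
#'
#' @param gamma_sleep STDP modulation factor during sleep (1 = none).
#' @param kappa_sleep embossing LTP gain (0 = none).
#' @param duration total duration (s); must exceed `schedule$t_wake`.
#' @param lif a [lif_config()].
#' @param stdp an [stdp_config()].
#' @param schedule a [sleep_schedule()].
#' @param input_cfg a [two_memory_config()] (its sleep interval is forced to
#'   the schedule's).
#' @param omega per-neuron mean weight (0.25 nS).
#' @param snapshot_stride_s snapshot interval (s).
#' @param gamma_mode see [sleep_modulated_constants()].
#' @param n_surrogates surrogate shuffles for the significance tests (200).
#' @param seed optional integer seed.
#' @return object of class `model2_run`: list with `times`, `W_snapshots`
#'   (n*m rows, one column per snapshot), `W_final`, `sel` (neurons x
#'   snapshots selectivity matrix), `sel_sleep`, `sel_final`, `sel_theta`,
#'   `plan`, `T_S`, `T_H`, `surrogate_S`, `surrogate_H`, `spike_counts`,
#'   and the configurations.
#' @export
run_model2 <- function(gamma_sleep = 1, kappa_sleep = 0, duration = 900,
                       lif = lif_config(), stdp = stdp_config(),
                       schedule = sleep_schedule(),
                       input_cfg = two_memory_config(),
                       omega = 0.25, snapshot_stride_s = 5,
                       gamma_mode = c("weaken_potentiation",
                                      "both_multiplied"),
                       n_surrogates = 200L, seed = NULL) {
  gamma_mode <- match.arg(gamma_mode)
  if (duration <= schedule$t_wake) {
    stop("`duration` must exceed the sleep end time", call. = FALSE)
  }
  if (gamma_sleep <= 0) stop("`gamma_sleep` must be positive", call. = FALSE)
  stopifnot(inherits(lif, "lif_config"), inherits(stdp, "stdp_config"),
            inherits(schedule, "sleep_schedule"),
            inherits(input_cfg, "two_memory_config"),
            lif$m_inputs == input_cfg$m)
  .seed_if_given(seed)
  dt <- lif$dt
  # Input raster for the full run, rates halved inside the sleep interval.
  icfg <- input_cfg
  icfg$t_sleep <- schedule$t_sleep
  icfg$t_wake <- schedule$t_wake
  inp <- gen_two_memory_input(icfg, duration)
  ext_unit <- rep.int(seq_len(icfg$m), lengths(inp$raster$spikes))
  ext_time <- unlist(inp$raster$spikes, use.names = FALSE)
  ext_step <- as.integer(floor(ext_time / dt)) + 1L
  ord <- order(ext_step)
  ext_step <- ext_step[ord]; ext_unit <- ext_unit[ord]

  n <- lif$n_neurons; m <- lif$m_inputs
  W <- normalize_weights(matrix(stats::runif(n * m), n, m), 0, omega)

  run_phase <- function(state, step_lo, step_hi, theta, kappa) {
    sim_model2_cpp(
      W = state$W, ext_step = ext_step, ext_unit = ext_unit,
      step_lo = step_lo, step_hi = step_hi, dt = dt,
      tau_m = lif$tau_m, v_rest = lif$v_rest, v_th = lif$v_thresh,
      v_reset = lif$v_reset, t_ref = lif$t_ref,
      tau_syn = lif$tau_syn, tau_inh = lif$tau_inh,
      e_exc = lif$e_exc, e_inh = lif$e_inh, g_leak = lif$g_leak,
      inh_weight = lif$inh_weight,
      inh_delay_steps = max(1L, as.integer(round(lif$inh_delay / dt))),
      tau_stdp = stdp$tau_stdp, c_p = stdp$c_p, c_d = stdp$c_d,
      sigma_v = stdp$sigma_v,
      t_sleep = schedule$t_sleep, t_wake = schedule$t_wake,
      gamma_sleep = gamma_sleep,
      gamma_both = gamma_mode == "both_multiplied",
      has_ltp = kappa > 0, theta = theta, kappa = kappa,
      t_peak = schedule$t_ltp_peak, t_std = schedule$t_ltp_std,
      ltp_A = schedule$ltp_integral / (schedule$t_ltp_std * sqrt(2 * pi)),
      omega = omega,
      V = state$V, g_e = state$g_e, g_i = state$g_i,
      ref_until = state$ref_until,
      last_pre = state$last_pre, last_post = state$last_post,
      inh_queue = state$inh_queue,
      snapshot_stride = max(1L, as.integer(round(snapshot_stride_s / dt))))
  }
  n_steps <- as.integer(floor(duration / dt + 1e-9))
  sleep_step <- as.integer(floor(schedule$t_sleep / dt + 1e-9))
  wake_step <- as.integer(floor(schedule$t_wake / dt + 1e-9))
  state0 <- list(W = W, V = rep(lif$v_rest, n), g_e = numeric(n),
                 g_i = numeric(n), ref_until = rep(-1, n),
                 last_pre = rep(-1e9, m), last_post = rep(-1e9, n),
                 inh_queue = integer(max(1L,
                   as.integer(round(lif$inh_delay / dt)))))
  as_state <- function(ph) {
    list(W = ph$W, V = ph$V, g_e = ph$g_e, g_i = ph$g_i,
         ref_until = ph$ref_until, last_pre = ph$last_pre,
         last_post = ph$last_post, inh_queue = ph$inh_queue)
  }
  ph1 <- run_phase(state0, 1L, sleep_step, matrix(0, 1, 1), 0)
  plan <- build_embossing_plan(ph1$W)     # weights at t_sleep - dt
  ph2 <- run_phase(as_state(ph1), sleep_step + 1L, wake_step, plan$theta,
                   kappa_sleep)
  ph3 <- run_phase(as_state(ph2), wake_step + 1L, n_steps, plan$theta,
                   kappa_sleep)

  times <- c(ph1$snap_steps, ph2$snap_steps, ph3$snap_steps) * dt
  W_snapshots <- cbind(ph1$snaps, ph2$snaps, ph3$snaps)
  mA <- input_cfg$memory_a; mB <- input_cfg$memory_b
  sel <- apply(W_snapshots, 2L, function(wv) {
    selectivity_matrix(matrix(wv, n, m), mA, mB)
  })
  sel_sleep <- selectivity_matrix(ph1$W, mA, mB)  # at t_sleep
  sel_final <- selectivity_matrix(ph3$W, mA, mB)  # Sel[infinity]
  sel_theta <- selectivity_matrix(plan$theta, mA, mB)
  T_S <- proportion_switches(sel_sleep, sel_final)
  T_H <- proportion_hits(sel_theta, sel_final)
  sur_S <- surrogate_test(sel_sleep, sel_final, statistic = "switch",
                          n_surrogates = n_surrogates)
  sur_H <- surrogate_test(sel_theta, sel_final, statistic = "hit",
                          n_surrogates = n_surrogates)
  structure(list(times = times, W_snapshots = W_snapshots,
                 W_final = ph3$W, sel = sel, sel_sleep = sel_sleep,
                 sel_final = sel_final, sel_theta = sel_theta, plan = plan,
                 T_S = T_S, T_H = T_H,
                 surrogate_S = sur_S, surrogate_H = sur_H,
                 spike_counts = ph1$spike_counts + ph2$spike_counts +
                   ph3$spike_counts,
                 spikes = {
                   st <- c(ph1$sp_step, ph2$sp_step, ph3$sp_step)
                   su <- c(ph1$sp_unit, ph2$sp_unit, ph3$sp_unit)
                   tm <- (st - 0.5) * dt
                   spike_raster(lapply(split(tm, factor(su, levels = seq_len(n))),
                                       as.numeric),
                                duration_s = n_steps * dt)
                 },
                 rate_wake_hz = sum(ph1$spike_counts) /
                   (lif$n_neurons * schedule$t_sleep),
                 rate_sleep_hz = sum(ph2$spike_counts) /
                   (lif$n_neurons * (schedule$t_wake - schedule$t_sleep)),
                 gamma_sleep = gamma_sleep, kappa_sleep = kappa_sleep,
                 lif = lif, stdp = stdp, schedule = schedule,
                 input_labels = inp$labels),
            class = "model2_run")
}

#' @export
print.model2_run <- function(x, ...) {
  cat(sprintf(
    "<model2_run> gamma=%.2f kappa=%.2f  T_S=%.3f (p=%.3g)  T_H=%.3f (p=%.3g)\n",
    x$gamma_sleep, x$kappa_sleep, x$T_S, x$surrogate_S$p_value,
    x$T_H, x$surrogate_H$p_value))
  invisible(x)
}
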