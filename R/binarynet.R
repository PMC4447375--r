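#' Configuration of the stochastic binary network
#'
#' A fully connected excitatory network of N stochastic binary units updated
#' every 4 ms. The total current of unit i is
#' `I_i = w_ie * e_i + (1/(N-1)) * sum_j w_ij * v_j`, the firing probability
#' is the adjusted sigmoid `P = 1 / (1 + exp(K_t - K_s * I))`, and weights
#' follow a stable Hebbian rule: synchronous firing within a bin potentiates
#' by `C_p * J(w) * dt` with `J(w) = exp(-w) - exp(-1)` (stronger for weak
#' synapses, zero at w = 1), while a presynaptic spike without a
#' postsynaptic one depresses by `C_d * (0 - theta) * dt`.
#'
#' @param N neuron count (>= 2).
#' @param K_t,K_s sigmoid constants (6, 11); with these values the
#'   spontaneous network (w_ie = 0) fires at roughly 0.5-1 Hz.
#' @param w_ie external input weight (0.5).
#' @param dt update step in seconds (0.004).
#' @param C_p potentiation rate (6.25 / s).
#' @param C_d depression rate (0.021 / s).
#' @param theta depression threshold (1).
#' @param w_min,w_max weight clip bounds. The floor prevents negative
#'   weights (the depression rule has none of its own); the ceiling is a
#'   guard for the additive LTP bonus.
#' @return object of class `model1_config`.
#' @export
model1_config <- function(N, K_t = 6, K_s = 11, w_ie = 0.5, dt = 0.004,
                          C_p = 6.25, C_d = 0.021, theta = 1,
                          w_min = 0, w_max = 1.5) {
  if (!is.numeric(N) || N < 2) stop("`N` must be >= 2", call. = FALSE)
  .check_positive(dt, "dt")
  .check_nonnegative(C_p, "C_p")
  .check_nonnegative(C_d, "C_d")
  if (w_max <= w_min) stop("`w_max` must exceed `w_min`", call. = FALSE)
  structure(list(N = as.integer(N), K_t = K_t, K_s = K_s, w_ie = w_ie,
                 dt = dt, C_p = C_p, C_d = C_d, theta = theta,
                 w_min = w_min, w_max = w_max),
            class = "model1_config")
}

#' Initialize a weight matrix
#'
#' Off-diagonal entries uniform on `[0, 1]`, diagonal fixed at 0 (no
#' self-connections, ever).
#'
#' @param cfg a [model1_config()].
#' @param seed optional integer seed.
#' @return N x N numeric matrix.
#' @export
init_weights <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "model1_config"))
  .seed_if_given(seed)
  w <- matrix(stats::runif(cfg$N * cfg$N), cfg$N, cfg$N)
  diag(w) <- 0
  w
}

#' Total synaptic current
#'
#' `I_i = w_ie * e_i + (1/(N-1)) * sum_j w_ij * v_j`. The diagonal is
#' excluded automatically because `w_ii = 0`.
#'
#' @param v binary state vector (length N).
#' @param w N x N weight matrix (zero diagonal).
#' @param e external binary input vector (length N).
#' @param cfg a [model1_config()].
#' @return numeric current vector of length N.
#' @export
total_current <- function(v, w, e, cfg) {
  stopifnot(inherits(cfg, "model1_config"))
  N <- cfg$N
  if (length(v) != N || length(e) != N || !all(dim(w) == c(N, N))) {
    stop("dimension mismatch between v, e, w and cfg$N", call. = FALSE)
  }
  cfg$w_ie * e + as.vector(w %*% v) / (N - 1)
}

#' Firing probability from current
#'
#' The adjusted sigmoid `P = 1 / (1 + exp(K_t - K_s * I))`; strictly in
#' (0, 1) and increasing in I, with midpoint at `I = K_t / K_s`.
#'
#' @param current numeric current vector.
#' @param cfg a [model1_config()].
#' @return probability vector.
#' @export
fire_probability <- function(current, cfg) {
  stopifnot(inherits(cfg, "model1_config"))
  1 / (1 + exp(cfg$K_t - cfg$K_s * current))
}

#' One Hebbian plasticity step
#'
#' Applies the instantaneous rule to every ordered pair (post i, pre j),
#' i != j, given the binary states of the current 4 ms bin: if both fire,
#' `w_ij += C_p * (exp(-w_ij) - exp(-1)) * dt`; if only the presynaptic unit
#' fires, `w_ij += C_d * (v_i - theta) * dt`; if the presynaptic unit is
#' silent, no change. Weights are then clipped to `[w_min, w_max]` and the
#' diagonal stays 0.
#'
#' @param v binary state vector of the current bin.
#' @param w N x N weight matrix.
#' @param cfg a [model1_config()].
#' @return updated weight matrix.
#' @export
hebbian_step <- function(v, w, cfg) {
  stopifnot(inherits(cfg, "model1_config"))
  N <- cfg$N
  if (length(v) != N || !all(dim(w) == c(N, N))) {
    stop("dimension mismatch", call. = FALSE)
  }
  v <- as.numeric(v != 0)
  # Potentiation carries v_i * v_j; the depression term carries
  # (v_i - theta) * v_j and vanishes for synchronous pairs when theta = 1.
  pot <- cfg$C_p * (exp(-w) - exp(-1)) * (v %o% v)
  dep <- cfg$C_d * ((v - cfg$theta) %o% v)
  w2 <- w + (pot + dep) * cfg$dt
  w2 <- pmin(pmax(w2, cfg$w_min), cfg$w_max)
  diag(w2) <- 0
  w2
}

#' Simulate the binary network
#'
#' Per step: currents are computed from the previous bin's states, new
#' states are drawn from the sigmoid probability, and plasticity is applied
#' to the new-bin states; if an LTP schedule is supplied its Gaussian bonus
#' is added each step from the trigger time onwards. Snapshots of the weight
#' matrix are recorded every `snapshot_stride` steps (the initial matrix is
#' snapshot 1). The simulation uses R's RNG, so runs are reproducible under
#' `set.seed()` / the `seed` argument.
#'
#' @param cfg a [model1_config()].
#' @param external a [spike_raster()] with `n_units == N`; each external
#'   unit drives exactly one network neuron (feedforward only; external
#'   spikes do not act as presynaptic partners in the plasticity rule).
#' @param duration seconds to simulate (default: the raster duration).
#' @param ltp optional [ltp_schedule()].
#' @param snapshot_stride snapshot interval in steps (default 250 = 1 s).
#' @param w_init optional initial weight matrix (default [init_weights()]).
#' @param v_init optional initial binary state (default all zero).
#' @param t0 absolute time (s) of the simulation start; external spike times
#'   are interpreted relative to the run, while the LTP Gaussian is
#'   evaluated at absolute time `t0 + step * dt`.
#' @param record_spikes record the network spike raster (default TRUE).
#' @param seed optional integer seed.
#' @return object of class `weight_trajectory`: list with `times` (absolute
#'   snapshot times), `W` (matrix, N^2 rows, one column per snapshot,
#'   column-major vectorization), `N`, `config`, `w_final`, `v_final`,
#'   `spikes` (network [spike_raster()] or NULL), `t0`.
#' @export
simulate_model1 <- function(cfg, external, duration = external$duration_s,
                            ltp = NULL, snapshot_stride = 250L,
                            w_init = NULL, v_init = NULL, t0 = 0,
                            record_spikes = TRUE, seed = NULL) {
  stopifnot(inherits(cfg, "model1_config"), inherits(external, "spike_raster"))
  if (external$n_units != cfg$N) {
    stop("external raster must have one unit per network neuron",
         call. = FALSE)
  }
  if (duration > external$duration_s + 1e-9) {
    stop("external raster shorter than requested simulation", call. = FALSE)
  }
  .seed_if_given(seed)
  n_steps <- as.integer(floor(duration / cfg$dt + 1e-9))
  if (n_steps < 1L) stop("duration shorter than one step", call. = FALSE)
  if (is.null(w_init)) w_init <- init_weights(cfg)
  if (!all(dim(w_init) == c(cfg$N, cfg$N))) stop("w_init dimension mismatch",
                                                 call. = FALSE)
  if (is.null(v_init)) v_init <- integer(cfg$N)
  # Flatten external spikes to (step, unit) pairs sorted by step.
  ext_unit <- rep.int(seq_len(cfg$N), lengths(external$spikes))
  ext_time <- unlist(external$spikes, use.names = FALSE)
  if (length(ext_time)) {
    ext_step <- as.integer(floor(ext_time / cfg$dt)) + 1L
    keep <- ext_step <= n_steps
    ord <- order(ext_step[keep])
    ext_step <- ext_step[keep][ord]
    ext_unit <- ext_unit[keep][ord]
  } else {
    ext_step <- integer(0)
    ext_unit <- integer(0)
  }
  has_ltp <- !is.null(ltp)
  if (has_ltp) stopifnot(inherits(ltp, "ltp_schedule"))
  res <- sim_model1_cpp(
    w = w_init, v0 = as.integer(v_init != 0),
    ext_step = ext_step, ext_unit = ext_unit,
    n_steps = n_steps, t0 = t0,
    K_t = cfg$K_t, K_s = cfg$K_s, w_ie = cfg$w_ie, dt = cfg$dt,
    C_p = cfg$C_p, C_d = cfg$C_d, theta = cfg$theta,
    w_min = cfg$w_min, w_max = cfg$w_max,
    snapshot_stride = as.integer(snapshot_stride),
    record_spikes = record_spikes,
    has_ltp = has_ltp,
    cieg = if (has_ltp) ltp$cieg else matrix(0, 1, 1),
    ltp_t_T = if (has_ltp) ltp$t_T else 0,
    ltp_mu = if (has_ltp) ltp$mu else 0,
    ltp_sigma = if (has_ltp) ltp$sigma else 1,
    ltp_scaled = if (has_ltp) ltp$scaled else TRUE)
  spikes <- NULL
  if (record_spikes) {
    sp_t <- (res$sp_step - 0.5) * cfg$dt  # bin-center times, relative to run
    spikes_list <- split(sp_t, factor(res$sp_unit, levels = seq_len(cfg$N)))
    spikes <- spike_raster(lapply(spikes_list, as.numeric),
                           duration_s = n_steps * cfg$dt)
  }
  structure(list(times = t0 + res$snap_steps * cfg$dt,
                 W = res$snaps, N = cfg$N, config = cfg,
                 w_final = res$w_final, v_final = res$v_final,
                 spikes = spikes, t0 = t0),
            class = "weight_trajectory")
}

#' @export
print.weight_trajectory <- function(x, ...) {
  cat(sprintf("<weight_trajectory> N=%d, %d snapshots over [%.1f, %.1f] s\n",
              x$N, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Extract one snapshot as a matrix
#' @param traj a `weight_trajectory`.
#' @param i snapshot index (default: last).
#' @return N x N weight matrix.
#' @export
traj_snapshot <- function(traj, i = length(traj$times)) {
  stopifnot(inherits(traj, "weight_trajectory"))
  matrix(traj$W[, i], traj$N, traj$N)
}

#' Run the binary network on Poisson input until steady state
#'
#' Feeds independent Poisson spike trains at a fixed rate and simulates in
#' chunks until every synapse's trailing-window OLS slope satisfies
#' `|dw/dt| <= eps`, or `max_duration` is reached. Snapshots are taken every
#' second; the slope window defaults to 100 s.
#'
#' @param cfg a [model1_config()].
#' @param rate input rate in Hz.
#' @param eps convergence threshold on |dw/dt| (0.00025 / s).
#' @param window_s trailing OLS window in seconds.
#' @param chunk_s chunk length in seconds.
#' @param max_duration give-up horizon in seconds.
#' @param seed optional integer seed.
#' @return list with `converged` (logical), `time` (convergence time, s; NA
#'   if not reached), `w_init`, `w_final`, `mean_w` (mean off-diagonal
#'   weight at the end), `mean_w_series` (per-second mean-weight series) and
#'   `rate`.
#' @export
run_model1_to_convergence <- function(cfg, rate, eps = 0.00025,
                                      window_s = 500, chunk_s = 250,
                                      max_duration = 12000, seed = NULL) {
  stopifnot(inherits(cfg, "model1_config"))
  .seed_if_given(seed)
  stride <- max(1L, as.integer(round(1 / cfg$dt)))  # 1-s snapshots
  w <- init_weights(cfg)
  w0 <- w
  v <- integer(cfg$N)
  buf_t <- numeric(0)
  buf_w <- NULL                       # N^2 x k rolling snapshot buffer
  mean_series <- numeric(0)
  t_now <- 0
  converged_at <- NA_real_
  off <- .offdiag_mask(cfg$N)
  n_keep <- as.integer(window_s) + 1L
  while (t_now < max_duration && is.na(converged_at)) {
    ext <- gen_poisson_raster(cfg$N, rate, chunk_s)
    traj <- simulate_model1(cfg, ext, duration = chunk_s,
                            snapshot_stride = stride, w_init = w, v_init = v,
                            t0 = t_now, record_spikes = FALSE)
    w <- traj$w_final
    v <- traj$v_final
    keep <- if (length(buf_t)) -1L else TRUE  # drop duplicated boundary snapshot
    new_t <- traj$times
    new_w <- traj$W
    if (length(buf_t)) { new_t <- new_t[-1L]; new_w <- new_w[, -1L, drop = FALSE] }
    buf_t <- c(buf_t, new_t)
    buf_w <- if (is.null(buf_w)) new_w else cbind(buf_w, new_w)
    mean_series <- c(mean_series, colMeans(new_w[off, , drop = FALSE]))
    if (length(buf_t) > n_keep) {
      drop <- seq_len(length(buf_t) - n_keep)
      buf_t <- buf_t[-drop]
      buf_w <- buf_w[, -drop, drop = FALSE]
    }
    t_now <- t_now + chunk_s
    if (length(buf_t) >= n_keep) {
      tc <- buf_t - mean(buf_t)
      slopes <- as.vector(buf_w %*% tc) / sum(tc * tc)
      if (all(abs(slopes) <= eps)) converged_at <- buf_t[length(buf_t)]
    }
  }
  list(converged = !is.na(converged_at), time = converged_at,
       w_init = w0, w_final = w,
       mean_w = mean(w[off]),
       mean_w_series = mean_series, rate = rate)
}

# Logical mask of off-diagonal entries of an N x N matrix (vectorized).
.offdiag_mask <- function(N) {
  m <- matrix(TRUE, N, N)
  diag(m) <- FALSE
  as.vector(m)
}

#' Mean firing rate of a simulated network
#' @param traj a `weight_trajectory` with recorded spikes.
#' @return mean rate in Hz across neurons.
#' @export
network_mean_rate <- function(traj) {
  stopifnot(inherits(traj, "weight_trajectory"))
  if (is.null(traj$spikes)) stop("trajectory has no recorded spikes",
                                 call. = FALSE)
  mean(raster_rates(traj$spikes))
}
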