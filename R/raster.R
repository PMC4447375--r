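#' Spike raster container
#'
#' A spike raster holds, for each of `n_units` units, a sorted vector of spike
#' times in seconds over `[0, duration_s)`. Rasters are the common currency of
#' the package: the generators below produce them, the binary network consumes
#' them as external drive, and the integrate-and-fire network consumes the
#' two-memory variant.
#'
#' @param spikes list of numeric vectors, one per unit, each strictly
#'   increasing, all times in `[0, duration_s)`.
#' @param duration_s total duration in seconds.
#' @param bin_width_s default bin width in seconds used when the raster is
#'   binned to a binary matrix (0.004 s, the synchrony bin of the binary
#'   network model).
#' @return An object of class `spike_raster`.
#' @export
spike_raster <- function(spikes, duration_s, bin_width_s = 0.004) {
  stopifnot(is.list(spikes))
  .check_positive(duration_s, "duration_s")
  .check_positive(bin_width_s, "bin_width_s")
  for (i in seq_along(spikes)) {
    s <- spikes[[i]]
    if (length(s)) {
      if (any(!is.finite(s)) || any(s < 0) || any(s >= duration_s)) {
        stop(sprintf("unit %d has spike times outside [0, duration_s)", i),
             call. = FALSE)
      }
      if (is.unsorted(s, strictly = TRUE)) {
        stop(sprintf("unit %d spike times are not strictly increasing", i),
             call. = FALSE)
      }
    }
    spikes[[i]] <- as.numeric(s)
  }
  structure(
    list(spikes = spikes, n_units = length(spikes),
         duration_s = as.numeric(duration_s),
         bin_width_s = as.numeric(bin_width_s)),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  n_sp <- sum(lengths(x$spikes))
  cat(sprintf(
    "<spike_raster> %d units, %.1f s, %d spikes (mean rate %.3f Hz)\n",
    x$n_units, x$duration_s, n_sp,
    n_sp / max(1e-12, x$n_units * x$duration_s)))
  invisible(x)
}

#' Bin a raster to a binary matrix
#'
#' Multiple spikes falling in the same bin collapse to 1: the binary neuron
#' model admits only \{0, 1\} states per 4 ms bin.
#'
#' @param raster a [spike_raster()].
#' @param bin_width_s bin width in seconds; defaults to the raster's own.
#' @return integer matrix (`n_units` x `n_bins`) of 0/1.
#' @export
bin_raster <- function(raster, bin_width_s = raster$bin_width_s) {
  stopifnot(inherits(raster, "spike_raster"))
  .check_positive(bin_width_s, "bin_width_s")
  n_bins <- max(1L, as.integer(ceiling(raster$duration_s / bin_width_s - 1e-9)))
  out <- matrix(0L, nrow = raster$n_units, ncol = n_bins)
  for (i in seq_len(raster$n_units)) {
    b <- pmin(n_bins, floor(raster$spikes[[i]] / bin_width_s) + 1L)
    out[i, unique(b)] <- 1L
  }
  out
}

#' Empirical per-unit firing rates
#' @param raster a [spike_raster()].
#' @return numeric vector of rates in Hz.
#' @export
raster_rates <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  lengths(raster$spikes) / raster$duration_s
}

#' Mean pairwise binned Pearson correlation
#'
#' Bins the raster to a binary matrix and returns the mean off-diagonal
#' Pearson correlation between units. Units with no variance (silent or
#' saturated) are dropped with a warning.
#'
#' @param raster a [spike_raster()].
#' @param bin_width_s bin width in seconds.
#' @return scalar mean off-diagonal correlation.
#' @export
raster_pairwise_corr <- function(raster, bin_width_s = raster$bin_width_s) {
  m <- bin_raster(raster, bin_width_s)
  v <- apply(m, 1L, stats::var)
  keep <- v > 0
  if (!all(keep)) {
    warning(sprintf("%d unit(s) with zero variance dropped from correlation",
                    sum(!keep)))
  }
  if (sum(keep) < 2L) return(NA_real_)
  cc <- stats::cor(t(m[keep, , drop = FALSE]))
  mean(cc[lower.tri(cc)])
}

# Internal: one homogeneous Poisson spike train on [0, duration).
.poisson_train <- function(rate, duration) {
  k <- stats::rpois(1L, rate * duration)
  if (k == 0L) return(numeric(0))
  # unique() guards against double-precision ties (strictly increasing times)
  unique(sort(stats::runif(k, 0, duration)))
}

#' Generate independent Poisson spike trains
#'
#' Homogeneous Poisson processes, independent across units, emulating
#' non-correlated external drive at the mean rates observed across wake-sleep
#' states (roughly 3-40 Hz).
#'
#' @param n number of units.
#' @param rate mean firing rate in Hz (>= 0).
#' @param duration duration in seconds.
#' @param seed optional integer seed.
#' @return a [spike_raster()].
#' @export
gen_poisson_raster <- function(n, rate, duration, seed = NULL) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  .check_nonnegative(rate, "rate")
  .check_positive(duration, "duration")
  .seed_if_given(seed)
  spikes <- lapply(seq_len(n), function(i) .poisson_train(rate, duration))
  spike_raster(spikes, duration)
}

#' Generate correlated Poisson spike trains
#'
#' Uses a shared mother train: a hidden Poisson process at the target rate
#' whose events are copied to each unit with probability `sqrt(corr_target)`;
#' the remaining rate is filled with independent Poisson spikes so each unit's
#' mean rate is preserved. For small per-bin spike probabilities the expected
#' pairwise binned Pearson correlation equals the copy probability squared,
#' i.e. `corr_target`.
#'
#' @param n number of units.
#' @param rate mean firing rate in Hz.
#' @param corr_target target mean pairwise binned Pearson correlation, in
#'   `[0, 1)`.
#' @param duration duration in seconds.
#' @param seed optional integer seed.
#' @param jitter_s optional Gaussian jitter (s) applied to copied events;
#'   default 0 keeps copies exactly synchronous within a bin.
#' @return a [spike_raster()].
#' @export
gen_correlated_raster <- function(n, rate, corr_target, duration, seed = NULL,
                                  jitter_s = 0) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  .check_nonnegative(rate, "rate")
  .check_positive(duration, "duration")
  .check_nonnegative(jitter_s, "jitter_s")
  if (!is.numeric(corr_target) || corr_target < 0 || corr_target >= 1) {
    stop("`corr_target` must be in [0, 1)", call. = FALSE)
  }
  .seed_if_given(seed)
  if (corr_target == 0 || rate == 0) {
    return(gen_poisson_raster(n, rate, duration))
  }
  p_copy <- sqrt(corr_target)
  mother <- .poisson_train(rate, duration)
  spikes <- lapply(seq_len(n), function(i) {
    shared <- mother[stats::runif(length(mother)) < p_copy]
    if (jitter_s > 0 && length(shared)) {
      shared <- shared + stats::rnorm(length(shared), 0, jitter_s)
      shared <- shared[shared >= 0 & shared < duration]
    }
    own <- .poisson_train(rate * (1 - p_copy), duration)
    s <- sort(c(shared, own))
    unique(s)
  })
  spike_raster(spikes, duration)
}

#' Generate a state-conditioned raster from a hypnogram
#'
#' Within each hypnogram episode the units fire as correlated Poisson
#' processes with that state's mean rate and pairwise correlation target
#' (shared mother-train mechanism as in [gen_correlated_raster()]). Units
#' additionally carry persistent log-normal rate multipliers
#' (`rate_cv` controls their spread), emulating the broad per-unit firing
#' rate distributions of population recordings: a unit that is fast in one
#' state is fast in every state. The default parameters respect the
#' empirical orderings across wake-sleep states: firing rate
#' WK > REM > SWS and synchrony WK > SWS > REM.
#'
#' @param hyp a [hypnogram()].
#' @param stats_by_state a [state_stats()] list.
#' @param n number of units.
#' @param rate_cv coefficient of variation of the per-unit rate multipliers
#'   (0 gives homogeneous units; default 0.6, giving a realistic several-
#'   fold spread of unit rates).
#' @param seed optional integer seed.
#' @return a [spike_raster()] spanning the hypnogram duration.
#' @export
gen_state_raster <- function(hyp, stats_by_state = state_stats(), n,
                             rate_cv = 0.6, seed = NULL) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1", call. = FALSE)
  .check_nonnegative(rate_cv, "rate_cv")
  for (s in c("WK", "SWS", "REM")) {
    if (is.null(stats_by_state[[s]])) {
      stop(sprintf("`stats_by_state` missing state %s", s), call. = FALSE)
    }
  }
  .seed_if_given(seed)
  # persistent per-unit rate multipliers, mean 1
  mult <- if (rate_cv > 0) {
    sdl <- sqrt(log(1 + rate_cv^2))
    stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
  } else rep(1, n)
  duration <- hyp$end_s[nrow(hyp)]
  per_unit <- vector("list", n)
  for (i in seq_len(n)) per_unit[[i]] <- vector("list", nrow(hyp))
  for (ep in seq_len(nrow(hyp))) {
    st <- hyp$state[ep]
    len <- hyp$end_s[ep] - hyp$start_s[ep]
    if (len <= 0) next
    pars <- stats_by_state[[st]]
    rate <- pars$mean_rate_hz
    p_copy <- sqrt(pars$pairwise_corr)
    jit <- pars$jitter_s %||% 0
    mother <- if (p_copy > 0) .poisson_train(rate, len) else numeric(0)
    for (i in seq_len(n)) {
      shared <- mother[stats::runif(length(mother)) < p_copy]
      if (jit > 0 && length(shared)) {
        shared <- shared + stats::rnorm(length(shared), 0, jit)
        shared <- shared[shared >= 0 & shared < len]
      }
      fill <- max(0, rate * mult[i] - p_copy * rate)
      own <- .poisson_train(fill, len)
      s <- unique(sort(c(shared, own)))
      per_unit[[i]][[ep]] <- s + hyp$start_s[ep]
    }
  }
  spikes <- lapply(per_unit, function(chunks) {
    s <- unlist(chunks, use.names = FALSE)
    if (is.null(s)) numeric(0) else unique(sort(s))
  })
  spike_raster(spikes, duration)
}

#' Default per-state rate and synchrony parameters
#'
#' Rates follow the WK > REM > SWS ordering within the 5-10 Hz range typical
#' of CA1 population recordings; correlation targets follow WK > SWS > REM
#' with REM nearly asynchronous. All values are conventions and fully
#' configurable.
#'
#' @param wk,sws,rem per-state lists with fields `mean_rate_hz`,
#'   `pairwise_corr` and optional `jitter_s`.
#' @return a named list with entries `WK`, `SWS`, `REM`.
#' @export
state_stats <- function(
    wk  = list(mean_rate_hz = 10,  pairwise_corr = 0.06,  jitter_s = 0),
    sws = list(mean_rate_hz = 5,   pairwise_corr = 0.03,  jitter_s = 0),
    rem = list(mean_rate_hz = 7.5, pairwise_corr = 0.005, jitter_s = 0)) {
  for (p in list(wk, sws, rem)) {
    .check_positive(p$mean_rate_hz, "mean_rate_hz")
    if (p$pairwise_corr < 0 || p$pairwise_corr >= 1) {
      stop("`pairwise_corr` must be in [0, 1)", call. = FALSE)
    }
  }
  list(WK = wk, SWS = sws, REM = rem)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Two-memory input configuration
#'
#' 200 input units split into memory A (units 1-100) and memory B (units
#' 101-200). In every 125 ms window exactly one memory is active; active
#' units fire Poisson at 20 Hz and inactive units at 10 Hz, both halved
#' during the sleep interval.
#'
#' @param m total input units.
#' @param memory_a,memory_b unit id sets; must partition `1:m`.
#' @param f_active_hz,f_inactive_hz active/inactive Poisson rates (Hz).
#' @param window_s window length in seconds.
#' @param t_sleep,t_wake sleep interval bounds (s), or `NULL` for no sleep.
#' @param sleep_factor multiplicative rate factor inside the sleep interval.
#' @return an object of class `two_memory_config`.
#' @export
two_memory_config <- function(m = 200L, memory_a = 1:100, memory_b = 101:200,
                              f_active_hz = 20, f_inactive_hz = 10,
                              window_s = 0.125, t_sleep = NULL, t_wake = NULL,
                              sleep_factor = 0.5) {
  if (length(intersect(memory_a, memory_b)) > 0L) {
    stop("memory id sets overlap", call. = FALSE)
  }
  if (!setequal(c(memory_a, memory_b), seq_len(m))) {
    stop("memory_a and memory_b must partition 1..m", call. = FALSE)
  }
  if (!(f_active_hz > f_inactive_hz && f_inactive_hz > 0)) {
    stop("need f_active_hz > f_inactive_hz > 0", call. = FALSE)
  }
  .check_positive(window_s, "window_s")
  if (xor(is.null(t_sleep), is.null(t_wake))) {
    stop("supply both `t_sleep` and `t_wake`, or neither", call. = FALSE)
  }
  structure(list(m = as.integer(m), memory_a = as.integer(memory_a),
                 memory_b = as.integer(memory_b),
                 f_active_hz = f_active_hz, f_inactive_hz = f_inactive_hz,
                 window_s = window_s, t_sleep = t_sleep, t_wake = t_wake,
                 sleep_factor = sleep_factor),
            class = "two_memory_config")
}

#' Generate two-memory alternating Poisson input
#'
#' In each window one memory is chosen uniformly at random to be active.
#' Units of the active memory fire at `f_active_hz`, the others at
#' `f_inactive_hz`; both rates are multiplied by `sleep_factor` for windows
#' whose start lies inside `[t_sleep, t_wake)`. A trailing partial window is
#' truncated.
#'
#' @param cfg a [two_memory_config()].
#' @param duration total duration in seconds.
#' @param seed optional integer seed.
#' @return list with `raster` (a [spike_raster()]), `labels` (character
#'   vector, one of "A"/"B" per window) and `window_s`.
#' @export
gen_two_memory_input <- function(cfg = two_memory_config(), duration,
                                 seed = NULL) {
  stopifnot(inherits(cfg, "two_memory_config"))
  .check_positive(duration, "duration")
  .seed_if_given(seed)
  n_win <- floor(duration / cfg$window_s + 1e-9)
  duration <- n_win * cfg$window_s
  labels <- ifelse(stats::runif(n_win) < 0.5, "A", "B")
  win_start <- (seq_len(n_win) - 1L) * cfg$window_s
  asleep <- if (is.null(cfg$t_sleep)) rep(FALSE, n_win) else {
    win_start >= cfg$t_sleep & win_start < cfg$t_wake
  }
  in_a <- seq_len(cfg$m) %in% cfg$memory_a
  spikes <- vector("list", cfg$m)
  for (u in seq_len(cfg$m)) {
    active_u <- if (in_a[u]) labels == "A" else labels == "B"
    rate_u <- ifelse(active_u, cfg$f_active_hz, cfg$f_inactive_hz)
    rate_u <- ifelse(asleep, rate_u * cfg$sleep_factor, rate_u)
    k <- stats::rpois(n_win, rate_u * cfg$window_s)
    tot <- sum(k)
    if (tot == 0L) { spikes[[u]] <- numeric(0); next }
    offs <- rep(win_start, k)
    s <- sort(offs + stats::runif(tot, 0, cfg$window_s))
    spikes[[u]] <- unique(pmin(s, duration - 1e-9))
  }
  list(raster = spike_raster(spikes, duration), labels = labels,
       window_s = cfg$window_s)
}
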