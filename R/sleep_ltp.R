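#' Sleep-LTP variants
#'
#' The five variants of the long-term potentiation bonus applied to the
#' binary network around a SWS/REM transition:
#' `ltp1_full_sws`, `ltp1_30s_sws_end` and `ltp1_60s_transition` gate the
#' bonus by pairwise spike synchrony over, respectively, the entire SWS
#' episode preceding the selected REM, the last 30 s of that SWS, or those
#' 30 s plus the first 30 s of REM; `ltp2_permissive` and `ltp2_restrictive`
#' gate it by the angle of each synapse's weight trajectory at the
#' transition.
#' @name ltp_variants
#' @keywords internal
NULL

LTP_VARIANTS <- c("ltp1_full_sws", "ltp1_30s_sws_end", "ltp1_60s_transition",
                  "ltp2_permissive", "ltp2_restrictive")

#' LTP schedule
#'
#' The long-term bonus added to the weight update from the trigger time
#' `t_T` onwards is `Cieg_ij * g(t)` with a Gaussian
#' `g(t) = a * exp(-(t - (t_T + mu))^2 / (2 sigma^2))`. With `scaled = TRUE`
#' (default) `a = dt / (sigma * sqrt(2*pi))` so the time-integrated bonus of
#' a synapse equals its `Cieg_ij`; with `scaled = FALSE` the raw per-step
#' density `a = 1 / (sigma * sqrt(2*pi))` is used.
#'
#' @param variant one of the five variant names (see [ltp_variants]).
#' @param cieg per-synapse gain matrix in `[0, 1]`, zero diagonal.
#' @param t_T trigger time (s): selected REM onset + 30 s.
#' @param mu peak delay (1800 s = 30 min).
#' @param sigma Gaussian width in seconds (default 600 s, so +/- 3 sigma
#'   spans the ~3600 s application window).
#' @param scaled logical; see above.
#' @return object of class `ltp_schedule`.
#' @export
ltp_schedule <- function(variant, cieg, t_T, mu = 1800, sigma = 600,
                         scaled = TRUE) {
  variant <- match.arg(variant, LTP_VARIANTS)
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (any(cieg < 0 | cieg > 1)) stop("`cieg` must lie in [0, 1]",
                                     call. = FALSE)
  if (any(diag(cieg) != 0)) stop("`cieg` must have a zero diagonal",
                                 call. = FALSE)
  structure(list(variant = variant, cieg = cieg, t_T = t_T, mu = mu,
                 sigma = sigma, scaled = scaled),
            class = "ltp_schedule")
}

#' Select the triggering REM episode and transition windows
#'
#' The LTP Gaussian is triggered 30 s after the onset of the selected REM
#' episode. The transition windows are the last 30 s of the preceding SWS
#' episode and the first 30 s of REM, abutting at the SWS/REM boundary. A
#' SWS episode shorter than 30 s truncates the pre-window with a warning; a
#' REM episode shorter than 30 s is an error (the post-window cannot be
#' evaluated before the trigger).
#'
#' @param hyp a [hypnogram()].
#' @param rem_index index of the REM episode to use (the 4th in the
#'   full-length sleep studies).
#' @return list with `t_T`, `rem_onset`, `sws_start`, `sws_end`,
#'   `pre_window` and `post_window` (each `c(start, end)` in seconds).
#' @export
select_trigger <- function(hyp, rem_index = 4L) {
  stopifnot(inherits(hyp, "hypnogram"))
  rem_rows <- which(hyp$state == "REM")
  if (rem_index < 1 || rem_index > length(rem_rows)) {
    stop(sprintf("hypnogram has only %d REM episode(s), rem_index=%d",
                 length(rem_rows), rem_index), call. = FALSE)
  }
  r <- rem_rows[rem_index]
  rem_onset <- hyp$start_s[r]
  rem_len <- hyp$end_s[r] - rem_onset
  if (rem_len < 30) {
    stop("selected REM episode shorter than 30 s: cannot evaluate the post-window",
         call. = FALSE)
  }
  sws_start <- hyp$start_s[r - 1L]
  sws_end <- hyp$end_s[r - 1L]
  pre_lo <- rem_onset - 30
  if (pre_lo < sws_start) {
    warning("preceding SWS episode shorter than 30 s: pre-window truncated")
    pre_lo <- sws_start
  }
  list(t_T = rem_onset + 30, rem_onset = rem_onset,
       sws_start = sws_start, sws_end = sws_end,
       pre_window = c(pre_lo, rem_onset),
       post_window = c(rem_onset, rem_onset + 30))
}

#' Synchrony-based LTP gain (LTP1)
#'
#' `Cieg_ij` is the ratio of presynaptic spikes that occurred synchronously
#' with postsynaptic spikes: the number of 4 ms bins in the epoch where both
#' neuron i (post) and neuron j (pre) fire, divided by the number of bins
#' where j fires. Synapses whose presynaptic unit is silent in the epoch get
#' 0 (no evidence of synchrony).
#'
#' @param spikes network [spike_raster()] (times relative to the raster).
#' @param epoch `c(start, end)` in the raster's time base.
#' @param bin_width_s synchrony bin (0.004 s).
#' @return N x N gain matrix in `[0, 1]`, zero diagonal.
#' @export
cieg_ltp1 <- function(spikes, epoch, bin_width_s = 0.004) {
  stopifnot(inherits(spikes, "spike_raster"))
  if (epoch[2] <= epoch[1]) stop("empty epoch", call. = FALSE)
  if (epoch[1] < -1e-9 || epoch[1] >= spikes$duration_s) {
    stop("epoch outside raster duration", call. = FALSE)
  }
  # a trailing fraction of a bin may be lost to step discretization
  epoch[2] <- min(epoch[2], spikes$duration_s)
  n <- spikes$n_units
  n_bins <- max(1L, as.integer(ceiling((epoch[2] - epoch[1]) / bin_width_s - 1e-9)))
  m <- matrix(0L, n, n_bins)
  for (i in seq_len(n)) {
    s <- spikes$spikes[[i]]
    s <- s[s >= epoch[1] & s < epoch[2]]
    if (length(s)) {
      b <- pmin(n_bins, floor((s - epoch[1]) / bin_width_s) + 1L)
      m[i, unique(b)] <- 1L
    }
  }
  shared <- m %*% t(m)              # shared[i, j] = co-firing bins of i and j
  pre_count <- rowSums(m)           # bins where j fires
  cieg <- sweep(shared, 2L, pmax(pre_count, 1L), "/")
  cieg[, pre_count == 0L] <- 0
  diag(cieg) <- 0
  cieg
}

#' Per-synapse OLS slope over a snapshot window
#'
#' Ordinary least-squares slope of `w_ij(t)` against snapshot time over all
#' snapshots falling in the window, for every synapse at once.
#'
#' @param traj a `weight_trajectory`.
#' @param window `c(start, end)` in the trajectory's (absolute) time base.
#' @return N x N slope matrix in weight units per second.
#' @export
fit_window_slope <- function(traj, window) {
  stopifnot(inherits(traj, "weight_trajectory"))
  idx <- which(traj$times >= window[1] - 1e-9 & traj$times <= window[2] + 1e-9)
  if (length(idx) < 3L) {
    stop(sprintf("need >= 3 snapshots in window, found %d", length(idx)),
         call. = FALSE)
  }
  tc <- traj$times[idx] - mean(traj$times[idx])
  slopes <- as.vector(traj$W[, idx, drop = FALSE] %*% tc) / sum(tc * tc)
  matrix(slopes, traj$N, traj$N)
}

#' Trajectory angle at the SWS/REM transition
#'
#' The angle formed by the two fitted line segments of `w_ij(t)` before and
#' after the transition: `beta = pi - (atan(m_rem) - atan(m_sws))`. Equal
#' slopes give a straight angle (pi); `beta < pi` iff the REM slope exceeds
#' the SWS slope, and any positive REM slope gives `beta < 3*pi/2`, which
#' reproduces the permissive/restrictive case structure.
#'
#' @param m_sws,m_rem slope values or matrices (pre- and post-transition).
#' @return angle(s) in radians.
#' @export
beta_angle <- function(m_sws, m_rem) {
  pi - (atan(m_rem) - atan(m_sws))
}

#' Trajectory-based LTP gain (LTP2)
#'
#' Synapses with a non-positive REM slope get 0. Otherwise the gain falls
#' linearly with the transition angle, `Cieg = max(0, 1 - beta / beta_max)`,
#' with `beta_max = 3*pi/2` for the permissive variant and `pi` for the
#' restrictive one (so the restrictive gain is never above the permissive
#' gain for the same slopes).
#'
#' Weight-trajectory slopes are of order 1e-3 per second, so raw arctangents
#' would collapse all angles onto pi. The slopes are therefore
#' non-dimensionalized before the angle is computed: by default both slope
#' matrices are divided by the pooled standard deviation of all off-diagonal
#' slopes, making typical trajectory angles order-1; pass `slope_scale` to
#' fix the factor.
#'
#' @param m_sws,m_rem N x N slope matrices from [fit_window_slope()] on the
#'   transition windows.
#' @param variant `"ltp2_permissive"` or `"ltp2_restrictive"`.
#' @param slope_scale optional multiplicative normalization applied to both
#'   slope matrices before the angle; `NULL` (default) uses
#'   1 / pooled off-diagonal SD.
#' @return N x N gain matrix in `[0, 1]`, zero diagonal.
#' @export
cieg_ltp2 <- function(m_sws, m_rem,
                      variant = c("ltp2_permissive", "ltp2_restrictive"),
                      slope_scale = NULL) {
  variant <- match.arg(variant)
  stopifnot(all(dim(m_sws) == dim(m_rem)))
  N <- nrow(m_sws)
  if (is.null(slope_scale)) {
    off <- .offdiag_mask(N)
    s <- stats::sd(c(m_sws[off], m_rem[off]))
    slope_scale <- if (is.finite(s) && s > 0) 1 / s else 1
  }
  beta <- beta_angle(m_sws * slope_scale, m_rem * slope_scale)
  beta_max <- if (variant == "ltp2_permissive") 3 * pi / 2 else pi
  cieg <- matrix(pmax(0, 1 - beta / beta_max), N, ncol(m_sws))
  cieg[m_rem <= 0] <- 0
  diag(cieg) <- 0
  cieg
}

#' Gaussian LTP increment at a time point
#'
#' The per-step additive weight increment of the schedule at absolute time
#' `t`: zero before the trigger, otherwise
#' `Cieg_ij * a * exp(-(t - (t_T + mu))^2 / (2 sigma^2))` with `a` as in
#' [ltp_schedule()]. Summed over a full schedule with `Cieg = 1` and
#' `scaled = TRUE` the increments integrate to ~1.
#'
#' @param t absolute time in seconds.
#' @param sched an [ltp_schedule()].
#' @param dt simulation step (s), used by the scaled normalization.
#' @return N x N increment matrix.
#' @export
gaussian_bonus <- function(t, sched, dt = 0.004) {
  stopifnot(inherits(sched, "ltp_schedule"))
  if (t < sched$t_T) return(sched$cieg * 0)
  a <- (if (sched$scaled) dt else 1) / (sched$sigma * sqrt(2 * pi))
  z <- (t - (sched$t_T + sched$mu)) / sched$sigma
  sched$cieg * a * exp(-0.5 * z * z)
}

#' Build the LTP schedule for one variant from a completed pre-trigger run
#'
#' Computes the per-synapse gain matrix from the pre-trigger simulation:
#' spike synchrony over the variant's epoch for the LTP1 family, or the
#' transition-window slopes for the LTP2 family.
#'
#' @param variant one of the five variant names.
#' @param trigger result of [select_trigger()].
#' @param traj pre-trigger `weight_trajectory` covering the transition
#'   windows at a snapshot stride of at most ~10 s.
#' @param mu,sigma,scaled forwarded to [ltp_schedule()].
#' @return an [ltp_schedule()].
#' @export
build_ltp_schedule <- function(variant, trigger, traj,
                               mu = 1800, sigma = 600, scaled = TRUE) {
  variant <- match.arg(variant, LTP_VARIANTS)
  cieg <- switch(
    variant,
    ltp1_full_sws = cieg_ltp1(traj$spikes,
                              c(trigger$sws_start, trigger$sws_end) - traj$t0),
    ltp1_30s_sws_end = cieg_ltp1(traj$spikes, trigger$pre_window - traj$t0),
    ltp1_60s_transition = cieg_ltp1(
      traj$spikes, c(trigger$pre_window[1], trigger$post_window[2]) - traj$t0),
    ltp2_permissive = ,
    ltp2_restrictive = {
      m_sws <- fit_window_slope(traj, trigger$pre_window)
      m_rem <- fit_window_slope(traj, trigger$post_window)
      cieg_ltp2(m_sws, m_rem, variant)
    })
  ltp_schedule(variant, cieg, t_T = trigger$t_T, mu = mu, sigma = sigma,
               scaled = scaled)
}
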