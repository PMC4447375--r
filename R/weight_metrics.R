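#' Net synaptic weight change
#'
#' Mean of the element-by-element differences between two weight matrices
#' over the `N(N-1)` off-diagonal connections. Negative values indicate
#' global downscaling, positive values global upscaling.
#'
#' @param w1,w2 N x N weight matrices (zero diagonal), earlier and later.
#' @return scalar `M_dw`.
#' @export
net_weight_change <- function(w1, w2) {
  if (!all(dim(w1) == dim(w2))) stop("size mismatch", call. = FALSE)
  N <- nrow(w1)
  off <- .offdiag_mask(N)
  mean(w2[off] - w1[off])
}

#' Similarity index between weight patterns
#'
#' Normalized inverse of the summed absolute differences to a reference
#' pattern: `SI = 1 - sum(|w - ref|) / (N(N-1))` over off-diagonal entries,
#' so the reference itself scores 1 and a pattern differing by 1 everywhere
#' scores 0. The raw sum is attached as attribute `"raw_sum"`.
#'
#' @param w,ref N x N weight matrices.
#' @return scalar in `[0, 1]` (for weights within `[0, 1]`).
#' @export
similarity_index <- function(w, ref) {
  if (!all(dim(w) == dim(ref))) stop("size mismatch", call. = FALSE)
  off <- .offdiag_mask(nrow(w))
  raw <- sum(abs(w[off] - ref[off]))
  structure(1 - raw / sum(off), raw_sum = raw)
}

#' Spearman rank correlation between weight patterns
#'
#' Rank correlation of the vectorized off-diagonal entries against a
#' reference pattern; ties get average ranks. Quantifies restructuring: a
#' drop means the ranking of synaptic strengths has been reordered even if
#' the overall scale is preserved.
#'
#' @param w,ref N x N weight matrices.
#' @return scalar in `[-1, 1]`; `NA` with a warning if either pattern has
#'   zero rank variance.
#' @export
spearman_weights <- function(w, ref) {
  if (!all(dim(w) == dim(ref))) stop("size mismatch", call. = FALSE)
  off <- .offdiag_mask(nrow(w))
  a <- w[off]; b <- ref[off]
  if (length(a) < 2L) stop("need >= 2 off-diagonal entries", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant weight pattern: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b, method = "spearman")
}

#' Metric time series along a trajectory
#'
#' Evaluates similarity and Spearman correlation of every snapshot against a
#' reference snapshot, plus the running net weight change.
#'
#' @param traj a `weight_trajectory`.
#' @param ref_time time (s) of the reference snapshot (nearest snapshot is
#'   used; default: the first).
#' @return data.frame with columns `time_s`, `similarity`, `spearman`,
#'   `m_dw`, `mean_w`.
#' @export
trajectory_metrics <- function(traj, ref_time = traj$times[1L]) {
  stopifnot(inherits(traj, "weight_trajectory"))
  k_ref <- which.min(abs(traj$times - ref_time))
  ref <- traj_snapshot(traj, k_ref)
  off <- .offdiag_mask(traj$N)
  out <- data.frame(time_s = traj$times, similarity = NA_real_,
                    spearman = NA_real_, m_dw = NA_real_, mean_w = NA_real_)
  for (k in seq_along(traj$times)) {
    wk <- traj_snapshot(traj, k)
    out$similarity[k] <- as.numeric(similarity_index(wk, ref))
    out$spearman[k] <- suppressWarnings(spearman_weights(wk, ref))
    out$m_dw[k] <- net_weight_change(ref, wk)
    out$mean_w[k] <- mean(wk[off])
  }
  out
}

#' Steady-state convergence time of a trajectory
#'
#' The first snapshot time at which the OLS slope of every synapse over the
#' trailing window satisfies `|dw/dt| <= eps`.
#'
#' @param traj a `weight_trajectory`.
#' @param eps slope threshold (0.00025 per second).
#' @param window_s trailing window length in seconds (default 500 s; the
#'   criterion itself fixes only `eps`, the estimation window is a package
#'   convention chosen so single plasticity events do not dominate the
#'   slope estimate).
#' @return convergence time in seconds, or `NA` if never reached.
#' @export
convergence_time <- function(traj, eps = 0.00025, window_s = 500) {
  stopifnot(inherits(traj, "weight_trajectory"))
  tt <- traj$times
  if (window_s > tt[length(tt)] - tt[1L]) {
    stop("window longer than trajectory", call. = FALSE)
  }
  for (k in seq_along(tt)) {
    idx <- which(tt > tt[k] - window_s - 1e-9 & tt <= tt[k] + 1e-9)
    if (length(idx) < 3L || tt[k] - tt[1L] < window_s - 1e-9) next
    tc <- tt[idx] - mean(tt[idx])
    slopes <- as.vector(traj$W[, idx, drop = FALSE] %*% tc) / sum(tc * tc)
    if (all(abs(slopes) <= eps)) return(tt[k])
  }
  NA_real_
}

#' Moments and histogram of off-diagonal weights
#'
#' @param w N x N weight matrix.
#' @param breaks histogram breaks (default 30 equal bins over the data
#'   range).
#' @return list with `mean`, `sd`, and `histogram` (data.frame `mid`,
#'   `prob`; probabilities sum to 1).
#' @export
distribution_stats <- function(w, breaks = 30) {
  off <- .offdiag_mask(nrow(w))
  x <- w[off]
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(mean = mean(x), sd = stats::sd(x),
       histogram = data.frame(mid = h$mids, prob = h$counts / length(x)))
}
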