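#' Rate sweep of the binary network
#'
#' One convergence run per (rate, seed) with independent Poisson input,
#' reporting the mean and SD of the converged off-diagonal weights, the
#' convergence time and the net weight change from the uniform
#' initialization.
#'
#' @param rates input rates in Hz.
#' @param n_seeds independent repetitions per rate.
#' @param cfg a [model1_config()].
#' @param base_seed seeds used are `base_seed + (1:n_seeds)` per rate.
#' @param ... forwarded to [run_model1_to_convergence()] (e.g.
#'   `max_duration`).
#' @return data.frame with one row per run: `rate`, `seed`, `mean_w`,
#'   `sd_w`, `conv_time`, `converged`, `m_dw`.
#' @export
sweep_rates <- function(rates, n_seeds = 5L, cfg = model1_config(N = 50L),
                        base_seed = 0L, ...) {
  if (any(rates <= 0)) stop("rates must be positive", call. = FALSE)
  rows <- list()
  off <- .offdiag_mask(cfg$N)
  for (r in rates) {
    for (s in seq_len(n_seeds)) {
      res <- run_model1_to_convergence(cfg, rate = r,
                                       seed = base_seed + s, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        rate = r, seed = base_seed + s,
        mean_w = res$mean_w, sd_w = stats::sd(res$w_final[off]),
        conv_time = res$time, converged = res$converged,
        m_dw = net_weight_change(res$w_init, res$w_final))
    }
  }
  do.call(rbind, rows)
}

#' Compare the five LTP variants on a common hypnogram run
#'
#' Per seed: one pre-trigger simulation on the state raster (identical
#' initial weights, inputs and spike history for every arm), then one
#' post-trigger continuation per arm — the five LTP variants plus a no-LTP
#' baseline — all continuing from the same state with the same
#' post-trigger random stream, so arms differ only through the LTP bonus.
#' End-of-window Spearman correlation, similarity and net weight change are
#' measured against the reference snapshot.
#'
#' @param hyp a [hypnogram()] containing at least `rem_index` REM episodes.
#' @param n number of neurons (external units match).
#' @param variants variant names (default all five).
#' @param n_seeds independent repetitions.
#' @param cfg optional [model1_config()] (default `model1_config(N = n)`).
#' @param stats_by_state per-state input statistics ([state_stats()]).
#' @param rem_index REM episode that triggers the LTP Gaussian.
#' @param mu,sigma LTP Gaussian peak delay and width (s). The reference
#'   analyses use 1800/600 s; scaled studies may shrink both.
#' @param t_end end of the post-trigger window (default `t_T + mu +
#'   3*sigma`).
#' @param ref_time time of the reference snapshot for the restructuring
#'   metrics (default 0).
#' @param base_seed first seed.
#' @return data.frame with one row per (seed, arm): `variant`, `seed`,
#'   `spearman_end`, `similarity_end`, `m_dw`, `n_recruited` (synapses with
#'   a positive LTP gain; NA for the baseline).
#' @export
compare_ltp_variants <- function(hyp, n, variants = LTP_VARIANTS,
                                 n_seeds = 10L, cfg = NULL,
                                 stats_by_state = state_stats(),
                                 rem_index = 2L, mu = 1800, sigma = 600,
                                 t_end = NULL, ref_time = 0,
                                 base_seed = 0L) {
  stopifnot(inherits(hyp, "hypnogram"))
  if (is.null(cfg)) cfg <- model1_config(N = n)
  trigger <- select_trigger(hyp, rem_index)
  if (is.null(t_end)) t_end <- trigger$t_T + mu + 3 * sigma
  rows <- list()
  for (s in seq_len(n_seeds)) {
    set.seed(base_seed + s)
    raster <- gen_state_raster(hyp, stats_by_state, n)
    w0 <- init_weights(cfg)
    # pre-trigger phase, shared bit-for-bit by every arm
    pre_raster <- .crop_raster(raster, 0, trigger$t_T)
    traj1 <- simulate_model1(cfg, pre_raster, duration = trigger$t_T,
                             snapshot_stride = max(1L, round(1 / cfg$dt)),
                             w_init = w0, t0 = 0)
    ref <- if (ref_time <= 0) w0 else
      traj_snapshot(traj1, which.min(abs(traj1$times - ref_time)))
    post_raster <- .crop_raster(raster, trigger$t_T, t_end)
    phase2_seed <- base_seed + 10000L + s
    run_arm <- function(sched) {
      traj2 <- simulate_model1(cfg, post_raster,
                               duration = t_end - trigger$t_T,
                               ltp = sched,
                               snapshot_stride = max(1L, round(1 / cfg$dt)),
                               w_init = traj1$w_final,
                               v_init = traj1$v_final,
                               t0 = trigger$t_T, record_spikes = FALSE,
                               seed = phase2_seed)
      traj2$w_final
    }
    w_base <- run_arm(NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      variant = "no_ltp", seed = base_seed + s,
      spearman_end = spearman_weights(w_base, ref),
      similarity_end = as.numeric(similarity_index(w_base, ref)),
      m_dw = net_weight_change(ref, w_base), n_recruited = NA_integer_)
    for (v in variants) {
      sched <- build_ltp_schedule(v, trigger, traj1, mu = mu, sigma = sigma)
      w_end <- run_arm(sched)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, seed = base_seed + s,
        spearman_end = spearman_weights(w_end, ref),
        similarity_end = as.numeric(similarity_index(w_end, ref)),
        m_dw = net_weight_change(ref, w_end),
        n_recruited = sum(sched$cieg > 0))
    }
  }
  do.call(rbind, rows)
}

# Restrict a raster to [t0, t1), re-based to time 0.
.crop_raster <- function(raster, t0, t1) {
  t1 <- min(t1, raster$duration_s)
  spikes <- lapply(raster$spikes, function(s) s[s >= t0 & s < t1] - t0)
  spike_raster(spikes, duration_s = t1 - t0,
               bin_width_s = raster$bin_width_s)
}

#' Sweep the sleep-modulation grid of the LIF network
#'
#' One batch of runs per (gamma, kappa) cell with fresh seeds, collecting
#' the switch and hit proportions and their surrogate tests. A cell's hit
#' (switch) mask is significant when the majority of its runs reject the
#' surrogate null at p < 0.05.
#'
#' @param gammas,kappas grid values of the STDP modulation factor and LTP
#'   gain.
#' @param n_runs runs per cell (>= 1).
#' @param base_seed seeds are `base_seed + run index`, distinct per cell.
#' @param ... forwarded to [run_model2()] (e.g. `duration`, `schedule`).
#' @return list with `runs` (one row per run: `gamma`, `kappa`, `run`,
#'   `T_S`, `T_H`, `p_S`, `p_H`) and `cells` (per-cell means and
#'   significance masks).
#' @export
sweep_sleep_grid <- function(gammas, kappas, n_runs = 20L, base_seed = 0L,
                             ...) {
  if (n_runs < 1L) stop("`n_runs` must be >= 1", call. = FALSE)
  rows <- list()
  cell_id <- 0L
  for (g in gammas) {
    for (k in kappas) {
      cell_id <- cell_id + 1L
      for (r in seq_len(n_runs)) {
        run <- run_model2(gamma_sleep = g, kappa_sleep = k,
                          seed = base_seed + cell_id * 1000L + r, ...)
        rows[[length(rows) + 1L]] <- data.frame(
          gamma = g, kappa = k, run = r, T_S = run$T_S, T_H = run$T_H,
          p_S = run$surrogate_S$p_value, p_H = run$surrogate_H$p_value)
      }
    }
  }
  runs <- do.call(rbind, rows)
  cells <- do.call(rbind, lapply(split(runs, list(runs$gamma, runs$kappa),
                                       drop = TRUE), function(d) {
    data.frame(gamma = d$gamma[1L], kappa = d$kappa[1L],
               mean_T_S = mean(d$T_S), mean_T_H = mean(d$T_H),
               sig_S = mean(d$p_S < 0.05, na.rm = TRUE) > 0.5,
               sig_H = mean(d$p_H < 0.05, na.rm = TRUE) > 0.5)
  }))
  rownames(cells) <- NULL
  list(runs = runs, cells = cells[order(cells$gamma, cells$kappa), ])
}

#' Summarize a completed experiment directory
#'
#' Reads the CSV tables written by the analysis drivers and produces a
#' machine-readable summary (written as `summary.json` when the jsonlite
#' package is available) plus a human-readable digest. Re-running the
#' report is idempotent.
#'
#' @param run_dir directory containing one or more of `rate_sweep.csv`,
#'   `ltp_variants.csv`, `sleep_grid_runs.csv`.
#' @return named list of per-table summaries, invisibly; errors listing the
#'   missing files if none are present.
#' @export
report <- function(run_dir) {
  if (!dir.exists(run_dir)) stop("no such directory: ", run_dir,
                                 call. = FALSE)
  known <- c("rate_sweep.csv", "ltp_variants.csv", "sleep_grid_runs.csv")
  present <- known[file.exists(file.path(run_dir, known))]
  if (!length(present)) {
    stop("no experiment tables found; expected one of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  out <- list()
  if ("rate_sweep.csv" %in% present) {
    d <- utils::read.csv(file.path(run_dir, "rate_sweep.csv"))
    out$rate_sweep <- do.call(rbind, lapply(split(d, d$rate), function(g) {
      data.frame(rate = g$rate[1L], mean_w = mean(g$mean_w),
                 mean_conv_time = mean(g$conv_time, na.rm = TRUE),
                 mean_m_dw = mean(g$m_dw))
    }))
  }
  if ("ltp_variants.csv" %in% present) {
    d <- utils::read.csv(file.path(run_dir, "ltp_variants.csv"))
    out$ltp_variants <- do.call(rbind, lapply(split(d, d$variant),
                                              function(g) {
      data.frame(variant = g$variant[1L],
                 mean_spearman = mean(g$spearman_end),
                 mean_similarity = mean(g$similarity_end),
                 mean_m_dw = mean(g$m_dw))
    }))
  }
  if ("sleep_grid_runs.csv" %in% present) {
    d <- utils::read.csv(file.path(run_dir, "sleep_grid_runs.csv"))
    out$sleep_grid <- do.call(rbind,
                              lapply(split(d, list(d$gamma, d$kappa),
                                           drop = TRUE), function(g) {
      data.frame(gamma = g$gamma[1L], kappa = g$kappa[1L],
                 mean_T_S = mean(g$T_S), mean_T_H = mean(g$T_H))
    }))
  }
  for (nm in names(out)) rownames(out[[nm]]) <- NULL
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(out, file.path(run_dir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  for (nm in names(out)) {
    cat("==", nm, "==\n")
    print(out[[nm]])
  }
  invisible(out)
}
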