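# Shared fixtures and reference implementations used across test files.

# A short hypnogram with round episode bounds, handy for trigger selection.
toy_hypnogram <- function() {
  hypnogram(state  = c("WK", "SWS", "REM", "WK", "SWS", "REM"),
            start_s = c(0, 100, 250, 320, 420, 570),
            end_s   = c(100, 250, 320, 420, 570, 640))
}

# A compact hypnogram for scaled sleep simulations (short WK bouts so runs
# stay cheap); rem episode 2 is the LTP trigger in the variant studies.
scaled_hypnogram <- function(n_cycles = 3, seed = NULL) {
  gen_hypnogram(n_cycles,
                hypnogram_params(wk_meanlog = log(60),  wk_sdlog = 0.3,
                                 sws_meanlog = log(90), sws_sdlog = 0.3,
                                 rem_meanlog = log(60), rem_sdlog = 0.2),
                seed = seed)
}

# Scaled sleep schedule for the LIF network property studies: 30 s wake for
# pattern formation, 60 s sleep with the LTP Gaussian peaking mid-sleep, and
# a 5 s tail so the final snapshot reflects what sleep did.
scaled_schedule <- function() {
  sleep_schedule(t_sleep = 30, t_wake = 90, t_ltp_peak = 50, t_ltp_std = 10)
}

# Naive reference simulator for the binary network: per-pair double loop for
# the plasticity rule, same RNG draw order as the compiled core (one
# runif(N) block per step, states from a strict '<' comparison).
reference_model1 <- function(cfg, external, n_steps, w0, v0 = integer(cfg$N)) {
  N <- cfg$N
  e_mat <- bin_raster(external, cfg$dt)
  w <- w0
  v <- as.integer(v0)
  spikes <- list()
  for (s in seq_len(n_steps)) {
    e <- if (s <= ncol(e_mat)) e_mat[, s] else integer(N)
    I <- cfg$w_ie * e + as.vector(w %*% v) / (N - 1)
    p <- 1 / (1 + exp(cfg$K_t - cfg$K_s * I))
    v_new <- as.integer(stats::runif(N) < p)
    for (j in seq_len(N)) {
      if (v_new[j] == 1L) {
        for (i in seq_len(N)) {
          if (i == j) next
          wij <- w[i, j]
          if (v_new[i] == 1L) {
            wij <- wij + cfg$C_p * (exp(-wij) - exp(-1)) * cfg$dt +
              cfg$C_d * (1 - cfg$theta) * cfg$dt
          } else {
            wij <- wij + cfg$C_d * (0 - cfg$theta) * cfg$dt
          }
          w[i, j] <- min(max(wij, cfg$w_min), cfg$w_max)
        }
      }
    }
    v <- v_new
  }
  list(w = w, v = v)
}

offdiag <- function(m) m[row(m) != col(m)]
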