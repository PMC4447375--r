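test_that("Poisson raster generator matches Poisson count statistics", {
  # zero-intensity process
  r0 <- gen_poisson_raster(5, 0, 10, seed = 1)
  expect_equal(sum(lengths(r0$spikes)), 0)

  # mean rate within 3 standard errors of the target
  r <- gen_poisson_raster(150, 5, 1000, seed = 2)
  se_pooled <- sqrt(5 / (1000 * 150))
  expect_lt(abs(mean(raster_rates(r)) - 5), 3 * se_pooled)

  # spike-count Fano factor over 1 s windows is ~1
  r <- gen_poisson_raster(150, 10, 500, seed = 3)
  counts <- unlist(lapply(r$spikes, function(s) tabulate(floor(s) + 1L, 500)))
  fano <- stats::var(counts) / mean(counts)
  expect_lt(abs(fano - 1), 0.1)

  expect_error(gen_poisson_raster(10, -1, 10), "rate")
  expect_error(gen_poisson_raster(10, 5, -10), "duration")
})

test_that("raster generators are bit-reproducible under a seed", {
  a <- gen_poisson_raster(20, 8, 50, seed = 42)
  b <- gen_poisson_raster(20, 8, 50, seed = 42)
  expect_identical(a, b)
  a <- gen_correlated_raster(10, 8, 0.04, 50, seed = 42)
  b <- gen_correlated_raster(10, 8, 0.04, 50, seed = 42)
  expect_identical(a, b)
  a <- gen_hypnogram(20, seed = 42)
  b <- gen_hypnogram(20, seed = 42)
  expect_identical(a, b)
})

test_that("correlated raster hits its correlation target and preserves rate", {
  # degenerate case: zero target behaves like independent Poisson
  r0 <- gen_correlated_raster(20, 10, 0, 500, seed = 4)
  expect_lt(abs(raster_pairwise_corr(r0)), 0.01)

  # calibration: achieved correlation within the specified band
  r <- gen_correlated_raster(40, 10, 0.05, 600, seed = 5)
  rho <- raster_pairwise_corr(r)
  expect_gt(rho, 0.03)
  expect_lt(rho, 0.07)
  # within the +/- 0.02 calibration tolerance
  expect_lt(abs(rho - 0.05), 0.02)

  # rate preserved within 3 SE regardless of the correlation target
  se_pooled <- sqrt(10 / (600 * 40))
  expect_lt(abs(mean(raster_rates(r)) - 10), 3 * se_pooled)

  expect_error(gen_correlated_raster(10, 5, 1, 10), "corr_target")
})

test_that("hypnogram generator obeys structure and sleep-architecture stats", {
  hyp <- gen_hypnogram(1000, seed = 11)
  # structural invariants are enforced by the constructor; spot-check anyway
  expect_true(all(hyp$state[which(hyp$state == "REM") - 1L] == "SWS"))
  expect_true(all(hyp$state[-1L] != hyp$state[-nrow(hyp)]))
  expect_true(all(abs(hyp$start_s[-1L] - hyp$end_s[-nrow(hyp)]) < 1e-9))

  # ~91.6% of REM-onset-to-REM-onset intervals shorter than 30 min
  expect_lt(abs(rem_interval_fraction(hyp) - 0.916), 0.02)

  # mean SWS episode duration near 87 s
  sws <- hyp[hyp$state == "SWS", ]
  expect_gt(mean(sws$end_s - sws$start_s), 70)
  expect_lt(mean(sws$end_s - sws$start_s), 105)

  expect_error(gen_hypnogram(0), "n_cycles")
  expect_error(hypnogram_params(sws_sdlog = -1), "sdlog")
})

test_that("state raster reproduces per-state rates and synchrony orderings", {
  hyp <- hypnogram(state = c("WK", "SWS", "REM"),
                   start_s = c(0, 200, 500), end_s = c(200, 500, 800))
  # homogeneous units: per-state mean rate within 3 SE of configured value
  r <- gen_state_raster(hyp, n = 40, rate_cv = 0, seed = 12)
  st <- state_stats()
  for (s in c("WK", "SWS", "REM")) {
    rows <- hyp[hyp$state == s, ]
    len <- sum(rows$end_s - rows$start_s)
    cnt <- sum(vapply(r$spikes, function(x) {
      sum(x >= rows$start_s[1] & x < rows$end_s[1])
    }, numeric(1)))
    target <- st[[s]]$mean_rate_hz
    se <- sqrt(target / (len * 40))
    expect_lt(abs(cnt / (40 * len) - target), 3 * se)
  }

  # synchrony ordering REM < SWS < WK under defaults
  crop <- function(lo, hi) {
    spike_raster(lapply(r$spikes, function(x) x[x >= lo & x < hi] - lo),
                 hi - lo)
  }
  rho <- c(WK = raster_pairwise_corr(crop(0, 200)),
           SWS = raster_pairwise_corr(crop(200, 500)),
           REM = raster_pairwise_corr(crop(500, 800)))
  expect_lt(rho["REM"], rho["SWS"])
  expect_lt(rho["SWS"], rho["WK"])

  expect_error(gen_state_raster(hyp, list(WK = state_stats()$WK), n = 5),
               "missing state")
})

test_that("two-memory input follows the window protocol", {
  cfg <- two_memory_config(t_sleep = 10, t_wake = 20)
  out <- gen_two_memory_input(cfg, 30, seed = 13)
  expect_equal(length(out$labels), 240)               # 30 s / 125 ms
  expect_true(all(out$labels %in% c("A", "B")))

  # expected spikes per active unit per window = 20 * 0.125 = 2.5 (awake)
  win_of <- function(t) floor(t / 0.125) + 1L
  awake <- which((seq_len(240) - 1L) * 0.125 < 10)
  n_active_a <- sum(out$labels[awake] == "A")
  cnt_a <- sum(vapply(out$raster$spikes[cfg$memory_a], function(s) {
    sum(win_of(s) %in% awake[out$labels[awake] == "A"])
  }, numeric(1)))
  mean_per_window <- cnt_a / (n_active_a * 100)
  expect_lt(abs(mean_per_window - 2.5), 3 * sqrt(2.5 / (n_active_a * 100)))

  # windows inside the sleep interval have halved rates
  asleep <- which((seq_len(240) - 1L) * 0.125 >= 10 &
                    (seq_len(240) - 1L) * 0.125 < 20)
  cnt_sleep <- sum(vapply(out$raster$spikes, function(s) {
    sum(win_of(s) %in% asleep)
  }, numeric(1)))
  cnt_wake1 <- sum(vapply(out$raster$spikes, function(s) {
    sum(win_of(s) %in% awake)
  }, numeric(1)))
  expect_lt(abs(cnt_sleep / cnt_wake1 - 0.5), 0.08)

  expect_error(two_memory_config(memory_a = 1:100, memory_b = 100:200),
               "overlap")
})

test_that("raster and hypnogram CSV round-trip and reject malformed input", {
  r <- gen_poisson_raster(3, 6, 20, seed = 14)
  f <- withr::local_tempfile(fileext = ".csv")
  write_raster(r, f)
  r2 <- read_raster(f)
  expect_equal(r2$n_units, 3)
  expect_equal(r2$duration_s, 20)
  for (i in 1:3) expect_equal(r2$spikes[[i]], r$spikes[[i]], tolerance = 1e-9)

  hyp <- toy_hypnogram()
  g <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram(hyp, g)
  expect_equal(read_hypnogram(g), hyp)

  # unknown state label names the line
  writeLines(c("state,start_s,end_s", "WK,0,10", "NREM,10,20"), g)
  expect_error(read_hypnogram(g), "line 3.*NREM")

  # empty raster body is valid given the metadata header
  writeLines(c("# n_units=2 duration_s=5", "unit_id,time_s"), f)
  r3 <- read_raster(f)
  expect_equal(r3$n_units, 2)
  expect_equal(r3$duration_s, 5)
  expect_equal(sum(lengths(r3$spikes)), 0)

  # unsorted spike times name the line
  writeLines(c("# n_units=1 duration_s=5", "unit_id,time_s",
               "1,2.0", "1,1.0"), f)
  expect_error(read_raster(f), "line 4.*increasing")
})
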