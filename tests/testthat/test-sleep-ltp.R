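# Build a weight_trajectory by hand: W has N^2 rows (column-major snapshots).
make_traj <- function(times, snaps, N) {
  structure(list(times = times,
                 W = vapply(snaps, as.vector, numeric(N * N)),
                 N = N, config = NULL, w_final = snaps[[length(snaps)]],
                 v_final = integer(N), spikes = NULL, t0 = times[1L]),
            class = "weight_trajectory")
}

test_that("trigger selection puts t_T 30 s after the chosen REM onset", {
  hyp <- toy_hypnogram()
  tr <- select_trigger(hyp, rem_index = 2L)
  expect_equal(tr$rem_onset, 570)
  expect_equal(tr$t_T, 600)
  expect_equal(tr$pre_window, c(540, 570))
  expect_equal(tr$post_window, c(570, 600))
  expect_equal(c(tr$sws_start, tr$sws_end), c(420, 570))

  # the documented case: REM onset at 10470 s gives a 10500 s trigger
  hyp2 <- hypnogram(c("WK", "SWS", "REM"), c(0, 10000, 10470),
                    c(10000, 10470, 10600))
  expect_equal(select_trigger(hyp2, 1L)$t_T, 10500)

  expect_error(select_trigger(hyp, rem_index = 3L), "only 2 REM")
  # REM shorter than 30 s cannot host the post-window
  hyp3 <- hypnogram(c("WK", "SWS", "REM"), c(0, 50, 120), c(50, 120, 140))
  expect_error(select_trigger(hyp3, 1L), "shorter than 30")
  # SWS shorter than 30 s truncates the pre-window with a warning
  hyp4 <- hypnogram(c("WK", "SWS", "REM"), c(0, 50, 70), c(50, 70, 140))
  expect_warning(tr4 <- select_trigger(hyp4, 1L), "truncated")
  expect_equal(tr4$pre_window, c(50, 70))
})

test_that("synchrony gain is the shared-bin ratio with the 0/0 convention", {
  # pre (unit 2) fires in 10 bins, 4 of them shared with post (unit 1)
  pre_bins <- c(1, 3, 5, 7, 9, 11, 13, 15, 17, 19)
  post_bins <- c(1, 3, 5, 7)                       # 4 shared bins
  mk <- function(bins) (bins - 0.5) * 0.004
  r <- spike_raster(list(mk(post_bins), mk(pre_bins), numeric(0)), 0.1)
  cieg <- cieg_ltp1(r, c(0, 0.1))
  expect_equal(cieg[1, 2], 0.4)
  # silent presynaptic unit: gain 0 for all its targets
  expect_equal(cieg[1, 3], 0)
  expect_equal(cieg[2, 3], 0)
  # identical spike trains: gain 1
  r2 <- spike_raster(list(mk(pre_bins), mk(pre_bins)), 0.1)
  expect_equal(cieg_ltp1(r2, c(0, 0.1))[1, 2], 1)
  expect_equal(diag(cieg), c(0, 0, 0))
  expect_error(cieg_ltp1(r, c(0.05, 0.05)), "empty epoch")
})

test_that("window slopes equal closed-form and lm() least squares", {
  N <- 2
  times <- 0:19
  # column-major 2x2 fill: entry [2,1] is the linear series, [1,2] constant
  snaps <- lapply(times, function(t) {
    matrix(c(0, 0.2 + 0.001 * t, 0.5, 0), N, N)
  })
  traj <- make_traj(times, snaps, N)
  sl <- fit_window_slope(traj, c(0, 19))
  expect_equal(sl[2, 1], 0.001, tolerance = 1e-12)
  expect_equal(sl[1, 2], 0, tolerance = 1e-12)

  # noisy series against the lm() oracle
  set.seed(31)
  y <- 0.3 + 0.002 * times + rnorm(20, 0, 0.01)
  snaps <- lapply(seq_along(times), function(k) {
    matrix(c(0, y[k], 0.5, 0), N, N)
  })
  traj <- make_traj(times, snaps, N)
  sl <- fit_window_slope(traj, c(0, 19))
  expect_equal(sl[2, 1], unname(coef(lm(y ~ times))[2]), tolerance = 1e-10)

  expect_error(fit_window_slope(traj, c(0, 1)), ">= 3 snapshots")
})

test_that("transition angle reproduces the documented case structure", {
  expect_equal(beta_angle(0.5, 0.5), pi)
  expect_equal(beta_angle(-1, 1), pi / 2)
  # any positive REM slope keeps the angle under 3*pi/2
  set.seed(32)
  m_sws <- rnorm(500, 0, 5)
  m_rem <- abs(rnorm(500, 0, 5)) + 1e-9
  expect_true(all(beta_angle(m_sws, m_rem) < 3 * pi / 2))
  # beta < pi exactly when the REM slope exceeds the SWS slope
  expect_true(all((beta_angle(m_sws, m_rem) < pi) == (m_rem > m_sws)))
})

test_that("trajectory-based gain is linear in the angle and properly gated", {
  m_sws <- matrix(c(0, -1, 1, 0), 2, 2)
  m_rem <- matrix(c(0, 1, -0.5, 0), 2, 2)
  perm <- cieg_ltp2(m_sws, m_rem, "ltp2_permissive", slope_scale = 1)
  restr <- cieg_ltp2(m_sws, m_rem, "ltp2_restrictive", slope_scale = 1)
  # non-positive REM slope is never potentiated
  expect_equal(perm[1, 2], 0)
  expect_equal(restr[1, 2], 0)
  # beta = pi/2 for slopes (-1, 1): permissive gain 1 - (pi/2)/(3pi/2) = 2/3
  expect_equal(perm[2, 1], 1 - (pi / 2) / (3 * pi / 2), tolerance = 1e-12)
  expect_equal(restr[2, 1], 1 - (pi / 2) / pi, tolerance = 1e-12)
  # restrictive never exceeds permissive on identical slopes
  set.seed(33)
  ms <- matrix(rnorm(100), 10, 10); diag(ms) <- 0
  mr <- matrix(rnorm(100), 10, 10); diag(mr) <- 0
  p <- cieg_ltp2(ms, mr, "ltp2_permissive")
  r <- cieg_ltp2(ms, mr, "ltp2_restrictive")
  expect_true(all(r <= p + 1e-12))
  expect_true(all(p >= 0 & p <= 1))
  # gain at the cutoff angle is zero; gain grows toward 1 as beta -> 0
  expect_equal(cieg_ltp2(matrix(0, 2, 2), matrix(1e-12, 2, 2),
                         "ltp2_restrictive", slope_scale = 1)[1, 2], 0,
               tolerance = 1e-9)
})

test_that("Gaussian bonus is triggered, scaled and integrates to the gain", {
  cieg <- matrix(0.5, 3, 3); diag(cieg) <- 0
  sched <- ltp_schedule("ltp1_full_sws", cieg, t_T = 100, mu = 1800,
                        sigma = 600)
  # zero before the trigger
  expect_equal(gaussian_bonus(99, sched), cieg * 0)
  # peak increment for unit gain: dt / (sigma * sqrt(2*pi))
  sched1 <- ltp_schedule("ltp1_full_sws", 1 - diag(3), t_T = 0, mu = 1800,
                         sigma = 600)
  peak <- gaussian_bonus(1800, sched1, dt = 0.004)
  expect_equal(peak[1, 2], 0.004 / (600 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(0.004 / (600 * sqrt(2 * pi)), 2.659e-6, tolerance = 1e-3)
  # Riemann sum over the schedule recovers the unit gain
  tt <- seq(0, 1800 + 6 * 600, by = 0.004)
  dens <- exp(-0.5 * ((tt - 1800) / 600)^2) / (600 * sqrt(2 * pi)) * 0.004
  expect_equal(sum(dens), 1, tolerance = 0.01)

  expect_error(ltp_schedule("ltp1_full_sws", cieg, 0, sigma = -1), "sigma")
  expect_error(ltp_schedule("ltp1_full_sws", cieg + 2, 0), "\\[0, 1\\]")
})

test_that("full-SWS synchrony epoch recruits a superset of the 30 s epoch", {
  cfg <- model1_config(N = 15)
  hyp <- toy_hypnogram()
  set.seed(34)
  ras <- gen_state_raster(hyp, n = 15)
  trig <- select_trigger(hyp, 1L)
  traj <- simulate_model1(cfg, ras, duration = trig$t_T,
                          snapshot_stride = 250L)
  full <- build_ltp_schedule("ltp1_full_sws", trig, traj)
  s30 <- build_ltp_schedule("ltp1_30s_sws_end", trig, traj)
  # co-firing bins in the last 30 s of SWS are a subset of the full episode
  expect_true(all(full$cieg[s30$cieg > 0] > 0))
  expect_gte(sum(full$cieg > 0), sum(s30$cieg > 0))
})
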