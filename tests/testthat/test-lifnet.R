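test_that("STDP increments evaluate the pairwise rule constants", {
  cfg <- stdp_config()
  # potentiation at vanishing lag approaches C_p
  expect_equal(stdp_potentiation(1e-12, 0.25, cfg), 3.2, tolerance = 1e-9)
  # one time constant later it is C_p / e
  expect_equal(stdp_potentiation(0.020, 0.25, cfg), 3.2 * exp(-1),
               tolerance = 1e-12)
  expect_equal(3.2 * exp(-1), 1.1772, tolerance = 1e-4)
  # depression at -20 ms on a 1 nS synapse
  expect_equal(stdp_depression(-0.020, 1, cfg), -0.03 * exp(-1),
               tolerance = 1e-12)
  expect_equal(-0.03 * exp(-1), -0.011036, tolerance = 1e-4)
  # the noise factor enters as stated
  expect_equal(stdp_potentiation(0, 2, cfg, v = 0.01), 3.2 + 0.02)
})

test_that("sleep modulation weakens potentiation and strengthens depression", {
  cfg <- stdp_config()
  sch <- sleep_schedule()
  expect_equal(sleep_modulated_constants(cfg, 1, 400, sch),
               list(c_p = 3.2, c_d = 0.03))
  expect_equal(sleep_modulated_constants(cfg, 2, 400, sch),
               list(c_p = 1.6, c_d = 0.06))
  # outside the sleep interval gamma is inert
  expect_equal(sleep_modulated_constants(cfg, 2, 100, sch),
               list(c_p = 3.2, c_d = 0.03))
  expect_equal(sleep_modulated_constants(cfg, 2, 585, sch),
               list(c_p = 3.2, c_d = 0.03))
  # literal-text alternative multiplies both
  expect_equal(sleep_modulated_constants(cfg, 2, 400, sch,
                                         mode = "both_multiplied"),
               list(c_p = 6.4, c_d = 0.06))
  expect_error(sleep_modulated_constants(cfg, 0, 400, sch), "gamma")
})

test_that("multiplicative normalization holds the row mean at omega exactly", {
  set.seed(51)
  W <- matrix(runif(45 * 200), 45, 200)
  dW <- matrix(rnorm(45 * 200, 0, 0.3), 45, 200)
  W2 <- normalize_weights(W, dW, omega = 0.25)
  expect_equal(rowMeans(W2), rep(0.25, 45), tolerance = 1e-12)
  expect_true(all(W2 >= 0))
  # identity when nothing changed and the mean is already omega
  W3 <- normalize_weights(W, 0, 0.25)
  expect_equal(normalize_weights(W3, 0, 0.25), W3, tolerance = 1e-12)
  # scale invariance: doubling a row changes nothing after normalization
  W4 <- W3; W4[1, ] <- 2 * W3[1, ]
  expect_equal(normalize_weights(W4, 0, 0.25)[1, ], W3[1, ],
               tolerance = 1e-12)
  expect_error(normalize_weights(matrix(0, 2, 3), 0), "non-positive")
})

test_that("embossing plan normalizes the reference row and avoids self-picks", {
  # uniform reference row gives unit gains
  W <- matrix(0.25, 5, 8)
  plan <- build_embossing_plan(W, seed = 52)
  expect_equal(plan$theta, matrix(1, 5, 8))
  expect_true(all(plan$k != seq_len(5)))
  # an entry at twice the row mean gets gain 2
  W[2, ] <- 0.1
  W[2, 1] <- 0.2 * 7 / 6   # make entry 1 equal twice the new row mean
  rm2 <- mean(W[2, ])
  plan <- build_embossing_plan(W, seed = 53)
  i <- which(plan$k == 2L)[1]
  expect_equal(plan$theta[i, 1], W[2, 1] / rm2, tolerance = 1e-12)
  # derangement property over many draws
  for (s in 1:20) expect_true(all(build_embossing_plan(W, seed = s)$k != 1:5))
  expect_error(build_embossing_plan(matrix(0, 3, 4)), "all-zero")
})

test_that("embossing LTP bonus integrates to 0.05 nS", {
  sch <- sleep_schedule()
  theta <- matrix(1, 2, 2)
  # zero gain switches the bonus off entirely
  expect_equal(ltp_bonus_m2(405, theta, 0, sch), matrix(0, 2, 2))
  # peak instantaneous rate A = 0.05 / (45 * sqrt(2*pi))
  peak <- ltp_bonus_m2(405, theta, 1, sch, dt = 1)
  expect_equal(peak[1, 1], 0.05 / (45 * sqrt(2 * pi)), tolerance = 1e-12)
  expect_equal(0.05 / (45 * sqrt(2 * pi)), 4.432e-4, tolerance = 1e-3)
  # Riemann sum of the unmodulated Gaussian recovers the 0.05 nS integral
  # (early sleep onset so the Heaviside gate removes no Gaussian mass)
  sch2 <- sleep_schedule(t_sleep = 40, t_wake = 800, t_ltp_peak = 405,
                         t_ltp_std = 45)
  tt <- seq(40, 800, by = 0.001)
  tot <- sum(vapply(tt, function(t) ltp_bonus_m2(t, theta, 1, sch2,
                                                 dt = 0.001)[1, 1],
                    numeric(1)))
  expect_equal(tot, 0.05, tolerance = 1e-4)
  # the default schedule's gate at t_sleep = 315 truncates the lower 2-sigma
  # tail, leaving ~97.7% of the mass
  tt <- seq(315, 800, by = 0.001)
  tot <- sum(vapply(tt, function(t) ltp_bonus_m2(t, theta, 1, sch,
                                                 dt = 0.001)[1, 1],
                    numeric(1)))
  expect_equal(tot, 0.05 * stats::pnorm(2), tolerance = 1e-4)
  # Heaviside gating before sleep onset
  expect_equal(ltp_bonus_m2(314, theta, 1, sch)[1, 1], 0)
})

test_that("membrane dynamics decay, integrate and release feedback IPSPs", {
  lif <- lif_config()
  n <- lif$n_neurons; m <- lif$m_inputs
  state <- function(V0) list(
    W = matrix(0.25, n, m), V = rep(V0, n), g_e = numeric(n),
    g_i = numeric(n), ref_until = rep(-1, n),
    last_pre = rep(-1e9, m), last_post = rep(-1e9, n),
    inh_queue = integer(2L))
  run <- function(st, steps, ext_step = integer(0), ext_unit = integer(0),
                  V_init = st$V) {
    sleepsyn:::sim_model2_cpp(
      W = st$W, ext_step = ext_step, ext_unit = ext_unit,
      step_lo = 1L, step_hi = steps, dt = lif$dt,
      tau_m = lif$tau_m, v_rest = lif$v_rest, v_th = lif$v_thresh,
      v_reset = lif$v_reset, t_ref = lif$t_ref, tau_syn = lif$tau_syn,
      tau_inh = lif$tau_inh, e_exc = lif$e_exc, e_inh = lif$e_inh,
      g_leak = lif$g_leak, inh_weight = lif$inh_weight, inh_delay_steps = 2L,
      tau_stdp = 0.02, c_p = 0, c_d = 0, sigma_v = 0,
      t_sleep = 1e9, t_wake = 2e9, gamma_sleep = 1, gamma_both = FALSE,
      has_ltp = FALSE, theta = matrix(0, 1, 1), kappa = 0,
      t_peak = 0, t_std = 1, ltp_A = 0, omega = 0.25,
      V = V_init, g_e = st$g_e, g_i = st$g_i, ref_until = st$ref_until,
      last_pre = st$last_pre, last_post = st$last_post,
      inh_queue = st$inh_queue, snapshot_stride = steps)
  }
  # zero input: the membrane relaxes to rest without spiking
  st <- state(-60)
  out <- run(st, 500L)
  expect_true(all(abs(out$V - lif$v_rest) < 0.01))
  expect_equal(sum(out$spike_counts), 0)
  # one neuron pushed over threshold: every neuron receives an IPSP after
  # the 2-step feedback delay
  V0 <- rep(lif$v_rest, n); V0[1] <- lif$v_thresh + 1
  out <- run(st, 4L, V_init = V0)
  expect_equal(out$spike_counts[1], 1L)
  expect_true(all(out$g_i > 0))
  # constant suprathreshold drive fires periodically at the refractory-
  # limited interspike interval predicted by the LIF solution
  st2 <- state(lif$v_rest)
  ext_step <- rep(1:2000, each = 40)
  ext_unit <- rep(1:40, times = 2000)
  lif2 <- lif_config(inh_weight = 0)   # disable competition
  out2 <- sleepsyn:::sim_model2_cpp(
    W = st2$W * 8, ext_step = ext_step, ext_unit = ext_unit,
    step_lo = 1L, step_hi = 2000L, dt = lif2$dt,
    tau_m = lif2$tau_m, v_rest = lif2$v_rest, v_th = lif2$v_thresh,
    v_reset = lif2$v_reset, t_ref = lif2$t_ref, tau_syn = lif2$tau_syn,
    tau_inh = lif2$tau_inh, e_exc = lif2$e_exc, e_inh = lif2$e_inh,
    g_leak = lif2$g_leak, inh_weight = 0, inh_delay_steps = 2L,
    tau_stdp = 0.02, c_p = 0, c_d = 0, sigma_v = 0,
    t_sleep = 1e9, t_wake = 2e9, gamma_sleep = 1, gamma_both = FALSE,
    has_ltp = FALSE, theta = matrix(0, 1, 1), kappa = 0,
    t_peak = 0, t_std = 1, ltp_A = 0, omega = 0.25,
    V = st2$V, g_e = st2$g_e, g_i = st2$g_i, ref_until = st2$ref_until,
    last_pre = st2$last_pre, last_post = st2$last_post,
    inh_queue = st2$inh_queue, snapshot_stride = 2000L)
  isi <- diff(which(tabulate(out2$sp_step[out2$sp_unit == 1], 2000) > 0))
  expect_gt(length(isi), 3)
  expect_lt(stats::sd(isi), 1.5)        # near-periodic
  expect_true(all(isi >= lif2$t_ref / lif2$dt))
})

test_that("full runs conserve the mean weight and stay reproducible", {
  sch <- scaled_schedule()
  r <- run_model2(gamma_sleep = 1, kappa_sleep = 2, duration = 95,
                  schedule = sch, seed = 54)
  # per-neuron mean weight is omega after every recorded update
  for (k in seq_along(r$times)) {
    Wk <- matrix(r$W_snapshots[, k], 45, 200)
    expect_equal(rowMeans(Wk), rep(0.25, 45), tolerance = 1e-9)
    expect_true(all(Wk >= 0))
  }
  r2 <- run_model2(gamma_sleep = 1, kappa_sleep = 2, duration = 95,
                   schedule = sch, seed = 54)
  expect_identical(r$W_final, r2$W_final)
  expect_identical(r$T_S, r2$T_S)
  expect_error(run_model2(duration = 500), "exceed")
  expect_error(run_model2(gamma_sleep = 0, duration = 900), "gamma")
})
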