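test_that("zero drive with zero history stays identically zero", {
  cfg <- pc_config(n_levels = 3, burn_in_ms = 0)
  zero <- pcwaves:::new_ts_set(matrix(0, 2, 400), fs = 1000)
  sim <- pc_simulate(cfg, input = zero)
  expect_true(all(sim$predictions == 0))
  expect_true(all(sim$residuals == 0))
})

test_that("simulator matches the scalar Euler oracle bit-for-bit", {
  set.seed(7)
  n <- 500
  for (L in c(1, 2, 4)) {
    inp <- rnorm(n)
    pri <- rnorm(n)
    cfg <- pc_config(n_levels = L, delta_t = 12, tau = 17, tau_d = 200,
                     burn_in_ms = 0)
    sim <- pc_simulate(cfg,
                       input = pcwaves:::new_ts_set(matrix(inp, 1), fs = 1000),
                       prior = pcwaves:::new_ts_set(matrix(pri, 1), fs = 1000))
    ref <- oracle_euler(L, 12, 17, 200, 1, inp, pri)
    expect_identical(matrix(sim$predictions[, 1, ], nrow = L), ref$y)
    expect_identical(matrix(sim$residuals[, 1, ], nrow = L), ref$x)
  }
  # step input on the two-area circuit
  step_in <- pcwaves:::new_ts_set(matrix(rep(1, n), 1), fs = 1000)
  cfg <- pc_config(n_levels = 1, delta_t = 12, tau = 17, tau_d = 200,
                   burn_in_ms = 0)
  sim <- pc_simulate(cfg, input = step_in)
  ref <- oracle_euler(1, 12, 17, 200, 1, rep(1, n))
  expect_identical(as.numeric(sim$predictions[1, 1, ]), as.numeric(ref$y))
})

test_that("linear mode is linear: scaling and superposition", {
  cfg <- pc_config(n_levels = 3, burn_in_ms = 0)
  a <- white_noise(2, 1, fs = 1000, seed = 1)
  b <- white_noise(2, 1, fs = 1000, seed = 2)
  sim_a <- pc_simulate(cfg, input = a)
  sim_3a <- pc_simulate(cfg, input = pcwaves:::new_ts_set(3 * unclass(a),
                                                          fs = 1000))
  expect_equal(sim_3a$predictions, 3 * sim_a$predictions, tolerance = 1e-12)
  sim_b <- pc_simulate(cfg, input = b)
  sim_ab <- pc_simulate(cfg,
                        input = pcwaves:::new_ts_set(unclass(a) + unclass(b),
                                                     fs = 1000))
  expect_equal(sim_ab$predictions, sim_a$predictions + sim_b$predictions,
               tolerance = 1e-10)
})

test_that("asymmetric 16/8 ms delays ring at the same frequency as 12 ms", {
  sym <- pc_config(n_levels = 1, delta_t = 12, tau = 17, tau_d = 200)
  asym <- pc_config(n_levels = 1, delta_t_fwd = 16, delta_t_bwd = 8,
                    tau = 17, tau_d = 200)
  expect_equal(asym$delta_t, 12)
  peak <- function(cfg) {
    sim <- pc_run(cfg, "input", n_trials = 60, duration_s = 3, seed = 5)
    irf <- crosscorrelate(pcwaves:::level_set(sim, 1), sim$input,
                          max_lag_ms = 1000)
    irf_spectrum(irf)$peak_frequency_hz
  }
  f_sym <- peak(sym)
  f_asym <- peak(asym)
  expect_lt(abs(f_sym - f_asym), 1)  # within one frequency bin
})

test_that("configuration contracts are enforced", {
  expect_error(pc_config(delta_t = 12.5, dt = 1), "integer multiple")
  expect_warning(pc_config(tau = 30, tau_d = 20), "tau_d")
  expect_error(pc_config(delta_t_fwd = 16), "both")
  cfg <- pc_config(n_levels = 2, overflow_guard = 1e-4, burn_in_ms = 0)
  drv <- white_noise(1, 0.5, fs = 1000, seed = 3)
  expect_error(pc_simulate(cfg, input = drv), "diverged at level")
  expect_error(pc_simulate(pc_config(), NULL, NULL), "at least one")
})

test_that("sigmoid mode squashes monotonically and stays wave-consistent", {
  cfg <- pc_config(n_levels = 7, nonlinearity = "sigmoid",
                   sigmoid_offset = 0.5)
  expect_equal(apply_nonlinearity(cfg, 0.5), 0)       # midpoint
  expect_lt(abs(apply_nonlinearity(cfg, -50) - (-1)), 1e-12)  # saturation
  v <- apply_nonlinearity(cfg, seq(-3, 3, by = 0.1))
  expect_true(all(diff(v) > 0))                        # monotone
  # forward waves survive the nonlinearity
  cfgs <- pc_config(n_levels = 7, nonlinearity = "sigmoid")
  sim <- pc_run(cfgs, "input", n_trials = 10, duration_s = 3, seed = 9)
  st <- wave_stats(eeg_maps(sim), normalize = "zscore")
  expect_gt(mean(st$log_ratio), 0)
})

test_that("tidy and glance summarise a run", {
  sim <- pc_run(pc_config(n_levels = 2), "input", n_trials = 2,
                duration_s = 1, seed = 1)
  td <- tidy(sim)
  expect_equal(nrow(td), 2 * 2 * 1000)
  expect_named(td, c("level", "trial", "time_s", "prediction", "residual"))
  gl <- glance(sim)
  expect_equal(gl$n_levels, 2)
  expect_equal(gl$duration_s, 1)
})
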