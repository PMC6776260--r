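test_that("closed-form oscillation frequency follows the 8-delay period", {
  expect_equal(oscillation_frequency(12), 125 / 12)
  expect_equal(oscillation_frequency(12.5), 10)
  expect_equal(oscillation_frequency(c(10, 15)), c(12.5, 1000 / 120))
  expect_error(oscillation_frequency(0), "positive")
})

test_that("optimal tau is 4/pi times the delay", {
  expect_equal(optimal_tau(12), 8 * 12 / (2 * pi))
  expect_equal(optimal_tau(7) / 7, 4 / pi)
  expect_error(optimal_tau(-1), "positive")
})

test_that("independent 2-D root search confirms the closed forms", {
  # neutral-oscillation ratio from the oracle bisection (the oracle's
  # optimiser resolves Re(alpha) to ~1e-6, bounding the achievable ratio
  # precision; the paper prints the ratio to 4 decimals)
  expect_equal(oracle_critical_ratio(10), 4 / pi, tolerance = 1e-4)
  # and from the package's own root finder
  expect_equal(critical_tau_ratio(12), 4 / pi, tolerance = 1e-9)
  # the neutral root's frequency equals both 2*pi/(8 dT) and 1/tau
  r <- oracle_roots(12, optimal_tau(12))
  dom <- r[which.min(abs(r[, 1])), ]
  expect_lt(abs(dom[1]), 1e-7)
  expect_equal(dom[2], 2 * pi / (8 * 12), tolerance = 1e-6)
  expect_equal(dom[2], 1 / optimal_tau(12), tolerance = 1e-6)
})

test_that("characteristic roots classify the dynamical regimes", {
  neutral <- characteristic_roots(12, optimal_tau(12))
  expect_true(any(neutral$regime == "oscillatory-neutral"))
  dom <- neutral[1, ]
  expect_lt(abs(dom$alpha_real), 1e-8)
  expect_equal(dom$frequency_hz, oscillation_frequency(12), tolerance = 1e-6)

  damped <- characteristic_roots(12, 100 * 12)
  osc <- damped[damped$omega > 1e-8, ]
  expect_true(all(osc$alpha_real < 0))

  growing <- characteristic_roots(12, 0.8 * 12)
  osc_g <- growing[growing$omega > 1e-8, ]
  expect_true(any(osc_g$alpha_real > 0))

  # vanishing delay: plain leaky integrator, real root at -1/tau
  tiny <- characteristic_roots(1e-4, 20)
  real_root <- tiny[tiny$regime == "non-oscillatory", ]
  expect_gt(nrow(real_root), 0)
  expect_equal(real_root$alpha_real[1], -1 / 20, tolerance = 1e-3)
})

test_that("root frequencies scale inversely with a joint time rescaling", {
  base <- characteristic_roots(12, 15)
  scaled <- characteristic_roots(24, 30)
  expect_equal(scaled$frequency_hz, base$frequency_hz / 2, tolerance = 1e-6)
  expect_equal(scaled$alpha_real, base$alpha_real / 2, tolerance = 1e-8)
})

test_that("regime map agrees with simulated spectral peaks", {
  # on the neutral curve the simulated IRF peak tracks Im(alpha)/2pi
  for (dT in c(10, 14)) {
    tau <- optimal_tau(dT)
    pred <- characteristic_roots(dT, tau)$frequency_hz[1]
    sim <- pc_run(pc_config(n_levels = 1, delta_t = dT, tau = tau),
                  "input", n_trials = 40, duration_s = 3, seed = 11)
    irf <- crosscorrelate(pcwaves:::level_set(sim, 1), sim$input, 1000)
    expect_lt(abs(irf_spectrum(irf)$peak_frequency_hz - pred), 1)
  }
})
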