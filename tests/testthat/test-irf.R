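test_that("identity and pure-delay systems recover the expected IRF", {
  d <- white_noise(4, 1.2, fs = 500, seed = 2)
  auto <- crosscorrelate(d, d, max_lag_ms = 200)
  expect_equal(which.max(auto$values), 1)         # white-noise autocorr: lag 0
  expect_equal(auto$values[1], 1, tolerance = 0.05)  # cov/var at lag 0

  lagn <- 25  # 50 ms at 500 Hz
  shifted <- cbind(matrix(0, 4, lagn),
                   unclass(d)[, 1:(ncol(d) - lagn)])
  irf <- crosscorrelate(pcwaves:::new_ts_set(shifted, fs = 500), d,
                        max_lag_ms = 200)
  expect_equal(irf$lag_ms[which.max(irf$values)], 50)
})

test_that("FFT cross-correlation equals the direct sliding product", {
  s <- white_noise(3, 1, fs = 1000, seed = 4)
  d <- white_noise(3, 1, fs = 1000, seed = 5)
  a <- crosscorrelate(s, d, max_lag_ms = 300, method = "fft")
  b <- crosscorrelate(s, d, max_lag_ms = 300, method = "direct")
  expect_equal(a$values, b$values, tolerance = 1e-10)
})

test_that("IRF scales linearly with drive amplitude", {
  cfg <- pc_config(n_levels = 1, delta_t = 12, tau = 17)
  d1 <- white_noise(5, 2, fs = 1000, cutoff_hz = 80, seed = 6,
                    variance = 1)
  d4 <- pcwaves:::new_ts_set(2 * unclass(d1), fs = 1000)
  s1 <- pc_simulate(cfg, input = d1)
  s4 <- pc_simulate(cfg, input = d4)
  i1 <- crosscorrelate(pcwaves:::level_set(s1, 1), s1$input, 500)
  i4 <- crosscorrelate(pcwaves:::level_set(s4, 1), s4$input, 500)
  # response per unit drive is amplitude-invariant for a linear system
  expect_equal(i1$values, i4$values, tolerance = 1e-10)
})

test_that("spectrum peak finds a known sinusoid and flags silence", {
  t_s <- seq(0, 1, by = 1 / 500)
  irf <- structure(list(values = cos(2 * pi * 10 * t_s), fs = 500,
                        lag_ms = t_s * 1000, n_trials = 1),
                   class = "pc_irf")
  sp <- irf_spectrum(irf)
  expect_equal(sp$peak_frequency_hz, 10, tolerance = 0.3)
  expect_true(sp$oscillatory)

  zero <- structure(list(values = rep(0, 100), fs = 500), class = "pc_irf")
  sz <- irf_spectrum(zero)
  expect_false(sz$oscillatory)
  expect_equal(sz$peak_amplitude, 0)
})

test_that("contract violations error cleanly", {
  d <- white_noise(2, 1, fs = 500, seed = 1)
  short <- pcwaves:::new_ts_set(unclass(d)[, 1:100], fs = 500)
  expect_error(crosscorrelate(short, d), "identical")
  expect_error(crosscorrelate(d, d, max_lag_ms = 5000), "exceeds")
})

test_that("per-trial IRF maps stack levels in hierarchy order", {
  sim <- pc_run(pc_config(n_levels = 3), "input", n_trials = 4,
                duration_s = 2, seed = 8)
  maps <- irf_maps(sim, "input", max_lag_ms = 500)
  expect_length(maps, 4)
  expect_equal(dim(maps[[1]]), c(3, 501))
  avg <- irf_maps(sim, "input", max_lag_ms = 500, per_trial = FALSE)
  expect_equal(dim(avg), c(3, 501))
  # trial average equals the mean of per-trial maps
  expect_equal(as.matrix(avg),
               Reduce(`+`, lapply(maps, as.matrix)) / 4, tolerance = 1e-12)
  expect_error(irf_maps(sim, "prior"), "no `prior` drive")
})
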