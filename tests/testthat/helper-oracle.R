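# Independent reference implementations used as oracles. These are written
# as plain scalar loops, deliberately sharing no code with the package.

# Scalar forward-Euler integrator for the delayed predictive-coding
# network: one trial, explicit loops over levels and steps, zero
# pre-history. Returns the full (untrimmed) traces.
oracle_euler <- function(n_levels, delta_t, tau, tau_d, dt, input,
                         prior = NULL) {
  n <- length(input)
  d <- round(delta_t / dt)
  y <- matrix(0, n_levels, n)
  x <- matrix(0, n_levels, n)
  gy <- function(l, t) if (t >= 1) y[l, t] else 0
  gx <- function(l, t) if (t >= 1) x[l, t] else 0
  gp <- function(t) {
    if (is.null(prior) || t < 1) 0 else prior[t]
  }
  for (t in 1:n) {
    for (l in 1:n_levels) {
      below <- if (l == 1) input[t] else y[l - 1, t]
      x[l, t] <- below - gy(l, t - d)
    }
    if (t < n) {
      for (l in 1:n_levels) {
        above <- if (l == n_levels) gp(t - d) else gy(l + 1, t - d)
        y[l, t + 1] <- y[l, t] +
          dt * (gx(l, t - d) / tau + (above - y[l, t]) / tau_d)
      }
    }
  }
  list(y = y, x = x)
}

# Independent complex root solver for alpha * tau + exp(-2 alpha dT) = 0:
# minimises |f|^2 over (Re, Im) with restarted Nelder-Mead from a grid of
# starts (no Newton, no shared code with the package's solver).
oracle_roots <- function(delta_t, tau, n_starts = 12) {
  obj <- function(p) {
    a <- complex(real = p[1], imaginary = p[2])
    Mod(a * tau + exp(-2 * a * delta_t))^2
  }
  om_max <- pi / (2 * delta_t)
  starts <- expand.grid(re = c(-0.05, 0, 0.05) / delta_t,
                        im = seq(om_max / n_starts, om_max,
                                 length.out = n_starts))
  sols <- apply(starts, 1, function(s) {
    o <- stats::optim(as.numeric(s), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 2000))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 2000))
    if (o$value < 1e-12) o$par else c(NA, NA)
  })
  sols <- t(sols)
  sols <- sols[stats::complete.cases(sols) &
                 sols[, 2] > 1e-6, , drop = FALSE]
  unique(round(sols, 7))
}

# Ratio tau/dT at which the dominant oscillatory root crosses the
# imaginary axis, by bisection on the oracle solver.
oracle_critical_ratio <- function(delta_t = 10) {
  re_dom <- function(ratio) {
    r <- oracle_roots(delta_t, ratio * delta_t)
    r[which.min(abs(r[, 1])), 1]
  }
  stats::uniroot(re_dom, c(0.9, 1.8), tol = 1e-8)$root
}

# Cached full-size study runs shared across acceptance tests.
.study_cache <- new.env(parent = emptyenv())

study_report <- function(drive) {
  key <- drive
  if (is.null(.study_cache[[key]])) {
    .study_cache[[key]] <- wave_report(
      pc_config(), drive, n_trials = 200, duration_s = 6,
      seed = if (drive == "input") 101 else 202,
      n_shuffles = 1000, keep_maps = (drive == "input")
    )
  }
  .study_cache[[key]]
}
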