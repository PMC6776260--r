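#' Two-parameter scan of the two-area circuit
#'
#' Runs the two-area model (sensory input + one predictive level) over a
#' grid of integration time constants and communication delays, and records
#' the spectral peak of the trial-averaged IRF in each cell — the numerical
#' regime map of where delayed predictive coding rings, and at what
#' frequency. Alpha-band (8-13 Hz) peaks dominate the biologically
#' plausible range (tau 15-25 ms, delay 10-15 ms); shorter constants move
#' the rhythm into beta/gamma.
#'
#' @param tau_grid,deltat_grid Parameter values in ms.
#' @param n_trials White-noise trials per cell (200 reproduces the full
#'   map; 20-50 gives a fast approximate map).
#' @param duration_s Trial duration in seconds.
#' @param tau_d Decay time constant in ms.
#' @param seed Integer seed (each cell derives its own substream).
#' @param max_lag_ms IRF support for the spectral measurement.
#' @return A `pc_scan` tibble: one row per cell with `tau`, `delta_t`,
#'   `peak_frequency_hz`, `peak_amplitude`, `alpha_band` (peak in 8-13 Hz),
#'   `n_trials`, `diverged`.
#' @examples
#' \donttest{
#' scan_two_level(c(15, 20), c(10, 14), n_trials = 10, duration_s = 1)
#' }
#' @export
scan_two_level <- function(tau_grid, deltat_grid, n_trials = 200,
                           duration_s = 3, tau_d = 200, seed = 1,
                           max_lag_ms = 1000) {
  stopifnot(length(tau_grid) > 0, length(deltat_grid) > 0)
  grid <- tidyr::expand_grid(tau = tau_grid, delta_t = deltat_grid)
  rows <- purrr::pmap(grid, function(tau, delta_t) {
    cell_seed <- (seed + round(1000 * tau) * 131 + round(1000 * delta_t)) %%
      .Machine$integer.max
    cfg <- pc_config(n_levels = 1, delta_t = delta_t, tau = tau,
                     tau_d = tau_d)
    res <- tryCatch({
      sim <- pc_run(cfg, "input", n_trials = n_trials,
                    duration_s = duration_s, seed = cell_seed)
      irf <- crosscorrelate(level_set(sim, 1), sim$input,
                            max_lag_ms = max_lag_ms)
      sp <- irf_spectrum(irf)
      tibble::tibble(peak_frequency_hz = sp$peak_frequency_hz,
                     peak_amplitude = sp$peak_amplitude, diverged = FALSE)
    }, error = function(e) {
      tibble::tibble(peak_frequency_hz = NA_real_,
                     peak_amplitude = NA_real_, diverged = TRUE)
    })
    dplyr::bind_cols(tibble::tibble(tau = tau, delta_t = delta_t), res)
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(
      alpha_band = !.data$diverged & .data$peak_frequency_hz >= 8 &
        .data$peak_frequency_hz <= 13,
      n_trials = n_trials
    )
  new_pc_scan(out, "two_level")
}

#' Two-parameter scan of the multilevel model's wave direction
#'
#' For each (tau, delay) cell, simulates the hierarchical model under the
#' requested drive and summarises the traveling-wave statistic over the
#' sliding-window maps: mean log ratio (positive = forward, negative =
#' backward) and the modal peak temporal frequency. Input drive yields
#' positive cells, prior drive negative ones, and with both drives the
#' input dominates (the top-down coupling is `tau/tau_d`-fold weaker).
#'
#' @inheritParams scan_two_level
#' @param drive_mode `"input"`, `"prior"`, or `"both"`.
#' @param n_levels Number of predictive levels.
#' @param normalize Row normalization for the maps (see [wave_stat()];
#'   model levels differ in gain by orders of magnitude, so `"zscore"` is
#'   the default here).
#' @return A `pc_scan` tibble with `tau`, `delta_t`, `mean_log_ratio`,
#'   `peak_frequency_hz` (modal), `n_maps`, `diverged`.
#' @export
scan_multilevel <- function(tau_grid, deltat_grid,
                            drive_mode = c("input", "prior", "both"),
                            n_trials = 20, duration_s = 6, n_levels = 7,
                            tau_d = 200, seed = 1,
                            normalize = c("zscore", "center")) {
  drive_mode <- match.arg(drive_mode)
  normalize <- match.arg(normalize)
  grid <- tidyr::expand_grid(tau = tau_grid, delta_t = deltat_grid)
  rows <- purrr::pmap(grid, function(tau, delta_t) {
    cell_seed <- (seed + round(1000 * tau) * 131 + round(1000 * delta_t)) %%
      .Machine$integer.max
    cfg <- pc_config(n_levels = n_levels, delta_t = delta_t, tau = tau,
                     tau_d = tau_d)
    res <- tryCatch({
      sim <- pc_run(cfg, drive_mode, n_trials = n_trials,
                    duration_s = duration_s, seed = cell_seed)
      st <- wave_stats(eeg_maps(sim), normalize = normalize)
      tibble::tibble(
        mean_log_ratio = mean(st$log_ratio),
        peak_frequency_hz = modal_value(st$peak_freq_hz),
        n_maps = nrow(st), diverged = FALSE
      )
    }, error = function(e) {
      tibble::tibble(mean_log_ratio = NA_real_,
                     peak_frequency_hz = NA_real_,
                     n_maps = 0L, diverged = TRUE)
    })
    dplyr::bind_cols(tibble::tibble(tau = tau, delta_t = delta_t), res)
  })
  new_pc_scan(dplyr::bind_rows(rows), paste0("multilevel_", drive_mode))
}

#' Scan of the decay time constant
#'
#' Varies the decay/top-down time constant while the integration constant
#' and delay stay fixed, averaging the wave statistic over independent
#' replicate simulations per value. The waves are robust for
#' `tau_d > ~50 ms`; as `tau_d` approaches `tau` the log ratios converge to
#' zero (the waves vanish) and the peak frequency drifts up toward ~15 Hz.
#'
#' @param tau_d_values Decay constants to scan, in ms.
#' @param tau,delta_t Fixed integration constant and delay, in ms.
#' @param replicates Independent simulations averaged per value.
#' @param duration_s Trial duration per replicate in seconds.
#' @param drive_mode `"input"`, `"prior"`, or `"both"`.
#' @param n_levels Number of predictive levels.
#' @param seed Integer seed.
#' @param normalize Row normalization for the maps.
#' @return A `pc_scan` tibble with `tau_d`, `mean_log_ratio`,
#'   `mean_max_power`, `mean_peak_frequency_hz`, `replicates`.
#' @export
scan_tau_d <- function(tau_d_values = seq(20, 200, by = 5), tau = 20,
                       delta_t = 12, replicates = 20, duration_s = 6,
                       drive_mode = c("input", "prior", "both"),
                       n_levels = 7, seed = 1,
                       normalize = c("zscore", "center")) {
  drive_mode <- match.arg(drive_mode)
  normalize <- match.arg(normalize)
  rows <- purrr::map(tau_d_values, function(td) {
    cfg <- pc_config(n_levels = n_levels, delta_t = delta_t, tau = tau,
                     tau_d = td)
    # one trial per replicate; trials are independent simulations
    sim <- pc_run(cfg, drive_mode, n_trials = replicates,
                  duration_s = duration_s,
                  seed = (seed + round(10 * td)) %% .Machine$integer.max)
    # whole-trial map per replicate
    maps <- lapply(seq_len(replicates), function(tr) sim_eeg(sim, tr))
    st <- wave_stats(maps, normalize = normalize)
    tibble::tibble(
      tau_d = td,
      mean_log_ratio = mean(st$log_ratio),
      mean_max_power = mean(pmax(st$fw_power, st$bw_power)),
      mean_peak_frequency_hz = mean(st$peak_freq_hz),
      replicates = replicates
    )
  })
  new_pc_scan(dplyr::bind_rows(rows), paste0("tau_d_", drive_mode))
}

#' Per-level autocorrelation timescales
#'
#' The network timescale of each level: the predictions are narrowband
#' oscillations, so the decay of interest is that of their amplitude
#' envelope, not of the ringing itself. For each level the analytic-signal
#' envelope of `y_L` is computed per trial, its trial-averaged
#' autocorrelation taken, subsampled, and the initial decay (down to
#' `floor`) fitted with `A * exp(-lag / theta)` by least squares on the
#' log-linear transform. Although every level shares the same integration
#' constant, theta grows steadily with the hierarchical level, mirroring
#' the cortical timescale hierarchy.
#'
#' @param sim A `pc_sim` (several seconds of data recommended).
#' @param max_lag_ms Fitting window in ms.
#' @param subsample_ms Lag spacing after subsampling, in ms.
#' @param floor Autocorrelation value at which the fit window ends (the
#'   tail below it is sampling noise).
#' @return A tibble with `level`, `theta_ms`, `r_squared`, `n_points`,
#'   `fit_ok`.
#' @examples
#' \donttest{
#' sim <- pc_run(pc_config(n_levels = 3), "input", n_trials = 5,
#'               duration_s = 4, seed = 1)
#' characterize_timescales(sim)
#' }
#' @export
characterize_timescales <- function(sim, max_lag_ms = 1000,
                                    subsample_ms = 10, floor = 0.05) {
  stopifnot(inherits(sim, "pc_sim"))
  L <- dim(sim$predictions)[1]
  n_trials <- dim(sim$predictions)[2]
  step <- max(1L, round(subsample_ms * sim$fs / 1000))
  rows <- purrr::map(seq_len(L), function(l) {
    m <- matrix(sim$predictions[l, , ], nrow = n_trials)
    env <- new_ts_set(t(apply(m, 1, analytic_envelope)), fs = sim$fs)
    ac <- crosscorrelate(env, env, max_lag_ms = max_lag_ms)
    r <- ac$values / ac$values[1]
    sel <- seq(1, length(r), by = step)
    r <- r[sel]; lag <- ac$lag_ms[sel]
    cut <- which(r < floor)[1]
    if (!is.na(cut)) {
      r <- r[seq_len(cut - 1)]
      lag <- lag[seq_len(cut - 1)]
    }
    if (length(r) < 3) {
      return(tibble::tibble(level = l, theta_ms = NA_real_,
                            r_squared = NA_real_, n_points = length(r),
                            fit_ok = FALSE))
    }
    fit <- stats::lm(log(r) ~ lag)
    slope <- unname(stats::coef(fit)[2])
    tibble::tibble(
      level = l,
      theta_ms = if (slope < 0) -1 / slope else NA_real_,
      r_squared = summary(fit)$r.squared,
      n_points = length(r),
      fit_ok = slope < 0
    )
  })
  dplyr::bind_rows(rows)
}

# amplitude envelope via the analytic signal
analytic_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(stats::fft(x) * h, inverse = TRUE) / n)
}

# trials x time ts_set for one level of a simulation
level_set <- function(sim, level) {
  new_ts_set(matrix(sim$predictions[level, , ],
                    nrow = dim(sim$predictions)[2]), fs = sim$fs)
}

modal_value <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  ux <- unique(x)
  ux[which.max(tabulate(match(x, ux)))]
}

new_pc_scan <- function(df, scan_type) {
  structure(df, scan_type = scan_type,
            class = c("pc_scan", class(df)))
}

#' @export
print.pc_scan <- function(x, ...) {
  cat(sprintf("<pc_scan:%s> %d cells\n", attr(x, "scan_type"), nrow(x)))
  NextMethod()
}
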