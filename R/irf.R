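#' Impulse response function by stimulus cross-correlation
#'
#' Estimates the impulse response (the "perceptual echo") of a response
#' signal to a white-noise drive: each trial of `signal` and `drive` is
#' mean-centred, their cross-covariance computed at non-negative lags
#' (drive leading), normalised by the drive variance, and averaged across
#' trials. Lags reaching past the trial end use the valid overlap only
#' (unbiased estimator), not zero padding. Computation goes through the FFT;
#' a direct sliding-dot-product reference is available as
#' `method = "direct"` for verification.
#'
#' @param signal A `ts_set` (trials x samples) or numeric matrix.
#' @param drive A `ts_set` with the same shape and sampling rate.
#' @param max_lag_ms Largest lag, in ms (default 1000: the echo's support).
#' @param fs Sampling rate in Hz, taken from `signal` when present.
#' @param method `"fft"` (default) or `"direct"`.
#' @param keep_trials Keep the per-trial cross-correlations (needed for
#'   per-trial wave maps).
#' @return A `pc_irf`: list with `lag_ms`, `values` (trial average),
#'   optionally `per_trial` (trials x lags), and `fs`.
#' @examples
#' d <- white_noise(4, 1.2, fs = 500, seed = 2)
#' irf <- crosscorrelate(d, d, max_lag_ms = 100)  # white-noise autocorrelation
#' which.max(irf$values)                          # peak at lag 0
#' @export
crosscorrelate <- function(signal, drive, max_lag_ms = 1000, fs = NULL,
                           method = c("fft", "direct"), keep_trials = FALSE) {
  method <- match.arg(method)
  if (is.null(fs)) fs <- attr(signal, "fs") %||% attr(drive, "fs")
  if (is.null(fs)) stop("supply `fs` or `ts_set` inputs")
  signal <- as.matrix(signal)
  drive <- as.matrix(drive)
  if (!identical(dim(signal), dim(drive))) {
    stop("`signal` and `drive` must have identical trial count and length")
  }
  n <- ncol(signal)
  max_lag <- round(max_lag_ms * fs / 1000)
  if (max_lag >= n) stop("`max_lag_ms` exceeds the trial length")

  s <- signal - rowMeans(signal)
  d <- drive - rowMeans(drive)
  dvar <- rowSums(d^2) / n
  counts <- n - (0:max_lag)

  cc <- if (method == "fft") {
    nfft <- stats::nextn(n + max_lag, 2)
    t(vapply(seq_len(nrow(s)), function(i) {
      sp <- stats::fft(c(s[i, ], numeric(nfft - n)))
      dp <- stats::fft(c(d[i, ], numeric(nfft - n)))
      raw <- Re(stats::fft(Conj(dp) * sp, inverse = TRUE)) / nfft
      raw[1:(max_lag + 1)]
    }, numeric(max_lag + 1)))
  } else {
    t(vapply(seq_len(nrow(s)), function(i) {
      vapply(0:max_lag, function(l) {
        sum(d[i, 1:(n - l)] * s[i, (1 + l):n])
      }, numeric(1))
    }, numeric(max_lag + 1)))
  }
  cc <- cc / outer(dvar, counts)  # unbiased covariance per unit drive variance

  structure(
    list(
      lag_ms = (0:max_lag) * 1000 / fs,
      values = colMeans(cc),
      per_trial = if (keep_trials) cc else NULL,
      n_trials = nrow(s),
      fs = fs
    ),
    class = "pc_irf"
  )
}

#' @export
print.pc_irf <- function(x, ...) {
  cat(sprintf("<pc_irf> %d lags (0..%g ms), averaged over %d trial(s)\n",
              length(x$lag_ms), max(x$lag_ms), x$n_trials))
  invisible(x)
}

#' @rdname crosscorrelate
#' @param x A `pc_irf`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.pc_irf <- function(x, ...) {
  tibble::tibble(lag_ms = x$lag_ms, value = x$values)
}

#' Amplitude spectrum and peak of an IRF
#'
#' Removes the mean of the (trial-averaged) IRF, computes its amplitude
#' spectrum, and reports the peak above a floor frequency (default 2 Hz, to
#' skip DC leakage). The IRF is zero-padded (factor `pad`) before the FFT
#' so the peak is located on a grid finer than the raw 1/support
#' resolution. An all-zero IRF yields zero amplitude and is flagged.
#'
#' @param irf A `pc_irf` or a plain numeric vector.
#' @param fs Sampling rate (taken from the `pc_irf` when present).
#' @param floor_hz Lowest frequency eligible as the peak.
#' @param pad Zero-padding factor for spectral interpolation.
#' @return A one-row tibble: `peak_frequency_hz`, `peak_amplitude`,
#'   `oscillatory` (FALSE when the IRF is identically zero), plus the full
#'   spectrum as a nested tibble in `spectrum`.
#' @examples
#' irf <- list(values = cos(2 * pi * 10 * seq(0, 1, by = 1/500)), fs = 500)
#' class(irf) <- "pc_irf"
#' irf_spectrum(irf)$peak_frequency_hz  # 10
#' @export
irf_spectrum <- function(irf, fs = NULL, floor_hz = 2, pad = 4) {
  v <- if (inherits(irf, "pc_irf")) irf$values else as.numeric(irf)
  if (is.null(fs)) fs <- if (inherits(irf, "pc_irf")) irf$fs else
    stop("supply `fs`")
  if (length(v) == 0) stop("empty IRF")
  n <- stats::nextn(pad * length(v), 2)
  amp <- Mod(stats::fft(c(v - mean(v),
                          numeric(n - length(v)))))[1:(floor(n / 2) + 1)]
  freq <- (seq_along(amp) - 1) * fs / n
  spec <- tibble::tibble(frequency_hz = freq, amplitude = amp)
  if (max(abs(v)) == 0) {
    return(tibble::tibble(peak_frequency_hz = NA_real_, peak_amplitude = 0,
                          oscillatory = FALSE, spectrum = list(spec)))
  }
  eligible <- which(freq >= floor_hz)
  k <- eligible[which.max(amp[eligible])]
  tibble::tibble(
    peak_frequency_hz = freq[k],
    peak_amplitude = amp[k],
    oscillatory = TRUE,
    spectrum = list(spec)
  )
}

#' Per-level IRF maps from a simulation
#'
#' Cross-correlates every level's prediction with the chosen drive and
#' stacks the level IRFs into ordered maps, the objects the traveling-wave
#' statistic consumes. With `per_trial = TRUE` one map per trial is
#' returned (each trial's own cross-correlation); otherwise a single
#' trial-averaged map.
#'
#' @param sim A `pc_sim` whose requested drive is present.
#' @param drive `"input"` or `"prior"`.
#' @param max_lag_ms IRF support in ms.
#' @param per_trial Return one map per trial.
#' @return A list of `space_time_map`s (`per_trial = TRUE`) or a single map.
#' @export
irf_maps <- function(sim, drive = c("input", "prior"), max_lag_ms = 1000,
                     per_trial = TRUE) {
  drive <- match.arg(drive)
  stopifnot(inherits(sim, "pc_sim"))
  drv <- sim[[drive]]
  if (is.null(drv)) stop(sprintf("simulation has no `%s` drive", drive))
  L <- dim(sim$predictions)[1]
  per_level <- lapply(seq_len(L), function(l) {
    crosscorrelate(new_ts_set(sim$predictions[l, , , drop = TRUE] |>
                                matrix(nrow = dim(sim$predictions)[2]),
                              fs = sim$fs),
                   drv, max_lag_ms = max_lag_ms, keep_trials = per_trial)
  })
  if (per_trial) {
    n_trials <- dim(sim$predictions)[2]
    lapply(seq_len(n_trials), function(tr) {
      m <- do.call(rbind, lapply(per_level, function(ir) ir$per_trial[tr, ]))
      space_time_map(m, fs = sim$fs)
    })
  } else {
    space_time_map(do.call(rbind, lapply(per_level, `[[`, "values")),
                   fs = sim$fs)
  }
}
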