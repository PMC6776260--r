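#' Simulate the delayed predictive-coding network
#'
#' Integrates the N-level network by explicit forward Euler. Each level L
#' holds a prediction `y_L(t)`; the residual at its afferent side is
#'
#'   `x_L(t) = y_{L-1}(t) - y_L(t - db)`
#'
#' with `y_0(t)` the sensory input, and the prediction evolves as
#'
#'   `dy_L/dt = x_L(t - df) / tau + (y_{L+1}(t - db) - y_L(t)) / tau_d`
#'
#' with `y_{N+1}(t)` the top-down prior (zero when absent, in which case the
#' second term is a plain decay). `df` and `db` are the forward (residual)
#' and backward (prediction) transmission delays. All state is zero for
#' t <= 0. Updates are Jacobi-style — every residual and every prediction at
#' a step is computed from already-settled history — so results do not
#' depend on the order in which levels are visited.
#'
#' The first `burn_in_ms` of every trace (the zero-history transient) is
#' dropped from the returned traces together with the matching stretch of
#' the drives, so downstream statistics see stationary signals. Supply
#' drives that are `burn_in_ms` longer than the duration you want analysed,
#' or use [pc_run()] which arranges this.
#'
#' In sigmoid mode every prediction is squashed by [apply_nonlinearity()]
#' before being passed to the neighbouring level, and the drives are scaled
#' by `drive_scale`.
#'
#' @param config A [pc_config()].
#' @param input Sensory drive: a `ts_set` (trials x samples, sampling rate
#'   `config$fs`), or `NULL` for no input.
#' @param prior Top-level drive `y_{N+1}(t)`, same conventions as `input`.
#'   When both drives are present they must have identical shape.
#' @return A `pc_sim` object: list with `config`, `predictions` and
#'   `residuals` (arrays `n_levels x n_trials x n_samples`, burn-in
#'   removed), the trimmed `input` and `prior`, `fs`, and `time_s`.
#' @examples
#' cfg <- pc_config(n_levels = 2, delta_t = 12, tau = 17, tau_d = 200)
#' drv <- white_noise(2, 1.5, fs = 1000, seed = 1)
#' sim <- pc_simulate(cfg, input = drv)
#' dim(sim$predictions)
#' @export
pc_simulate <- function(config, input = NULL, prior = NULL) {
  stopifnot(inherits(config, "pc_config"))
  if (is.null(input) && is.null(prior)) {
    stop("at least one of `input` and `prior` must be supplied")
  }
  shape <- function(x) if (is.null(x)) NULL else dim(x)
  if (!is.null(input) && !is.null(prior)) {
    if (!identical(shape(input), shape(prior))) {
      stop("`input` and `prior` must have identical trial count and length")
    }
    if (!isTRUE(all.equal(attr(input, "fs"), attr(prior, "fs")))) {
      stop("`input` and `prior` must share a sampling rate")
    }
  }
  ref <- if (!is.null(input)) input else prior
  fs <- attr(ref, "fs")
  if (!isTRUE(all.equal(fs, config$fs))) {
    stop(sprintf("drive sampling rate (%g Hz) does not match 1000/dt (%g Hz)",
                 fs, config$fs))
  }
  n_trials <- nrow(ref)
  nt <- ncol(ref)
  L <- config$n_levels
  dt <- config$dt
  df <- config$delay_fwd_steps
  db <- config$delay_bwd_steps
  sigm <- config$nonlinearity == "sigmoid"

  zero <- matrix(0, n_trials, nt)
  inp <- if (is.null(input)) zero else unclass(input)
  pri <- if (is.null(prior)) zero else unclass(prior)
  if (sigm) {
    inp <- inp * config$drive_scale
    pri <- pri * config$drive_scale
  }

  # state arrays: level x trial x time
  Y <- array(0, dim = c(L, n_trials, nt))
  X <- array(0, dim = c(L, n_trials, nt))
  # Yt: transmitted predictions (squashed in sigmoid mode)
  guard <- config$overflow_guard
  zslice <- matrix(0, L, n_trials)

  y_at <- function(t) {
    if (t >= 1) matrix(Y[, , t], nrow = L) else zslice
  }
  yt_at <- if (sigm) {
    function(t) {
      if (t >= 1) apply_nonlinearity(config, matrix(Y[, , t], nrow = L))
      else zslice
    }
  } else {
    y_at
  }
  x_at <- function(t) {
    if (t >= 1) matrix(X[, , t], nrow = L) else zslice
  }

  for (t in seq_len(nt)) {
    y_now <- y_at(t)
    yt_db <- yt_at(t - db)
    yt_now <- yt_at(t)
    # residuals from the current, already-settled state
    below <- rbind(inp[, t, drop = FALSE] |> t(),
                   yt_now[-L, , drop = FALSE])
    X[, , t] <- below - yt_db
    if (t < nt) {
      x_df <- x_at(t - df)
      above <- rbind(yt_db[-1, , drop = FALSE],
                     if (t - db >= 1) t(pri[, t - db, drop = FALSE]) else
                       matrix(0, 1, n_trials))
      y_next <- y_now + dt * (x_df / config$tau + (above - y_now) / config$tau_d)
      if (anyNA(y_next) || max(abs(y_next)) > guard) {
        bad <- which(abs(y_next) > guard | is.na(y_next), arr.ind = TRUE)
        stop(sprintf(
          "simulation diverged at level %d, step %d (|y| > %g)",
          bad[1, 1], t + 1, guard))
      }
      Y[, , t + 1] <- y_next
    }
  }

  drop_n <- round(config$burn_in_ms / dt)
  keep <- if (drop_n >= nt) {
    stop("burn-in longer than the simulated duration")
  } else {
    (drop_n + 1):nt
  }
  trim <- function(m, was_null) {
    if (was_null) return(NULL)
    new_ts_set(m[, keep, drop = FALSE], fs = fs)
  }
  structure(
    list(
      config = config,
      predictions = Y[, , keep, drop = FALSE],
      residuals = X[, , keep, drop = FALSE],
      input = trim(if (sigm) inp / config$drive_scale else inp, is.null(input)),
      prior = trim(if (sigm) pri / config$drive_scale else pri, is.null(prior)),
      fs = fs,
      time_s = (keep - keep[1]) / fs
    ),
    class = "pc_sim"
  )
}

#' One-call white-noise-driven simulation
#'
#' Generates independent band-limited white-noise drives, prepends the
#' burn-in stretch, and runs [pc_simulate()], so that `duration_s` seconds
#' of transient-free traces come back. Input and prior streams, when both
#' requested, are statistically independent.
#'
#' @param config A [pc_config()].
#' @param drive Which drive(s) to apply: sensory `"input"`, top-down
#'   `"prior"`, or `"both"`.
#' @param n_trials Number of trials.
#' @param duration_s Analysed (post-burn-in) duration per trial in seconds.
#' @param seed Integer seed for the drives.
#' @param cutoff_hz Spectral cutoff of the drives (see [white_noise()]).
#' @return A `pc_sim` (see [pc_simulate()]).
#' @examples
#' sim <- pc_run(pc_config(n_levels = 2, tau = 17), "input",
#'               n_trials = 2, duration_s = 1, seed = 1)
#' @export
pc_run <- function(config,
                   drive = c("input", "prior", "both"),
                   n_trials = 200,
                   duration_s = 6,
                   seed = 1,
                   cutoff_hz = 80) {
  drive <- match.arg(drive)
  total_s <- duration_s + config$burn_in_ms / 1000
  gen <- function(s) white_noise(n_trials, total_s, fs = config$fs,
                                 cutoff_hz = cutoff_hz, seed = s)
  input <- if (drive %in% c("input", "both")) gen(seed) else NULL
  prior <- if (drive %in% c("prior", "both")) gen(seed + 1000003L) else NULL
  pc_simulate(config, input = input, prior = prior)
}

#' @export
print.pc_sim <- function(x, ...) {
  d <- dim(x$predictions)
  cat(sprintf("<pc_sim> %d levels x %d trials x %.3g s @ %g Hz (%s mode)\n",
              d[1], d[2], d[3] / x$fs, x$fs, x$config$nonlinearity))
  cat(sprintf("  drives: input=%s prior=%s\n",
              !is.null(x$input), !is.null(x$prior)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation into long form
#'
#' @param x A `pc_sim`.
#' @param ... Unused.
#' @return A tibble with columns `level`, `trial`, `time_s`, `prediction`,
#'   `residual`.
#' @exportS3Method generics::tidy
tidy.pc_sim <- function(x, ...) {
  d <- dim(x$predictions)
  tibble::tibble(
    level = rep(seq_len(d[1]), times = d[2] * d[3]),
    trial = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time_s = rep(x$time_s, each = d[1] * d[2]),
    prediction = as.vector(x$predictions),
    residual = as.vector(x$residuals)
  )
}

#' One-row summary of a simulation
#'
#' @param x A `pc_sim`.
#' @param ... Unused.
#' @return A one-row tibble with the configuration and the root-mean-square
#'   prediction amplitude per run.
#' @exportS3Method generics::glance
glance.pc_sim <- function(x, ...) {
  d <- dim(x$predictions)
  tibble::tibble(
    n_levels = d[1],
    n_trials = d[2],
    duration_s = d[3] / x$fs,
    delta_t = x$config$delta_t,
    tau = x$config$tau,
    tau_d = x$config$tau_d,
    nonlinearity = x$config$nonlinearity,
    rms_prediction = sqrt(mean(x$predictions^2))
  )
}

#' Extract the simulated EEG proxy
#'
#' The prediction signals `y_L` stacked low-to-high are the model's stand-in
#' for a posterior-to-anterior electrode line; the residuals give the same
#' picture up to a phase shift and are available via `what = "residuals"`.
#'
#' @param sim A `pc_sim`.
#' @param trial Trial index.
#' @param what `"predictions"` (default) or `"residuals"`.
#' @return A `space_time_map` (levels x time).
#' @export
sim_eeg <- function(sim, trial = 1, what = c("predictions", "residuals")) {
  what <- match.arg(what)
  stopifnot(inherits(sim, "pc_sim"))
  m <- sim[[what]][, trial, , drop = TRUE]
  space_time_map(matrix(m, nrow = dim(sim$predictions)[1]), fs = sim$fs)
}
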