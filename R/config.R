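#' Configure a hierarchical predictive-coding model
#'
#' Builds the parameter set for an N-level predictive-coding network in
#' which each level holds a prediction `y_L(t)` of the level below and the
#' levels exchange signals with a finite communication delay. Residuals
#' (prediction errors) travel up with the forward delay, predictions travel
#' down with the backward delay; by default the two are equal. The dynamics
#' are governed by three time constants: the communication delay `delta_t`,
#' the integration time constant `tau` weighting incoming residuals, and the
#' slower decay/prior time constant `tau_d` weighting the top-down term.
#'
#' `n_levels` counts *predictive* levels; the sensory stage holding the
#' input and the first residual is level 0. The classic two-area circuit —
#' one sensory area sending residuals to one predictive area, whose
#' delayed-feedback loop rings at a period of `8 * delta_t` — is therefore
#' `n_levels = 1`; the seven-level traveling-wave model is `n_levels = 7`.
#'
#' @param n_levels Number of predictive levels (>= 1).
#' @param delta_t Inter-level communication delay in ms. Must be an integer
#'   multiple of `dt`. Ignored when `delta_t_fwd`/`delta_t_bwd` are given.
#' @param tau Integration time constant in ms (> 0).
#' @param tau_d Decay / top-down time constant in ms. Values below `tau`
#'   imply faster dynamics at higher levels and are accepted with a warning.
#' @param dt Integration step in ms.
#' @param delta_t_fwd,delta_t_bwd Optional asymmetric delays (residuals up /
#'   predictions down). Oscillatory behaviour depends chiefly on their sum,
#'   so e.g. 16/8 ms behaves like symmetric 12 ms.
#' @param nonlinearity `"linear"` (default) or `"sigmoid"`. In sigmoid mode
#'   every signal exchanged between levels is squashed by a logistic
#'   function before use.
#' @param sigmoid_gain,sigmoid_offset Logistic parameters for sigmoid mode:
#'   `sigmoid(v) = 2 / (1 + exp(-gain * (v - offset))) - 1`, a monotone map
#'   of the real line onto (-1, 1) centred at `offset`.
#' @param drive_scale Multiplier applied to input and prior in sigmoid mode
#'   so that unit-variance drives span roughly the linear range of the
#'   squashing function.
#' @param overflow_guard Absolute bound on any prediction; exceeding it
#'   aborts the simulation with the offending level and step named.
#' @param burn_in_ms Length of the start-up transient, in ms, excluded from
#'   the returned traces (drives are generated this much longer so the
#'   analysed duration is unaffected).
#'
#' @return An object of class `pc_config` (a named list).
#' @examples
#' cfg <- pc_config(n_levels = 1, delta_t = 12, tau = 17)
#' cfg$delay_fwd_steps
#' @export
pc_config <- function(n_levels = 7,
                      delta_t = 12,
                      tau = 20,
                      tau_d = 200,
                      dt = 1,
                      delta_t_fwd = NULL,
                      delta_t_bwd = NULL,
                      nonlinearity = c("linear", "sigmoid"),
                      sigmoid_gain = 1,
                      sigmoid_offset = 0,
                      drive_scale = 3,
                      overflow_guard = 1e100,
                      burn_in_ms = 500) {
  nonlinearity <- match.arg(nonlinearity)
  stopifnot(n_levels >= 1, dt > 0, tau > 0, tau_d > 0, burn_in_ms >= 0)
  if (is.null(delta_t_fwd) != is.null(delta_t_bwd)) {
    stop("supply both `delta_t_fwd` and `delta_t_bwd`, or neither")
  }
  if (is.null(delta_t_fwd)) {
    delta_t_fwd <- delta_t
    delta_t_bwd <- delta_t
  } else {
    delta_t <- (delta_t_fwd + delta_t_bwd) / 2
  }
  steps_of <- function(d, name) {
    s <- d / dt
    if (abs(s - round(s)) > 1e-9) {
      stop(sprintf("`%s` (%g ms) is not an integer multiple of `dt` (%g ms)",
                   name, d, dt))
    }
    as.integer(round(s))
  }
  if (tau_d < tau) {
    warning("`tau_d` < `tau`: higher levels would evolve faster than lower ",
            "ones, which is physiologically implausible; proceeding anyway")
  }
  if (delta_t < 1 || delta_t > 50) {
    warning(sprintf("delay `delta_t` = %g ms is outside the plausible 1-50 ms range",
                    delta_t))
  }
  structure(
    list(
      n_levels = as.integer(n_levels),
      delta_t = delta_t,
      delta_t_fwd = delta_t_fwd,
      delta_t_bwd = delta_t_bwd,
      tau = tau,
      tau_d = tau_d,
      dt = dt,
      fs = 1000 / dt,
      delay_fwd_steps = steps_of(delta_t_fwd, "delta_t_fwd"),
      delay_bwd_steps = steps_of(delta_t_bwd, "delta_t_bwd"),
      nonlinearity = nonlinearity,
      sigmoid_gain = sigmoid_gain,
      sigmoid_offset = sigmoid_offset,
      drive_scale = drive_scale,
      overflow_guard = overflow_guard,
      burn_in_ms = burn_in_ms
    ),
    class = "pc_config"
  )
}

#' @export
print.pc_config <- function(x, ...) {
  cat(sprintf("<pc_config> %d levels, dt = %g ms\n", x$n_levels, x$dt))
  if (x$delta_t_fwd == x$delta_t_bwd) {
    cat(sprintf("  delay    : %g ms (symmetric)\n", x$delta_t))
  } else {
    cat(sprintf("  delay    : fwd %g / bwd %g ms\n", x$delta_t_fwd, x$delta_t_bwd))
  }
  cat(sprintf("  tau      : %g ms\n", x$tau))
  cat(sprintf("  tau_d    : %g ms\n", x$tau_d))
  cat(sprintf("  mode     : %s\n", x$nonlinearity))
  invisible(x)
}

#' Inter-level squashing function
#'
#' The nonlinearity applied to every signal exchanged between levels when a
#' model runs in sigmoid mode: a logistic squashed to (-1, 1), monotone
#' increasing, with midpoint value 0 at `value = sigmoid_offset`.
#'
#' @param config A [pc_config()] in sigmoid mode.
#' @param value Numeric vector (or matrix) of signal values.
#' @return Squashed values, same shape as `value`.
#' @examples
#' cfg <- pc_config(n_levels = 2, nonlinearity = "sigmoid")
#' apply_nonlinearity(cfg, 0)   # midpoint -> 0
#' @export
apply_nonlinearity <- function(config, value) {
  stopifnot(inherits(config, "pc_config"))
  if (config$nonlinearity != "sigmoid") {
    stop("`apply_nonlinearity()` is defined for sigmoid-mode configurations")
  }
  2 / (1 + exp(-config$sigmoid_gain * (value - config$sigmoid_offset))) - 1
}
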