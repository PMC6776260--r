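#' Oscillation frequency of the simplified two-level delay equation
#'
#' For a two-level network with the slow top-down term neglected, the
#' dynamics reduce to `dy/dt = -y(t - 2*DeltaT) / tau`. A purely oscillatory
#' solution `y = exp(i*omega*t)` requires `cos(2*omega*DeltaT) = 0`, whose
#' lowest-frequency branch gives a period of exactly `8 * DeltaT`: the loop
#' delay sets the rhythm. With delays of 10-15 ms this lands in the alpha
#' band.
#'
#' @param delta_t Communication delay in ms (> 0); vectorised.
#' @return Frequency in Hz, `1000 / (8 * delta_t)`.
#' @examples
#' oscillation_frequency(12)    # ~10.4 Hz
#' oscillation_frequency(12.5)  # 10 Hz exactly
#' @export
oscillation_frequency <- function(delta_t) {
  if (any(delta_t <= 0)) stop("`delta_t` must be positive")
  1000 / (8 * delta_t)
}

#' Integration time constant for neutral oscillation
#'
#' The imaginary part of the characteristic equation requires
#' `omega * tau = 1` on the pure-oscillation branch; combined with the
#' period-`8*DeltaT` condition this pins the integration time constant to
#' `tau = 8 * DeltaT / (2*pi) = (4/pi) * DeltaT ~ 1.2732 * DeltaT`. Above
#' this ratio the dominant mode is damped, below it it grows.
#'
#' @param delta_t Communication delay in ms (> 0); vectorised.
#' @return Optimal `tau` in ms.
#' @examples
#' optimal_tau(12)              # ~15.28 ms
#' optimal_tau(1)               # the dimensionless ratio, 4/pi
#' @export
optimal_tau <- function(delta_t) {
  if (any(delta_t <= 0)) stop("`delta_t` must be positive")
  8 * delta_t / (2 * pi)
}

#' Dominant roots of the delay-equation characteristic equation
#'
#' Solves `-alpha * tau = exp(-2 * alpha * DeltaT)` numerically for complex
#' exponents `alpha = a + i*omega` by Newton iteration from a grid of starts
#' covering the principal frequency branch `omega` in `(0, pi / (2*DeltaT)]`
#' (the lowest-frequency oscillatory branch) plus the real axis. Each root
#' is classified by the sign of its real part and the size of its imaginary
#' part: `"oscillatory-neutral"` (|Re| ~ 0, Im > 0), `"damped-oscillatory"`
#' (Re < 0, Im > 0), `"growing-oscillatory"` (Re > 0, Im > 0) or
#' `"non-oscillatory"` (real root).
#'
#' @param delta_t Communication delay in ms (> 0).
#' @param tau Integration time constant in ms (> 0).
#' @param n_starts Number of Newton starting points along the branch.
#' @param tol Convergence tolerance on `|f(alpha)|`.
#' @return A tibble with columns `alpha_real` (1/ms), `omega` (rad/ms),
#'   `frequency_hz`, `tau_over_deltat`, and `regime`, one row per distinct
#'   root found, sorted by `|Re(alpha)|`.
#' @examples
#' characteristic_roots(12, optimal_tau(12))  # neutral root at ~10.4 Hz
#' @export
characteristic_roots <- function(delta_t, tau, n_starts = 25, tol = 1e-12) {
  stopifnot(delta_t > 0, tau > 0)
  f <- function(a) a * tau + exp(-2 * a * delta_t)
  fp <- function(a) tau - 2 * delta_t * exp(-2 * a * delta_t)

  newton <- function(a) {
    for (i in 1:200) {
      step <- f(a) / fp(a)
      if (!is.finite(Mod(step))) return(NULL)
      a <- a - step
      if (Mod(f(a)) < tol) return(a)
    }
    NULL
  }

  # starts: principal oscillatory branch and the real axis
  om_max <- pi / (2 * delta_t)
  starts <- c(
    complex(real = 0, imaginary = seq(om_max / n_starts, om_max,
                                      length.out = n_starts)),
    complex(real = seq(-2 / tau, -1e-4 / tau, length.out = 8), imaginary = 0)
  )
  roots <- purrr::compact(purrr::map(starts, newton))
  if (length(roots) == 0) {
    stop(sprintf(
      "root search failed for delta_t = %g, tau = %g over Im(alpha) in (0, %g]",
      delta_t, tau, om_max))
  }
  a <- unlist(roots)
  # fold conjugates onto Im >= 0, deduplicate
  a <- complex(real = Re(a), imaginary = abs(Im(a)))
  a <- a[!duplicated(round(a, 9))]
  # keep the principal branch only
  a <- a[Im(a) <= om_max + 1e-9]

  re <- Re(a); im <- Im(a)
  eps <- 1e-8
  regime <- dplyr::case_when(
    im <= eps            ~ "non-oscillatory",
    abs(re) < eps        ~ "oscillatory-neutral",
    re < 0               ~ "damped-oscillatory",
    TRUE                 ~ "growing-oscillatory"
  )
  out <- tibble::tibble(
    alpha_real = re,
    omega = im,
    frequency_hz = 1000 * im / (2 * pi),
    tau_over_deltat = tau / delta_t,
    regime = regime
  )
  dplyr::arrange(out, abs(.data$alpha_real))
}

#' Delay ratio giving neutral oscillation, found numerically
#'
#' Independent numerical route to the optimal `tau / DeltaT` ratio: searches
#' for the `tau` at which the dominant oscillatory root of
#' [characteristic_roots()] crosses the imaginary axis, by bisection on the
#' sign of `Re(alpha)`.
#'
#' @param delta_t Communication delay in ms.
#' @param interval Search interval for `tau / delta_t`.
#' @param tol Bisection tolerance on the ratio.
#' @return The critical ratio `tau / delta_t` (dimensionless).
#' @examples
#' critical_tau_ratio(12)   # ~ 4 / pi
#' @export
critical_tau_ratio <- function(delta_t = 12, interval = c(0.5, 3),
                               tol = 1e-10) {
  dominant_re <- function(ratio) {
    r <- characteristic_roots(delta_t, ratio * delta_t)
    r <- dplyr::filter(r, .data$omega > 1e-8)
    if (nrow(r) == 0) stop("no oscillatory root in bracket")
    r$alpha_real[1]
  }
  # Re(alpha) decreases with tau: growing below the ratio, damped above
  stats::uniroot(dominant_re, interval = interval * 1, tol = tol,
                 extendInt = "no")$root
}
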