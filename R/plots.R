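#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot simulated traces
#'
#' Line plot of every level's prediction for one trial, stacked by level.
#'
#' @param object A `pc_sim`.
#' @param trial Trial to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pc_sim <- function(object, trial = 1, ...) {
  df <- tidy(object) |> dplyr::filter(.data$trial == !!trial)
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$prediction)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$level), scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "prediction y_L(t)") +
    ggplot2::theme_minimal()
}

#' Plot an impulse response function
#'
#' @param object A `pc_irf`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pc_irf <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$lag_ms, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ms)", y = "IRF (response per unit drive)") +
    ggplot2::theme_minimal()
}

#' Plot a channels-by-time map
#'
#' Raster of the map with rows z-scored for display (statistics elsewhere
#' are unaffected).
#'
#' @param object A `space_time_map`.
#' @param zscore_rows Equalize row scales for display.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.space_time_map <- function(object, zscore_rows = TRUE, ...) {
  m <- as.matrix(object)
  if (zscore_rows) {
    m <- m - rowMeans(m)
    s <- apply(m, 1, stats::sd)
    m[s > 0, ] <- m[s > 0, , drop = FALSE] / s[s > 0]
  }
  fs <- attr(object, "fs")
  df <- tibble::tibble(
    channel = rep(seq_len(nrow(m)), times = ncol(m)),
    time_s = rep((seq_len(ncol(m)) - 1) / fs, each = nrow(m)),
    value = as.vector(m)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$channel,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick") +
    ggplot2::labs(x = "time (s)", y = "channel (low → high)") +
    ggplot2::theme_minimal()
}

#' Plot real vs surrogate log-ratio distributions
#'
#' Overlaid densities of the observed and channel-shuffled log ratios, the
#' figure from which the significant-wave proportions are read.
#'
#' @param object A `wave_surrogate`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.wave_surrogate <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$log_ratio, linetype = .data$sample)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::labs(x = "log ratio (FW / BW)", y = "density",
                  subtitle = sprintf("FW %.1f%%, BW %.1f%%, KS D = %.3f",
                                     object$fw_significant_pct,
                                     object$bw_significant_pct,
                                     object$ks_d)) +
    ggplot2::theme_minimal()
}

#' Plot a parameter scan
#'
#' Tile map (two-parameter scans) of peak frequency or mean log ratio, or
#' line plots for the decay-constant scan.
#'
#' @param object A `pc_scan`.
#' @param fill For tile maps, the column to colour by (default: peak
#'   frequency for the two-level scan, mean log ratio for multilevel).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pc_scan <- function(object, fill = NULL, ...) {
  type <- attr(object, "scan_type")
  df <- tibble::as_tibble(object)
  if (startsWith(type, "tau_d")) {
    long <- tidyr::pivot_longer(
      df, c("mean_log_ratio", "mean_max_power", "mean_peak_frequency_hz"),
      names_to = "measure", values_to = "value")
    return(
      ggplot2::ggplot(long, ggplot2::aes(.data$tau_d, .data$value)) +
        ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
        ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
        ggplot2::labs(x = "tau_D (ms)") +
        ggplot2::theme_minimal()
    )
  }
  fill <- fill %||% if (type == "two_level") "peak_frequency_hz" else
    "mean_log_ratio"
  ggplot2::ggplot(df, ggplot2::aes(.data$delta_t, .data$tau,
                                   fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "delay (ms)", y = "tau (ms)") +
    ggplot2::theme_minimal()
}
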