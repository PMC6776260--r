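#' Ordered channels-by-time map
#'
#' The container the traveling-wave statistic consumes: a matrix with >= 2
#' ordered rows (hierarchical levels low-to-high, or a posterior-to-anterior
#' electrode line such as Oz...Fz) and time along the columns, plus the
#' sampling rate.
#'
#' @param data Numeric matrix, channels x time.
#' @param fs Sampling rate in Hz.
#' @param channels Optional character vector of row labels.
#' @param spec Optional record of the generating parameters.
#' @return A `space_time_map`.
#' @export
space_time_map <- function(data, fs, channels = NULL, spec = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("a space-time map needs at least 2 channels")
  if (!is.null(channels) && length(channels) != nrow(data)) {
    stop("`channels` must label every row")
  }
  structure(data, fs = fs, channels = channels, spec = spec,
            class = c("space_time_map", "matrix", "array"))
}

#' @export
print.space_time_map <- function(x, ...) {
  cat(sprintf("<space_time_map> %d channels x %d samples @ %g Hz\n",
              nrow(x), ncol(x), attr(x, "fs")))
  invisible(x)
}

#' Tile a recording into sliding-window maps
#'
#' Cuts a channels-by-time recording into overlapping windows (default 1 s
#' with 500 ms overlap), one `space_time_map` per window. A window equal to
#' the recording length yields exactly one map; a 6-s trial yields 11.
#'
#' @param x A `space_time_map` or channels x time matrix.
#' @param window_s Window length in seconds.
#' @param overlap_s Overlap between consecutive windows in seconds.
#' @param fs Sampling rate (taken from `x` when present).
#' @return A list of `space_time_map`s.
#' @examples
#' rec <- plane_wave_map(7, 6, 250, freq_hz = 10, spatial_freq = 1/7)
#' length(build_maps(rec))  # 11
#' @export
build_maps <- function(x, window_s = 1, overlap_s = 0.5, fs = NULL) {
  if (is.null(fs)) fs <- attr(x, "fs")
  if (is.null(fs)) stop("supply `fs` or a `space_time_map`")
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("fewer than 2 channels")
  w <- round(window_s * fs)
  stride <- round((window_s - overlap_s) * fs)
  if (w > ncol(x)) stop("window longer than the recording")
  if (stride < 1) stop("overlap must be smaller than the window")
  starts <- seq(1, ncol(x) - w + 1, by = stride)
  lapply(starts, function(s) {
    space_time_map(x[, s:(s + w - 1), drop = FALSE], fs = fs,
                   channels = attr(x, "channels"))
  })
}

#' Sliding-window maps for every trial of a simulation
#'
#' Stacks each trial's per-level predictions into a levels x time map and
#' tiles it with [build_maps()]; the pooled list over trials is what the
#' surrogate test consumes for the simulated-EEG path.
#'
#' @param sim A `pc_sim`.
#' @param window_s,overlap_s Window geometry in seconds.
#' @param what `"predictions"` (EEG proxy) or `"residuals"`.
#' @return A list of `space_time_map`s pooled over trials.
#' @export
eeg_maps <- function(sim, window_s = 1, overlap_s = 0.5,
                     what = c("predictions", "residuals")) {
  what <- match.arg(what)
  stopifnot(inherits(sim, "pc_sim"))
  n_trials <- dim(sim$predictions)[2]
  unlist(lapply(seq_len(n_trials), function(tr) {
    build_maps(sim_eeg(sim, trial = tr, what = what),
               window_s = window_s, overlap_s = overlap_s)
  }), recursive = FALSE)
}

# 2D amplitude spectrum bookkeeping shared by wave_stat().
# Rows of the FFT index spatial frequency ks = 0..C-1, columns temporal
# frequency. For a real map, a wave whose phase advances from low to high
# rows (forward) concentrates its positive-temporal-frequency energy in the
# "negative" spatial bins (rows C, C-1, ...); a backward wave in the
# positive bins (rows 2, 3, ...). The zero-spatial-frequency row (and the
# shared spatial Nyquist row for even C) belongs to both quadrants.
quadrant_rows <- function(C) {
  half <- floor((C - 1) / 2)
  shared <- c(1L, if (C %% 2 == 0) C / 2 + 1L)
  list(
    fw = c(shared, C + 1L - seq_len(half)),
    bw = c(shared, 1L + seq_len(half)),
    shared = shared
  )
}

#' Forward/backward quadrant statistic of a map
#'
#' The traveling-wave statistic: each row of the map is mean-centred, the 2D
#' FFT amplitude computed, and the maximum amplitude extracted separately
#' from the forward quadrant (energy of waves whose phase advances from low
#' to high rows) and the backward quadrant (the reverse). The statistic is
#' `log_ratio = log(max_FW / max_BW)`: positive for net forward, negative
#' for net backward propagation, and exactly zero for maps symmetric under
#' channel-order reversal (e.g. a standing wave, all rows in phase). The
#' zero-spatial-frequency row is included in both quadrants by default
#' (`include_midline = FALSE` drops it from both); the DC temporal column is
#' always excluded.
#'
#' Rows of very different amplitude (e.g. hierarchical levels of the model,
#' whose variance grows severalfold per level) would otherwise reduce the
#' statistic to the loudest rows; `normalize = "zscore"` rescales each row
#' to unit variance first, which is how maps built from model levels should
#' be analysed. `"center"` (mean removal only) is appropriate for
#' recordings whose channels already share a scale.
#'
#' @param map A `space_time_map` (or matrix plus `fs`).
#' @param fs Sampling rate, if `map` is a bare matrix.
#' @param include_midline Include the zero-spatial-frequency row in both
#'   quadrants.
#' @param normalize Per-row preprocessing: `"center"` or `"zscore"`.
#' @return A one-row tibble: `fw_power`, `bw_power`, `log_ratio`,
#'   `peak_freq_hz` and `peak_spatial_freq` (cycles/channel, magnitude) of
#'   the overall quadrant maximum, `peak_direction` (+1 forward, -1
#'   backward, 0 on the midline), and `degenerate` (TRUE for a constant
#'   map, whose maxima are numerically zero).
#' @examples
#' m <- plane_wave_map(7, 1, 500, freq_hz = 10, spatial_freq = 1/7)
#' wave_stat(m)$log_ratio > 0
#' @export
wave_stat <- function(map, fs = NULL, include_midline = TRUE,
                      normalize = c("center", "zscore")) {
  normalize <- match.arg(normalize)
  if (is.null(fs)) fs <- attr(map, "fs")
  if (is.null(fs)) stop("supply `fs` or a `space_time_map`")
  m <- as.matrix(map)
  C <- nrow(m)
  n <- ncol(m)
  m <- m - rowMeans(m)
  if (normalize == "zscore") {
    sds <- sqrt(rowSums(m^2) / (n - 1))
    live <- sds > 0
    m[live, ] <- m[live, , drop = FALSE] / sds[live]
  }
  A <- Mod(stats::fft(m))

  qr <- quadrant_rows(C)
  fw_rows <- qr$fw
  bw_rows <- qr$bw
  if (!include_midline) {
    fw_rows <- setdiff(fw_rows, qr$shared)
    bw_rows <- setdiff(bw_rows, qr$shared)
    if (length(fw_rows) == 0) stop("too few channels without the midline")
  }
  # positive temporal frequencies, DC column excluded
  tcols <- 2:(floor(n / 2) + 1)
  Afw <- A[fw_rows, tcols, drop = FALSE]
  Abw <- A[bw_rows, tcols, drop = FALSE]
  fw_power <- max(Afw)
  bw_power <- max(Abw)
  degenerate <- (fw_power == 0 && bw_power == 0)

  # overall quadrant maximum for peak coordinates
  if (fw_power >= bw_power) {
    idx <- which(Afw == fw_power, arr.ind = TRUE)[1, ]
    row <- fw_rows[idx[1]]; dir_sign <- 1
  } else {
    idx <- which(Abw == bw_power, arr.ind = TRUE)[1, ]
    row <- bw_rows[idx[1]]; dir_sign <- -1
  }
  ks <- row - 1L
  spat <- min(ks, C - ks) / C
  if (spat == 0) dir_sign <- 0
  tibble::tibble(
    fw_power = fw_power,
    bw_power = bw_power,
    log_ratio = if (degenerate) NA_real_ else log(fw_power / bw_power),
    peak_freq_hz = (tcols[idx[2]] - 1) * fs / n,
    peak_spatial_freq = spat,
    peak_direction = dir_sign,
    degenerate = degenerate
  )
}

#' @rdname wave_stat
#' @param maps A list of `space_time_map`s.
#' @param ... Passed to [wave_stat()].
#' @return `wave_stats()`: a tibble with one row per map plus a `map` index.
#' @export
wave_stats <- function(maps, ...) {
  dplyr::bind_rows(lapply(maps, wave_stat, ...), .id = "map") |>
    dplyr::mutate(map = as.integer(.data$map))
}

#' Channel-shuffle surrogate test for traveling waves
#'
#' Compares the observed per-map log ratios with a null distribution in
#' which the channel order carries no spatial structure: each null draw
#' applies a fresh random non-identity permutation to the rows of one of
#' the maps (assigned round-robin) and recomputes the log ratio. Real and
#' null samples are histogrammed on shared equal-width bins, and the summed
#' positive part of (real - null) density over positive-log-ratio bins
#' gives the proportion of forward-wave epochs beyond chance (negative bins:
#' backward). A two-sample Kolmogorov-Smirnov statistic between the samples
#' is reported alongside.
#'
#' An alternative per-epoch rule (`rule = "percentile"`) classifies each
#' map against the 5th/95th percentile of its own shuffle null; it is a
#' cross-check and costs `n_shuffles` FFTs per map.
#'
#' @param maps A list of `space_time_map`s (>= 1).
#' @param n_shuffles Total null draws (default 1000; >= 100 recommended).
#' @param seed Integer seed for the permutations.
#' @param n_bins Number of shared histogram bins.
#' @param rule `"histogram"` (default, the plotted-difference rule) or
#'   `"percentile"`.
#' @param include_midline,normalize Passed to [wave_stat()].
#' @return A `wave_surrogate`: list with `real` and `null` log-ratio
#'   samples, `fw_significant_pct`, `bw_significant_pct`, `ks_d`, `ks_p`,
#'   `n_shuffles`, and the histogram `bins`.
#' @examples
#' maps <- replicate(8, plane_wave_map(7, 1, 250, 10, 1/7, noise_sd = 0.5,
#'                                     seed = NULL), simplify = FALSE)
#' st <- surrogate_test(maps, n_shuffles = 200, seed = 1)
#' st$fw_significant_pct > st$bw_significant_pct
#' @export
surrogate_test <- function(maps, n_shuffles = 1000, seed = 1, n_bins = 50,
                           rule = c("histogram", "percentile"),
                           include_midline = TRUE,
                           normalize = c("center", "zscore")) {
  rule <- match.arg(rule)
  normalize <- match.arg(normalize)
  if (length(maps) < 1) stop("need at least one map")
  if (n_shuffles < 100) warning("fewer than 100 shuffles makes a noisy null")
  if (length(maps) < 10) {
    warning("few maps: the histogram-difference estimate will be unstable")
  }
  C <- nrow(maps[[1]])
  real <- vapply(maps, function(m) {
    wave_stat(m, include_midline = include_midline,
              normalize = normalize)$log_ratio
  }, numeric(1))

  set.seed(seed)
  rand_perm <- function() {
    repeat {
      p <- sample.int(C)
      if (!identical(p, seq_len(C))) return(p)
    }
  }
  shuffled_lr <- function(m) {
    wave_stat(space_time_map(as.matrix(m)[rand_perm(), , drop = FALSE],
                             fs = attr(m, "fs")),
              include_midline = include_midline,
              normalize = normalize)$log_ratio
  }

  if (rule == "percentile") {
    per_map_null <- lapply(maps, function(m) {
      vapply(seq_len(n_shuffles), function(i) shuffled_lr(m), numeric(1))
    })
    null <- unlist(per_map_null)
    lo <- vapply(per_map_null, stats::quantile, numeric(1), probs = 0.05)
    hi <- vapply(per_map_null, stats::quantile, numeric(1), probs = 0.95)
    fw_pct <- 100 * mean(real > hi)
    bw_pct <- 100 * mean(real < lo)
    bins <- NULL
  } else {
    which_map <- rep_len(seq_along(maps), n_shuffles)
    null <- vapply(which_map, function(j) shuffled_lr(maps[[j]]), numeric(1))
    rng <- range(c(real, null), finite = TRUE)
    if (diff(rng) == 0) rng <- rng + c(-1, 1) * 1e-6
    bins <- seq(rng[1], rng[2], length.out = n_bins + 1)
    centers <- (bins[-1] + bins[-length(bins)]) / 2
    hr <- graphics::hist(real, breaks = bins, plot = FALSE)$counts /
      length(real)
    hn <- graphics::hist(null, breaks = bins, plot = FALSE)$counts /
      length(null)
    excess <- pmax(hr - hn, 0)
    fw_pct <- 100 * sum(excess[centers > 0])
    bw_pct <- 100 * sum(excess[centers < 0])
  }

  ks <- suppressWarnings(stats::ks.test(real, null))
  structure(
    list(
      real = real,
      null = null,
      n_shuffles = n_shuffles,
      fw_significant_pct = fw_pct,
      bw_significant_pct = bw_pct,
      ks_d = unname(ks$statistic),
      ks_p = ks$p.value,
      rule = rule,
      bins = bins
    ),
    class = "wave_surrogate"
  )
}

#' @export
print.wave_surrogate <- function(x, ...) {
  cat(sprintf("<wave_surrogate> %d epochs vs %d null draws (%s rule)\n",
              length(x$real), length(x$null), x$rule))
  cat(sprintf("  FW significant: %.1f%%   BW significant: %.1f%%\n",
              x$fw_significant_pct, x$bw_significant_pct))
  cat(sprintf("  KS D = %.4f (p = %.3g)\n", x$ks_d, x$ks_p))
  invisible(x)
}

#' @rdname surrogate_test
#' @param x A `wave_surrogate`.
#' @exportS3Method generics::tidy
tidy.wave_surrogate <- function(x, ...) {
  tibble::tibble(
    sample = c(rep("real", length(x$real)), rep("null", length(x$null))),
    log_ratio = c(x$real, x$null)
  )
}

#' @rdname surrogate_test
#' @exportS3Method generics::glance
glance.wave_surrogate <- function(x, ...) {
  tibble::tibble(
    n_epochs = length(x$real),
    n_shuffles = x$n_shuffles,
    fw_significant_pct = x$fw_significant_pct,
    bw_significant_pct = x$bw_significant_pct,
    ks_d = x$ks_d,
    ks_p = x$ks_p
  )
}

#' Cortical source-mixing transform
#'
#' Emulates scalp-level blurring: each output channel is a distance-weighted
#' average of the input channels, with the default kernel giving weight 1 to
#' the channel itself, then 0.8, 0.6, 0.4 for neighbours one, two and three
#' steps away and 0 beyond. Weights falling off the edge are dropped and the
#' remainder renormalised, so the map keeps its shape. Mixing flattens the
#' spatial phase gradient, raising the apparent propagation speed, but
#' preserves the wave's direction.
#'
#' @param map A `space_time_map`.
#' @param weights Odd-length symmetric kernel, centre = own channel.
#' @return A `space_time_map` of the same dimensions.
#' @examples
#' m <- plane_wave_map(7, 1, 250, 10, 2/7)
#' mixed <- source_mixing(m)
#' sign(wave_stat(mixed)$log_ratio) == sign(wave_stat(m)$log_ratio)
#' @export
source_mixing <- function(map,
                          weights = c(0.4, 0.6, 0.8, 1, 0.8, 0.6, 0.4)) {
  m <- as.matrix(map)
  C <- nrow(m)
  k <- length(weights)
  if (k %% 2 == 0) stop("kernel length must be odd")
  if (k > 2 * C - 1) stop("kernel wider than 2*channels - 1")
  half <- (k - 1) / 2
  out <- matrix(0, C, ncol(m))
  for (c0 in seq_len(C)) {
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1 & idx <= C
    w <- weights[ok] / sum(weights[ok])
    out[c0, ] <- crossprod(w, m[idx[ok], , drop = FALSE])
  }
  space_time_map(out, fs = attr(map, "fs"), channels = attr(map, "channels"))
}

#' Traveling-wave propagation speed
#'
#' Converts the dominant off-axis 2D-spectral peak of a map to a physical
#' speed: `speed = (peak temporal frequency / peak spatial frequency) *
#' inter-channel distance`. With `off_axis = TRUE` (default) the peak is
#' sought among traveling components only — i.e. the zero-spatial-frequency
#' midline, which carries the standing (globally synchronous) part of the
#' signal and has no propagation speed, is ignored. This matters after
#' source mixing, which boosts the common component above the wave. With
#' `off_axis = FALSE` a map whose global peak sits on the midline is a
#' standing wave and returns `Inf` as the "no finite speed" marker.
#'
#' @param map A `space_time_map`, or a one-row tibble from [wave_stat()].
#' @param spacing_m Inter-channel distance in metres (0.02 for neighbouring
#'   cortical regions, ~0.04 for scalp electrodes).
#' @param off_axis Take the peak from the off-axis (traveling) part of the
#'   spectrum.
#' @param ... Passed to [wave_stat()] when `map` is a map.
#' @return Speed in m/s (`Inf` for a standing wave when
#'   `off_axis = FALSE`).
#' @examples
#' m <- plane_wave_map(7, 1, 500, freq_hz = 10, spatial_freq = 1/7)
#' wave_speed(m, 0.02)  # 10 / (1/7) * 0.02 = 1.4
#' @export
wave_speed <- function(map, spacing_m = 0.02, off_axis = TRUE, ...) {
  st <- if (inherits(map, "space_time_map") || is.matrix(map)) {
    wave_stat(map, include_midline = !off_axis, ...)
  } else {
    map
  }
  if (isTRUE(st$degenerate)) stop("constant map: no spectral peak")
  if (st$peak_spatial_freq == 0) return(Inf)
  st$peak_freq_hz / st$peak_spatial_freq * spacing_m
}

#' @rdname wave_speed
#' @param maps A list of `space_time_map`s.
#' @return `wave_speeds()`: a tibble with one row per map (`speed_m_s` is
#'   `Inf` for standing-wave peaks).
#' @export
wave_speeds <- function(maps, spacing_m = 0.02, off_axis = TRUE, ...) {
  st <- wave_stats(maps, include_midline = !off_axis, ...)
  dplyr::mutate(
    st,
    speed_m_s = ifelse(.data$peak_spatial_freq == 0, Inf,
                       .data$peak_freq_hz / .data$peak_spatial_freq *
                         spacing_m)
  )
}
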