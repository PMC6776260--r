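#' Standard electrode lines
#'
#' Channel orderings used for wave analysis of human recordings: the 7
#' midline electrodes posterior-to-anterior (the default line for
#' occipito-frontal waves) and the left-to-right central line used as a
#' lateral control.
#'
#' @param montage `"midline"` or `"central"`.
#' @return Character vector of channel labels in analysis order.
#' @examples
#' montage_channels("midline")
#' @export
montage_channels <- function(montage = c("midline", "central")) {
  montage <- match.arg(montage)
  switch(montage,
         midline = c("Oz", "POz", "Pz", "CPz", "Cz", "FCz", "Fz"),
         central = c("C5", "C3", "C1", "Cz", "C2", "C4", "C6"))
}

#' Write / read a channels-by-time recording
#'
#' Plain-text container for recordings and simulated maps: a comma-separated
#' matrix (one row per channel, no header) plus a JSON sidecar
#' (`<path>.json`) holding the sampling rate and channel labels, so the
#' files stay inspectable without special tooling. The round trip
#' reproduces the matrix exactly to double precision.
#'
#' @param x A `space_time_map` or channels x time matrix.
#' @param path Path of the data file (sidecar written alongside).
#' @param fs Sampling rate in Hz (taken from `x` when present).
#' @param channels Optional channel labels.
#' @return `write_recording()`: `path`, invisibly.
#' @export
write_recording <- function(x, path, fs = NULL, channels = NULL) {
  if (is.null(fs)) fs <- attr(x, "fs")
  if (is.null(fs)) stop("supply `fs`")
  channels <- channels %||% attr(x, "channels")
  m <- as.matrix(x)
  utils::write.table(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- list(fs = fs, n_channels = nrow(m), n_samples = ncol(m),
               channels = channels)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_recording
#' @return `read_recording()`: a `space_time_map`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop(sprintf("missing metadata sidecar: %s", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  space_time_map(m, fs = meta$fs,
                 channels = if (length(meta$channels)) meta$channels)
}

#' Load a recording and select an ordered electrode line
#'
#' Reads a stored recording and returns the rows named by the montage, in
#' montage order (e.g. Oz first, Fz last), matching labels
#' case-insensitively. A channel missing from the recording is an error
#' that names it and lists what is available.
#'
#' @param path Data file written by [write_recording()].
#' @param montage `"midline"`, `"central"`, `"all"`, or a character vector
#'   of channel labels in the desired order.
#' @return A `space_time_map` with rows in montage order.
#' @export
load_recording <- function(path, montage = "midline") {
  rec <- read_recording(path)
  if (identical(montage, "all")) return(rec)
  wanted <- if (length(montage) == 1 && montage %in% c("midline", "central")) {
    montage_channels(montage)
  } else {
    as.character(montage)
  }
  have <- attr(rec, "channels")
  if (is.null(have)) stop("recording has no channel labels; use montage = \"all\"")
  idx <- match(tolower(wanted), tolower(have))
  if (anyNA(idx)) {
    stop(sprintf("channel(s) %s not found; available: %s",
                 paste(wanted[is.na(idx)], collapse = ", "),
                 paste(have, collapse = ", ")))
  }
  space_time_map(as.matrix(rec)[idx, , drop = FALSE], fs = attr(rec, "fs"),
                 channels = have[idx])
}

#' Write a run manifest
#'
#' Records what produced a set of outputs — configuration, seed, package
#' version, paths, timestamp — as JSON, so a run can be reproduced
#' byte-for-byte from its manifest.
#'
#' @param path Output JSON path.
#' @param config A [pc_config()] (or any list of parameters).
#' @param seed The seed used.
#' @param inputs,outputs Character vectors of paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, config, seed, inputs = character(),
                           outputs = character()) {
  manifest <- list(
    package = "pcwaves",
    version = as.character(utils::packageVersion("pcwaves")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = unclass(config),
    inputs = inputs,
    outputs = outputs
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
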