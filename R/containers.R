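#' Continuous multichannel recording
#'
#' @param data numeric matrix, channels x samples (fT for magnetometers,
#'   fT/unit-baseline for gradiometers, uV for EEG).
#' @param fs_hz sampling rate.
#' @param layout a [sensor_layout] matching the rows of `data`.
#' @param events data frame of markers with at least a `sample` column
#'   (0-based sample index of the event onset); typical columns are
#'   `trial`, `target` (stimulated or gazed target id), `cued` (cued target
#'   id), `frequency_hz`, `phase_rad`.
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, fs_hz, layout, events = NULL) {
  data <- as.matrix(data)
  if (fs_hz <= 0) stop("fs_hz must be positive")
  if (nrow(data) != n_channels(layout))
    stop("data rows must match layout channels")
  if (is.null(events))
    events <- data.frame(sample = integer(0))
  if (nrow(events) > 0 &&
      (any(events$sample < 0) || any(events$sample >= ncol(data))))
    stop("event sample indices must lie within [0, samples)")
  structure(list(data = data, fs_hz = fs_hz, layout = layout,
                 events = events),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$fs_hz, nrow(x$events)))
  invisible(x)
}

#' Set of fixed-length epochs
#'
#' @param data numeric array, epochs x channels x samples.
#' @param fs_hz sampling rate.
#' @param t0_ms time of the first sample relative to event onset (ms).
#' @param labels data frame with one row per epoch (event metadata carried
#'   over from the parent recording).
#' @param layout the [sensor_layout] of the channel dimension.
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs_hz, t0_ms, labels, layout) {
  if (length(dim(data)) != 3) stop("data must be epochs x channels x samples")
  if (nrow(labels) != dim(data)[1])
    stop("labels must have one row per epoch")
  if (dim(data)[2] != n_channels(layout))
    stop("channel dimension must match layout")
  structure(list(data = data, fs_hz = fs_hz, t0_ms = t0_ms,
                 labels = labels, layout = layout),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples @ %g Hz (t0 = %g ms)\n",
              d[1], d[2], d[3], x$fs_hz, x$t0_ms))
  invisible(x)
}

#' Epoch time axis in milliseconds
#' @param ep an [epoch_set].
#' @return numeric vector of length `dim(ep$data)[3]`.
#' @export
epoch_times_ms <- function(ep) {
  ep$t0_ms + (seq_len(dim(ep$data)[3]) - 1) * 1000 / ep$fs_hz
}

#' Subset an epoch set
#'
#' @param ep an [epoch_set].
#' @param epochs integer or logical index over epochs (default all).
#' @param channels channel names or indices (default all).
#' @return An [epoch_set].
#' @export
subset_epochs <- function(ep, epochs = NULL, channels = NULL) {
  if (is.null(epochs)) epochs <- seq_len(dim(ep$data)[1])
  if (is.null(channels)) {
    ch <- seq_len(dim(ep$data)[2])
  } else if (is.character(channels)) {
    ch <- match(channels, ep$layout$channel_names)
    if (anyNA(ch)) stop("unknown channel(s): ",
                        paste(channels[is.na(ch)], collapse = ", "))
  } else ch <- channels
  lay <- sensor_layout(ep$layout$channel_names[ch], ep$layout$kinds[ch],
                       ep$layout$positions[ch, , drop = FALSE],
                       ep$layout$parents[ch])
  epoch_set(ep$data[epochs, ch, , drop = FALSE], ep$fs_hz, ep$t0_ms,
            ep$labels[epochs, , drop = FALSE], lay)
}

#' Write / read a recording as a plain-text bundle
#'
#' The native serialization is a directory holding `data.csv` (samples x
#' channels), `events.csv` and `meta.json` (sampling rate, channel names,
#' kinds, positions) -- portable and diffable.
#'
#' @param rec a [continuous_recording].
#' @param path directory to create/overwrite.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns the reconstructed [continuous_recording].
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dm <- t(rec$data)
  colnames(dm) <- rec$layout$channel_names
  utils::write.csv(dm, file.path(path, "data.csv"), row.names = FALSE)
  utils::write.csv(rec$events, file.path(path, "events.csv"),
                   row.names = FALSE)
  meta <- list(fs_hz = rec$fs_hz,
               channel_names = rec$layout$channel_names,
               kinds = rec$layout$kinds,
               positions = rec$layout$positions,
               parents = rec$layout$parents)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  parents <- lapply(seq_along(meta$channel_names), function(i) {
    p <- meta$parents[[i]]
    if (is.null(p) || all(is.na(p))) NA_character_ else as.character(p)
  })
  lay <- sensor_layout(meta$channel_names, meta$kinds,
                       matrix(meta$positions, ncol = 2), parents)
  dm <- utils::read.csv(file.path(path, "data.csv"), check.names = FALSE)
  ev <- utils::read.csv(file.path(path, "events.csv"))
  continuous_recording(t(as.matrix(dm)), meta$fs_hz, lay, ev)
}
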