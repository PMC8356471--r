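#' Sensor layout
#'
#' Describes a sensor array: channel names, channel kinds and 2-D scalp
#' positions (flattened head-surface coordinates, arbitrary units). Planar
#' gradiometer channels synthesized from magnetometer pairs carry the names
#' of their two parent magnetometers.
#'
#' @param channel_names character vector of unique channel identifiers.
#' @param kinds per-channel kind: `"magnetometer"`, `"gradiometer"` or
#'   `"eeg"`. Recycled if length 1.
#' @param positions numeric matrix (channels x 2) of scalp coordinates;
#'   by convention the first column runs left-right and the second
#'   posterior-anterior.
#' @param parents list of length-2 character vectors naming the parent
#'   magnetometers of each gradiometer channel (`NA` for other kinds).
#' @return An object of class `sensor_layout`: a data-frame-backed list with
#'   one row per channel.
#' @export
sensor_layout <- function(channel_names, kinds, positions, parents = NULL) {
  channel_names <- as.character(channel_names)
  if (anyDuplicated(channel_names))
    stop("channel names must be unique")
  n <- length(channel_names)
  kinds <- rep_len(match.arg(kinds, c("magnetometer", "gradiometer", "eeg"),
                             several.ok = TRUE), n)
  positions <- matrix(as.numeric(positions), ncol = 2)
  if (nrow(positions) != n || !all(is.finite(positions)))
    stop("positions must be a finite (channels x 2) matrix")
  if (is.null(parents)) parents <- rep(list(NA_character_), n)
  for (i in seq_len(n)) {
    if (kinds[i] == "gradiometer") {
      p <- parents[[i]]
      if (length(p) != 2 || anyNA(p))
        stop("gradiometer channel '", channel_names[i],
             "' must reference exactly two parent magnetometers")
    }
  }
  structure(list(channel_names = channel_names, kinds = kinds,
                 positions = positions, parents = parents),
            class = "sensor_layout")
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat("<sensor_layout> ", length(x$channel_names), " channels (",
      paste(sprintf("%d %s", table(x$kinds), names(table(x$kinds))),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}

n_channels <- function(layout) length(layout$channel_names)

#' Default posterior magnetometer grid
#'
#' A compact grid of magnetometers over the parieto-occipital scalp, the
#' region where motion-onset and steady-state visual responses peak. The
#' grid straddles the midline so that a tangential dipolar field pattern
#' produces a polarity reversal across neighbouring sensors.
#'
#' @param nx,ny grid extent (channels = nx * ny).
#' @param kind `"magnetometer"` (fT) or `"eeg"` (uV).
#' @return A [sensor_layout].
#' @export
default_sensor_layout <- function(nx = 3, ny = 3, kind = "magnetometer") {
  g <- expand.grid(x = seq(-1, 1, length.out = nx),
                   y = seq(-1.5, -0.5, length.out = ny))
  prefix <- if (kind == "eeg") "EEG" else "MEG"
  sensor_layout(sprintf("%s%02d", prefix, seq_len(nrow(g))),
                kind, as.matrix(g))
}

#' Frequency-phase target layout
#'
#' The 3 x 3 on-screen target grid of a frequency-phase coded SSVEP speller:
#' each target carries a unique (frequency, phase) pair, a grid position and
#' a display character.
#'
#' @param frequency_hz,phase_rad numeric vectors of length 9.
#' @param characters display characters (defaults to "1".."9").
#' @return An object of class `target_layout` (a data frame with columns
#'   `target`, `frequency_hz`, `phase_rad`, `row`, `col`, `character`).
#' @export
target_layout <- function(frequency_hz, phase_rad,
                          characters = as.character(1:9)) {
  if (length(frequency_hz) != 9 || length(phase_rad) != 9)
    stop("a target layout has exactly 9 targets")
  phase_rad <- phase_rad %% (2 * pi)
  if (anyDuplicated(paste(frequency_hz, round(phase_rad, 12))))
    stop("(frequency, phase) pairs must be unique")
  if (any(frequency_hz <= 0)) stop("frequencies must be positive")
  out <- data.frame(target = 1:9, frequency_hz = frequency_hz,
                    phase_rad = phase_rad,
                    row = rep(1:3, each = 3), col = rep(1:3, 3),
                    character = characters, stringsAsFactors = FALSE)
  class(out) <- c("target_layout", "data.frame")
  out
}

#' Default frequency-phase layout
#'
#' Three integer frequencies (8, 9, 10 Hz) crossed with three phases
#' (0, 2pi/3, 4pi/3), giving nine unique frequency-phase combinations.
#'
#' @return A [target_layout].
#' @export
default_target_layout <- function() {
  target_layout(frequency_hz = rep(c(8, 9, 10), each = 3),
                phase_rad = rep(c(0, 2 * pi / 3, 4 * pi / 3), 3))
}
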