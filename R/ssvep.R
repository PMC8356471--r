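## Frequency-domain SSVEP characterization: stereotypical two-period
## time-domain response, spectral SNR against neighbouring DFT bins, Fourier
## phase and circular dispersion.

## amplitude spectrum |DFT|/N; bin k (0-based) holds frequency k*fs/N
amplitude_spectrum <- function(x) Mod(stats::fft(x)) / length(x)

## 0-based on-bin index of f, erroring when f is off-bin
on_bin_index <- function(n, fs_hz, f_hz, tol = 1e-6) {
  k <- f_hz * n / fs_hz
  if (abs(k - round(k)) > tol)
    stop(sprintf("frequency %g Hz is not on a DFT bin (resolution %g Hz)",
                 f_hz, fs_hz / n))
  round(k)
}

#' Stereotypical steady-state response
#'
#' Average over all two-period 50%-overlap segments of all epochs labelled
#' with frequency `f_hz`, yielding the stereotyped oscillatory waveform in
#' the time domain, with optional pointwise 95% BCa confidence band over
#' segments.
#'
#' @param ep an [epoch_set] whose labels carry `frequency_hz` (epochs
#'   should be band-pass filtered, e.g. 4-40 Hz, beforehand).
#' @param f_hz gazed frequency.
#' @param ci,n_boot,level,seed confidence-band parameters.
#' @return An `evoked_response` spanning two periods of `f_hz`; `n_epochs`
#'   is the number of segments averaged.
#' @export
stereotypical_response <- function(ep, f_hz, ci = FALSE, n_boot = 1000,
                                   level = 0.95, seed = 1) {
  sel <- ep$labels$frequency_hz == f_hz
  if (!any(sel)) stop("no epochs labelled with frequency ", f_hz, " Hz")
  segs <- segment_two_periods(subset_epochs(ep, sel), f_hz)
  m <- apply(segs$data, c(2, 3), mean)
  lo <- hi <- NULL
  if (ci) {
    b <- pointwise_bca(segs$data, n_boot, level, seed)
    lo <- b$low; hi <- b$high
  }
  structure(list(mean = m, ci_low = lo, ci_high = hi,
                 n_epochs = dim(segs$data)[1], t0_ms = 0, fs_hz = ep$fs_hz,
                 condition = sprintf("%g Hz", f_hz), layout = ep$layout),
            class = "evoked_response")
}

#' Spectral SNR at the gazed frequency
#'
#' Amplitude of the DFT bin at `f_hz`, normalized by the average amplitude
#' of the `n_neighbours` bins on each side (the target bin excluded; the DC
#' and Nyquist bins are never used as neighbours). For a 4-s epoch the bin
#' resolution is 0.25 Hz, so integer frequencies are always on-bin;
#' off-bin frequencies raise an error rather than being interpolated.
#'
#' @param x numeric vector: one channel of one epoch.
#' @param fs_hz sampling rate.
#' @param f_hz gazed frequency (must be on a DFT bin).
#' @param n_neighbours bins per side.
#' @return list of class `spectral_snr`: `frequency_hz`, `amplitude`,
#'   `snr_ratio` (dimensionless, capped at 1e6 for a zero noise floor).
#' @export
spectral_snr <- function(x, fs_hz, f_hz, n_neighbours = 6) {
  n <- length(x)
  k <- on_bin_index(n, fs_hz, f_hz)
  amp <- amplitude_spectrum(x)
  nyq <- floor(n / 2)
  nb <- c((k - n_neighbours):(k - 1), (k + 1):(k + n_neighbours))
  nb <- nb[nb >= 1 & nb < nyq | (nb == nyq & n %% 2 == 1)]
  noise <- mean(amp[nb + 1])
  a <- amp[k + 1]
  if (noise <= a * 1e-6) {
    warning("zero noise floor; SNR capped at 1e6")
    ratio <- 1e6
  } else ratio <- a / noise
  structure(list(frequency_hz = f_hz, amplitude = a, snr_ratio = ratio),
            class = "spectral_snr")
}

#' Fourier phase at the gazed frequency
#'
#' Argument of the DFT coefficient at `f_hz`, cosine-reference convention at
#' epoch onset (a pure `cos(2*pi*f*t)` has phase 0, `sin` has phase -pi/2),
#' mapped to (-pi, pi].
#'
#' @inheritParams spectral_snr
#' @return phase in radians.
#' @export
phase_at <- function(x, fs_hz, f_hz) {
  k <- on_bin_index(length(x), fs_hz, f_hz)
  Arg(stats::fft(x)[k + 1])
}

#' Circular standard deviation
#'
#' `sqrt(-2 * ln(Rbar))` with `Rbar` the mean resultant length of the unit
#' phasors; 0 for identical phases, `Inf` when the phasors cancel exactly.
#'
#' @param phases angles in radians (>= 2 values).
#' @return dispersion in radians.
#' @export
circular_std <- function(phases) {
  if (length(phases) < 2) stop("need >= 2 phases")
  rbar <- Mod(mean(exp(1i * phases)))
  if (rbar < 1e-12) return(Inf)          # exact antipodal cancellation
  sqrt(-2 * log(rbar))
}

#' Per-epoch SSVEP feature table
#'
#' Convenience sweep of [spectral_snr] and [phase_at] over all epochs and
#' channels of a session at each epoch's own gazed frequency.
#'
#' @param ep an [epoch_set] with `frequency_hz` labels.
#' @param channels channel names or indices (default all).
#' @return data frame with columns `epoch`, `channel`, `frequency_hz`,
#'   `amplitude`, `snr_ratio`, `phase_rad`.
#' @export
ssvep_feature_table <- function(ep, channels = NULL) {
  d <- dim(ep$data)
  if (is.null(channels)) channels <- seq_len(d[2])
  if (is.character(channels))
    channels <- match(channels, ep$layout$channel_names)
  rows <- vector("list", d[1] * length(channels))
  k <- 1
  for (e in seq_len(d[1])) {
    f <- ep$labels$frequency_hz[e]
    for (c in channels) {
      x <- ep$data[e, c, ]
      s <- spectral_snr(x, ep$fs_hz, f)
      rows[[k]] <- data.frame(epoch = e,
                              channel = ep$layout$channel_names[c],
                              frequency_hz = f, amplitude = s$amplitude,
                              snr_ratio = s$snr_ratio,
                              phase_rad = phase_at(x, ep$fs_hz, f))
      k <- k + 1
    }
  }
  do.call(rbind, rows)
}
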