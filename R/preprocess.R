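## Deterministic preprocessing: zero-phase band-pass filtering, mastoid
## re-referencing, epoching, baselining, polyphase downsampling, planar
## gradiometer synthesis and two-period overlapping segmentation.
##
## Conventions: 0-based sample indices, half-open windows [start, end).

## forward-backward IIR pass with odd-reflection padding (>= 3x the filter
## polynomial length); symmetric inputs map to symmetric outputs.
filtfilt_padded <- function(b, a, x) {
  n <- length(x)
  npad <- min(n - 1, max(3 * max(length(a), length(b)), 100))
  if (npad < 3 * max(length(a), length(b)))
    stop("signal too short for zero-phase filtering")
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(npad + 1):(npad + n)]
}

apply_channelwise <- function(x, fun) {
  if (inherits(x, "continuous_recording")) {
    x$data <- t(apply(x$data, 1, fun))
    x
  } else if (inherits(x, "epoch_set")) {
    d <- dim(x$data)
    for (e in seq_len(d[1]))
      for (c in seq_len(d[2]))
        x$data[e, c, ] <- fun(x$data[e, c, ])
    x
  } else stop("x must be a continuous_recording or epoch_set")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (two-pass) Butterworth filtering per channel, so the
#' net magnitude response is the squared single-pass response and the phase
#' response is identically zero. Edges are handled by odd-reflection
#' padding.
#'
#' @param x a [continuous_recording] or [epoch_set].
#' @param low_hz,high_hz band edges (Hz); must satisfy
#'   `0 < low < high < fs/2`.
#' @param order filter order of the analog prototype (default 4).
#' @return Same type as `x`, filtered.
#' @export
bandpass_filter <- function(x, low_hz, high_hz, order = 4) {
  fs <- x$fs_hz
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  apply_channelwise(x, function(v) filtfilt_padded(bf$b, bf$a, v))
}

#' Re-reference EEG channels to the mastoid average
#'
#' Subtracts the mean of the two mastoid signals from every EEG channel;
#' magnetometer and gradiometer channels are reference-free and pass
#' through unchanged.
#'
#' @param rec a [continuous_recording].
#' @param left_name,right_name mastoid channel names (must be EEG).
#' @return A [continuous_recording].
#' @export
rereference_mastoids <- function(rec, left_name, right_name) {
  i <- match(c(left_name, right_name), rec$layout$channel_names)
  if (anyNA(i)) stop("mastoid channel not found")
  if (!all(rec$layout$kinds[i] == "eeg"))
    stop("mastoid channels must be EEG")
  ref <- 0.5 * (rec$data[i[1], ] + rec$data[i[2], ])
  eeg <- rec$layout$kinds == "eeg"
  rec$data[eeg, ] <- sweep(rec$data[eeg, , drop = FALSE], 2, ref)
  rec
}

#' Extract fixed-length epochs around events
#'
#' One epoch per selected event, spanning the half-open window
#' `[onset + tmin, onset + tmax)` in 0-based samples. Events whose window
#' would exceed the recording are skipped (their count is reported in a
#' message).
#'
#' @param rec a [continuous_recording].
#' @param tmin_ms,tmax_ms epoch window relative to event onset (ms).
#' @param event_filter optional predicate taking the event data frame and
#'   returning a logical vector of events to keep.
#' @return An [epoch_set]; labels are the selected event rows.
#' @export
extract_epochs <- function(rec, tmin_ms, tmax_ms, event_filter = NULL) {
  if (tmin_ms >= tmax_ms) stop("tmin must be < tmax")
  ev <- rec$events
  if (!is.null(event_filter)) ev <- ev[event_filter(ev), , drop = FALSE]
  fs <- rec$fs_hz
  s0 <- ev$sample + round(tmin_ms * fs / 1000)
  ns <- round(tmax_ms * fs / 1000) - round(tmin_ms * fs / 1000)
  ok <- s0 >= 0 & (s0 + ns) <= ncol(rec$data)
  if (sum(!ok) > 0)
    message(sum(!ok), " event(s) skipped: epoch window outside recording")
  ev <- ev[ok, , drop = FALSE]
  s0 <- s0[ok]
  if (nrow(ev) == 0) stop("no usable events")
  d <- array(0, c(nrow(ev), nrow(rec$data), ns))
  for (e in seq_len(nrow(ev)))
    d[e, , ] <- rec$data[, (s0[e] + 1):(s0[e] + ns), drop = FALSE]
  epoch_set(d, fs, round(tmin_ms * fs / 1000) * 1000 / fs, ev, rec$layout)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the baseline window
#' `[base_start_ms, base_end_ms)`; the baseline mean of the output is zero.
#'
#' @param ep an [epoch_set].
#' @param base_start_ms,base_end_ms baseline window relative to event onset.
#' @return An [epoch_set].
#' @export
baseline_correct <- function(ep, base_start_ms = -200, base_end_ms = 0) {
  t <- epoch_times_ms(ep)
  sel <- t >= base_start_ms & t < base_end_ms
  if (!any(sel) || base_start_ms < ep$t0_ms ||
      base_end_ms > t[length(t)] + 1000 / ep$fs_hz)
    stop("baseline window outside epoch")
  base <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
  ep$data <- ep$data - as.vector(base)      # recycles over samples
  ep
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

## windowed-sinc anti-alias FIR for rational resampling by p/q, with each
## polyphase branch normalized to unit DC gain
resample_kernel <- function(p, q) {
  N <- 2 * 10 * max(p, q)
  h <- signal::fir1(N, 1 / max(p, q))
  ph <- (seq_along(h) - 1) %% p
  for (b in 0:(p - 1)) h[ph == b] <- h[ph == b] / sum(h[ph == b])
  list(h = h, delay = N / 2, p = p, q = q,
       npad = ceiling((N / 2) / p) + 1)
}

## linear convolution via FFT on a 2-3-5-smooth padded length
fft_conv <- function(x, h) {
  nout <- length(x) + length(h) - 1
  nfft <- stats::nextn(nout, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - length(x))))
  H <- stats::fft(c(h, numeric(nfft - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(nout)] / nfft
}

## polyphase rational resampler with odd-reflection padding
resample_poly <- function(x, p, q, kern = NULL) {
  d <- gcd2(p, q); p <- p / d; q <- q / d
  if (p == 1 && q == 1) return(x)
  if (is.null(kern)) kern <- resample_kernel(p, q)
  n <- length(x)
  npad <- kern$npad
  if (npad + 1 > n) stop("signal too short to resample")
  xp <- c(2 * x[1] - x[(npad + 1):2], x, 2 * x[n] - x[(n - 1):(n - npad)])
  up <- numeric(length(xp) * p)
  up[seq(1, length(up), by = p)] <- xp
  yf <- fft_conv(up, kern$h)
  m <- floor(n * p / q)
  yf[kern$delay + npad * p + (0:(m - 1)) * q + 1]
}

#' Downsample epochs
#'
#' Anti-aliased polyphase resampling to a lower rate; the output has
#' `floor(n * fs_new / fs)` samples per epoch and band-limited content below
#' the new Nyquist is preserved to within a fraction of a percent.
#'
#' @param ep an [epoch_set].
#' @param fs_new target sampling rate (Hz), less than `ep$fs_hz`.
#' @return An [epoch_set] at `fs_new`.
#' @export
downsample <- function(ep, fs_new = 150) {
  fs <- ep$fs_hz
  if (fs_new >= fs) stop("fs_new must be < fs")
  r <- gcd2(round(fs_new * 1e6), round(fs * 1e6))
  p <- round(fs_new * 1e6) / r
  q <- round(fs * 1e6) / r
  d <- dim(ep$data)
  m <- floor(d[3] * p / q)
  kern <- resample_kernel(p, q)
  out <- array(0, c(d[1], d[2], m))
  for (e in seq_len(d[1]))
    for (c in seq_len(d[2]))
      out[e, c, ] <- resample_poly(ep$data[e, c, ], p, q, kern)
  epoch_set(out, fs_new, ep$t0_ms, ep$labels, ep$layout)
}

#' Synthesize planar gradiometer channels
#'
#' Each gradiometer is the difference of two magnetometer channels
#' (first minus second). Because a tangential dipole reverses polarity
#' across neighbouring on-scalp magnetometers, differencing adds the signal
#' coherently while averaging independent noise, boosting amplitude SNR by
#' about sqrt(2). With `pairs = "all"`, all k(k-1)/2 magnetometer pairs are
#' formed.
#'
#' @param ep an [epoch_set].
#' @param pairs list of length-2 character vectors of magnetometer names,
#'   or `"all"` for every pair.
#' @param keep_magnetometers if `TRUE` (default) the parent channels are
#'   retained alongside the new gradiometers.
#' @return An [epoch_set] extended with gradiometer channels named
#'   `"<first>-<second>"`.
#' @export
make_gradiometers <- function(ep, pairs = "all", keep_magnetometers = TRUE) {
  lay <- ep$layout
  mags <- lay$channel_names[lay$kinds == "magnetometer"]
  if (identical(pairs, "all")) {
    if (length(mags) < 2) stop("need >= 2 magnetometers")
    pairs <- utils::combn(mags, 2, simplify = FALSE)
  }
  idx <- lapply(pairs, function(p) {
    i <- match(p, lay$channel_names)
    if (anyNA(i)) stop("unknown channel(s): ",
                       paste(p[is.na(i)], collapse = ", "))
    if (!all(lay$kinds[i] == "magnetometer"))
      stop("gradiometer parents must be magnetometers")
    i
  })
  d <- dim(ep$data)
  gdata <- array(0, c(d[1], length(pairs), d[3]))
  gpos <- matrix(0, length(pairs), 2)
  gnames <- character(length(pairs))
  for (k in seq_along(pairs)) {
    i <- idx[[k]]
    gdata[, k, ] <- ep$data[, i[1], , drop = FALSE] -
      ep$data[, i[2], , drop = FALSE]
    gpos[k, ] <- colMeans(lay$positions[i, , drop = FALSE])
    gnames[k] <- paste(pairs[[k]], collapse = "-")
  }
  if (keep_magnetometers) {
    newdata <- array(0, c(d[1], d[2] + length(pairs), d[3]))
    newdata[, seq_len(d[2]), ] <- ep$data
    newdata[, d[2] + seq_along(pairs), ] <- gdata
    newlay <- sensor_layout(c(lay$channel_names, gnames),
                            c(lay$kinds, rep("gradiometer", length(pairs))),
                            rbind(lay$positions, gpos),
                            c(lay$parents, pairs))
  } else {
    newdata <- gdata
    newlay <- sensor_layout(gnames, "gradiometer", gpos, pairs)
  }
  epoch_set(newdata, ep$fs_hz, ep$t0_ms, ep$labels, newlay)
}

## 0-based segment start offsets within an epoch of `len` samples.
## Starts lie on the exact (fractional) step grid k * 2*(fs/f)*(1-overlap),
## each rounded to the nearest sample: rounding per start keeps the phase
## error bounded by half a sample instead of accumulating across segments
## when the period is not an integer number of samples -- accumulation
## would scramble the phase code that separates same-frequency targets.
segment_starts <- function(len, n, f_hz, fs_hz, overlap = 0.5,
                           discard_before_ms = 0) {
  if (len < n) return(integer(0))
  step <- 2 * (fs_hz / f_hz) * (1 - overlap)
  starts <- round(seq(0, len, by = step))
  starts <- starts[starts + n <= len]
  if (discard_before_ms > 0)
    starts <- starts[starts >= discard_before_ms * fs_hz / 1000]
  starts
}

#' Cut epochs into two-period overlapping segments
#'
#' Segments of length `n = round(2 * fs / f_hz)` samples (two cycles of the
#' gazed flicker frequency), starting on the exact one-period grid
#' `k * 2 * (fs/f) * (1 - overlap)` rounded per start; a trailing partial
#' segment is dropped. Real-time spelling discards the segments starting
#' before `discard_before_ms` to skip the onset transient.
#'
#' @param ep an [epoch_set].
#' @param f_hz gazed frequency (Hz).
#' @param overlap fractional overlap between consecutive segments.
#' @param discard_before_ms drop segments starting before this time (ms from
#'   epoch start).
#' @return A list of class `segment_set`: `data` (segments x channels x n),
#'   `source_frequency_hz`, `n`, `fs_hz`, `epoch_id` (parent epoch of each
#'   segment), `layout`.
#' @export
segment_two_periods <- function(ep, f_hz, overlap = 0.5,
                                discard_before_ms = 0) {
  fs <- ep$fs_hz
  n <- round(2 * fs / f_hz)
  d <- dim(ep$data)
  if (d[3] < n) stop("epoch shorter than two periods (", n, " samples)")
  starts <- segment_starts(d[3], n, f_hz, fs, overlap, discard_before_ms)
  if (length(starts) == 0) stop("no segments after discard rule")
  nseg <- length(starts) * d[1]
  out <- array(0, c(nseg, d[2], n))
  eid <- integer(nseg)
  k <- 1
  for (e in seq_len(d[1])) {
    for (s in starts) {
      out[k, , ] <- ep$data[e, , (s + 1):(s + n)]
      eid[k] <- e
      k <- k + 1
    }
  }
  structure(list(data = out, source_frequency_hz = f_hz, n = n, fs_hz = fs,
                 epoch_id = eid, layout = ep$layout),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments x %d channels x %d samples (two periods of %g Hz)\n",
              dim(x$data)[1], dim(x$data)[2], x$n, x$source_frequency_hz))
  invisible(x)
}
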