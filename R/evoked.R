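## Evoked-response characterization: target/non-target averaging, BCa
## bootstrap confidence intervals, component peak/latency estimation and
## component SNR in dB.

#' BCa bootstrap confidence interval
#'
#' Bias-corrected and accelerated interval for an arbitrary statistic: the
#' bias correction z0 comes from the fraction of the bootstrap distribution
#' below the point estimate, the acceleration from the jackknife skewness.
#' All-identical bootstrap replicates yield a zero-width interval.
#'
#' @param samples a vector, or a matrix/data frame resampled by rows.
#' @param statistic function mapping a resample to a scalar.
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed RNG seed for the resampling.
#' @return Named numeric vector `c(low, high)`.
#' @export
bca_bootstrap_ci <- function(samples, statistic = mean, n_boot = 1000,
                             level = 0.95, seed = 1) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1)
  n <- nrow(samples)
  if (n < 2) stop("need >= 2 samples")
  take <- function(i) {
    s <- samples[i, , drop = FALSE]
    statistic(if (ncol(samples) == 1) s[, 1] else s)
  }
  t0 <- take(seq_len(n))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot),
                  function(b) take(sample.int(n, replace = TRUE)),
                  numeric(1))
  if (all(boots == t0)) return(c(low = t0, high = t0))
  z0 <- stats::qnorm((sum(boots < t0) + 0.5 * sum(boots == t0)) / n_boot)
  jack <- vapply(seq_len(n), function(i) take(seq_len(n)[-i]), numeric(1))
  dj <- mean(jack) - jack
  denom <- 6 * sum(dj^2)^1.5
  a <- if (denom > 0) sum(dj^3) / denom else 0
  zal <- stats::qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
  adj <- stats::pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
  ci <- unname(stats::quantile(boots, adj, type = 6, names = FALSE))
  c(low = ci[1], high = ci[2])
}

#' Average evoked response
#'
#' Sample-wise mean over epochs matching a condition, with optional
#' pointwise 95% BCa bootstrap confidence band. For motion-onset sessions
#' the `"target"` condition selects epochs whose stimulated cross equals the
#' cued cross, `"non-target"` the rest.
#'
#' @param ep an [epoch_set].
#' @param condition `"target"`, `"non-target"`, `"all"`, or a predicate on
#'   `ep$labels`.
#' @param ci compute the pointwise confidence band (vectorized BCa over all
#'   channel/time points).
#' @param n_boot,level,seed bootstrap parameters.
#' @return An object of class `evoked_response`: `mean` (channels x
#'   samples), `ci_low`/`ci_high` (or NULL), `n_epochs`, `t0_ms`, `fs_hz`,
#'   `condition`, `layout`.
#' @export
average_evoked <- function(ep, condition = "target", ci = FALSE,
                           n_boot = 1000, level = 0.95, seed = 1) {
  sel <- condition_index(ep, condition)
  if (!any(sel)) stop("no epochs match the condition")
  x <- ep$data[sel, , , drop = FALSE]
  m <- apply(x, c(2, 3), mean)
  lo <- hi <- NULL
  if (ci) {
    b <- pointwise_bca(x, n_boot, level, seed)
    lo <- b$low; hi <- b$high
  }
  structure(list(mean = m, ci_low = lo, ci_high = hi,
                 n_epochs = sum(sel), t0_ms = ep$t0_ms, fs_hz = ep$fs_hz,
                 condition = if (is.character(condition)) condition else
                   "custom",
                 layout = ep$layout),
            class = "evoked_response")
}

condition_index <- function(ep, condition) {
  if (is.function(condition)) return(condition(ep$labels))
  switch(condition,
         target = ep$labels$target == ep$labels$cued,
         `non-target` = ep$labels$target != ep$labels$cued,
         all = rep(TRUE, nrow(ep$labels)),
         stop("unknown condition: ", condition))
}

## vectorized pointwise BCa over all (channel, sample) cells of an
## epochs x channels x samples array, statistic = mean over epochs
pointwise_bca <- function(x, n_boot = 1000, level = 0.95, seed = 1) {
  n <- dim(x)[1]
  xm <- matrix(x, nrow = n)                 # n x (channels*samples)
  t0 <- colMeans(xm)
  set.seed(seed)
  counts <- matrix(0, n_boot, n)
  for (b in seq_len(n_boot)) {
    tb <- tabulate(sample.int(n, replace = TRUE), n)
    counts[b, ] <- tb
  }
  boots <- (counts %*% xm) / n              # n_boot x cells
  z0 <- stats::qnorm((colSums(sweep(boots, 2, t0, "<")) +
                        0.5 * colSums(sweep(boots, 2, t0, "=="))) / n_boot)
  ## jackknife means: (sum - x_i) / (n-1); acceleration per cell
  s <- colSums(xm)
  jack_dev <- (matrix(s, n, length(s), byrow = TRUE) - xm) / (n - 1)
  dj <- sweep(-jack_dev, 2, colMeans(jack_dev), "+")
  denom <- 6 * colSums(dj^2)^1.5
  a <- ifelse(denom > 0, colSums(dj^3) / denom, 0)
  zal <- stats::qnorm(c((1 - level) / 2, 1 - (1 - level) / 2))
  qlo <- qhi <- numeric(length(t0))
  for (j in seq_along(t0)) {
    if (!is.finite(z0[j])) { qlo[j] <- qhi[j] <- t0[j]; next }
    adj <- stats::pnorm(z0[j] + (z0[j] + zal) / (1 - a[j] * (z0[j] + zal)))
    q <- stats::quantile(boots[, j], adj, type = 6, names = FALSE)
    qlo[j] <- q[1]; qhi[j] <- q[2]
  }
  d <- dim(x)[2:3]
  list(low = matrix(qlo, d[1], d[2]), high = matrix(qhi, d[1], d[2]))
}

#' @export
print.evoked_response <- function(x, ...) {
  cat(sprintf("<evoked_response> '%s': %d channels x %d samples @ %g Hz, n = %d epochs%s\n",
              x$condition, nrow(x$mean), ncol(x$mean), x$fs_hz, x$n_epochs,
              if (is.null(x$ci_low)) "" else ", with 95% CI"))
  invisible(x)
}

#' @export
plot.evoked_response <- function(x, channel = NULL, ...) {
  t <- x$t0_ms + (seq_len(ncol(x$mean)) - 1) * 1000 / x$fs_hz
  if (is.null(channel)) {
    graphics::matplot(t, t(x$mean), type = "l", lty = 1,
                      xlab = "time (ms)", ylab = "amplitude", ...)
  } else {
    i <- if (is.character(channel))
      match(channel, x$layout$channel_names) else channel
    graphics::plot(t, x$mean[i, ], type = "l", xlab = "time (ms)",
                   ylab = "amplitude",
                   main = x$layout$channel_names[i], ...)
    if (!is.null(x$ci_low)) {
      graphics::lines(t, x$ci_low[i, ], lty = 2)
      graphics::lines(t, x$ci_high[i, ], lty = 2)
    }
  }
  invisible(x)
}

#' Locate an evoked component peak
#'
#' Finds the extreme value of the requested polarity across all channels
#' within a latency window of the evoked mean. When the underlying epochs
#' are supplied, 95% BCa bootstrap confidence intervals for amplitude and
#' latency are computed by resampling epochs and re-running the peak search
#' on each resampled average.
#'
#' @param ev an [evoked_response].
#' @param window_ms length-2 latency search window (ms).
#' @param polarity `"negative"`, `"positive"` or `"absolute"`.
#' @param epochs optional [epoch_set] (same condition) for bootstrap CIs.
#' @param condition condition used to select epochs (as in
#'   [average_evoked]).
#' @param n_boot,seed bootstrap parameters.
#' @return list of class `component_stats`: `channel`, `peak_amplitude`,
#'   `latency_ms`, optional `latency_ci`, `amplitude_ci`, and `window_ms`.
#' @export
find_peak <- function(ev, window_ms, polarity = c("negative", "positive",
                                                  "absolute"),
                      epochs = NULL, condition = "target", n_boot = 1000,
                      seed = 1) {
  polarity <- match.arg(polarity)
  t <- ev$t0_ms + (seq_len(ncol(ev$mean)) - 1) * 1000 / ev$fs_hz
  sel <- which(t >= window_ms[1] & t <= window_ms[2])
  if (length(sel) == 0) stop("empty search window")
  peak_of <- function(m) {
    w <- m[, sel, drop = FALSE]
    v <- switch(polarity, negative = -w, positive = w, absolute = abs(w))
    i <- arrayInd(which.max(v), dim(v))
    c(channel = i[1], latency = t[sel[i[2]]], amplitude = w[i[1], i[2]])
  }
  pk <- peak_of(ev$mean)
  out <- list(channel = ev$layout$channel_names[pk["channel"]],
              peak_amplitude = unname(pk["amplitude"]),
              latency_ms = unname(pk["latency"]),
              window_ms = window_ms)
  if (!is.null(epochs)) {
    x <- epochs$data[condition_index(epochs, condition), , , drop = FALSE]
    n <- dim(x)[1]
    xm <- matrix(x, nrow = n)
    stat <- function(rows) {
      m <- matrix(colMeans(matrix(xm[rows, ], nrow = length(rows))),
                  dim(x)[2], dim(x)[3])
      peak_of(m)
    }
    idx <- matrix(seq_len(n), ncol = 1)
    out$latency_ci <- bca_bootstrap_ci(idx, function(i) stat(i)["latency"],
                                       n_boot = n_boot, seed = seed)
    out$amplitude_ci <- bca_bootstrap_ci(idx,
                                         function(i) stat(i)["amplitude"],
                                         n_boot = n_boot, seed = seed)
  }
  class(out) <- "component_stats"
  out
}

#' @export
print.component_stats <- function(x, ...) {
  cat(sprintf("<component_stats> peak %.2f at %g ms on %s (window %g-%g ms)\n",
              x$peak_amplitude, x$latency_ms, x$channel,
              x$window_ms[1], x$window_ms[2]))
  if (!is.null(x$latency_ci))
    cat(sprintf("  latency 95%% CI [%g, %g] ms; amplitude 95%% CI [%.2f, %.2f]\n",
                x$latency_ci[1], x$latency_ci[2],
                x$amplitude_ci[1], x$amplitude_ci[2]))
  invisible(x)
}

#' Component SNR in dB
#'
#' Ratio, in dB, of the evoked mean's power (mean squared amplitude) in a
#' window centred on the component peak to its power in the pre-onset
#' baseline window: `10 * log10(P_window / P_baseline)`. The confidence
#' interval uses the percentile bootstrap over epochs.
#'
#' @param ep an [epoch_set] (epochs of the condition of interest).
#' @param channel channel name or index.
#' @param peak_latency_ms component peak latency (ms).
#' @param window_ms width of the window of interest centred at the peak.
#' @param baseline_ms length-2 baseline window (ms).
#' @param n_boot,level,seed percentile-bootstrap parameters.
#' @return list of class `component_snr`: `snr_db`, `ci`, `channel`,
#'   `window_ms`.
#' @export
component_snr_db <- function(ep, channel, peak_latency_ms, window_ms = 100,
                             baseline_ms = c(-200, 0), n_boot = 1000,
                             level = 0.95, seed = 1) {
  i <- if (is.character(channel))
    match(channel, ep$layout$channel_names) else channel
  if (is.na(i)) stop("unknown channel")
  t <- epoch_times_ms(ep)
  wsel <- t >= peak_latency_ms - window_ms / 2 &
    t < peak_latency_ms + window_ms / 2
  bsel <- t >= baseline_ms[1] & t < baseline_ms[2]
  if (!any(wsel) || !any(bsel)) stop("window outside epoch")
  x <- ep$data[, i, , drop = TRUE]          # epochs x samples
  snr_of <- function(rows) {
    m <- colMeans(x[rows, , drop = FALSE])
    pb <- mean(m[bsel]^2)
    if (pb == 0) {
      warning("zero baseline power; SNR is +Inf")
      return(Inf)
    }
    10 * log10(mean(m[wsel]^2) / pb)
  }
  n <- nrow(x)
  snr <- snr_of(seq_len(n))
  set.seed(seed)
  boots <- vapply(seq_len(n_boot),
                  function(b) snr_of(sample.int(n, replace = TRUE)),
                  numeric(1))
  ci <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(list(snr_db = snr, ci = c(low = ci[1], high = ci[2]),
                 channel = ep$layout$channel_names[i],
                 window_ms = peak_latency_ms + c(-1, 1) * window_ms / 2),
            class = "component_snr")
}

#' @export
print.component_snr <- function(x, ...) {
  cat(sprintf("<component_snr> %s: %.2f dB (95%% CI [%.2f, %.2f])\n",
              x$channel, x$snr_db, x$ci[1], x$ci[2]))
  invisible(x)
}
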