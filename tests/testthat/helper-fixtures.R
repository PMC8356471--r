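# Shared fixtures and independent oracles. Generated sessions are cached so
# several test files can reuse the same (deterministic) recording.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

tiny_layout <- function(n = 1, kind = "magnetometer") {
  sensor_layout(sprintf("CH%02d", seq_len(n)), kind,
                cbind(seq(-1, 1, length.out = max(n, 2))[seq_len(n)], -1))
}

# single-channel epoch set from a samples vector (or epochs x samples matrix)
toy_epochs <- function(x, fs = 150, t0_ms = 0, labels = NULL, n_channels = 1) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  d <- array(0, c(nrow(x), n_channels, ncol(x)))
  for (c in seq_len(n_channels)) d[, c, ] <- x
  if (is.null(labels)) labels <- data.frame(trial = seq_len(nrow(x)))
  epoch_set(d, fs, t0_ms, labels, tiny_layout(n_channels))
}

# 9-target frequency-phase epochs built directly at 150 Hz: per trial a pure
# (frequency, phase) sinusoid through a fixed gain map plus white noise.
# Fast stand-in for a full generated+preprocessed training session.
synth_fp_epochs <- function(n_per_target = 4, amplitude = 5, sigma = 1,
                            fs = 150, dur_s = 4, n_ch = 3, seed = 1,
                            layout = default_target_layout()) {
  set.seed(seed)
  ns <- round(dur_s * fs)
  tg <- rep(1:9, n_per_target)
  gain <- seq(1, 0.4, length.out = n_ch)
  d <- array(stats::rnorm(length(tg) * n_ch * ns, 0, sigma),
             c(length(tg), n_ch, ns))
  t <- (seq_len(ns) - 1) / fs
  for (e in seq_along(tg)) {
    f <- layout$frequency_hz[tg[e]]
    s <- amplitude * sin(2 * pi * f * t + layout$phase_rad[tg[e]])
    for (c in seq_len(n_ch)) d[e, c, ] <- d[e, c, ] + gain[c] * s
  }
  epoch_set(d, fs, 0,
            data.frame(trial = seq_along(tg), target = tg,
                       frequency_hz = layout$frequency_hz[tg],
                       phase_rad = layout$phase_rad[tg]),
            tiny_layout(n_ch))
}

# default 45-trial motion-onset session, filtered 0.5-15 Hz and epoched,
# shared across evoked/decoder tests
cached_erp_epochs <- function() {
  cached("erp_epochs", {
    rec <- generate_erp_session(erp_session_config(seed = 42),
                                default_sensor_layout())
    rec <- bandpass_filter(rec, 0.5, 15)
    baseline_correct(extract_epochs(rec, -200, 600))
  })
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); oracle-side only
rvonmises <- function(n, mu, kappa) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1
    }
  }
  ifelse(out > pi, out - 2 * pi, out)
}

# brute-force constrained-minimum-variance oracle: minimize w' S w subject
# to a.w = 1 by BFGS over the null-space parameterization w = w0 + Z t
lcmv_oracle <- function(a, S) {
  p <- length(a)
  w0 <- a / sum(a * a)
  Z <- qr.Q(qr(cbind(a, diag(p))))[, 2:p, drop = FALSE]   # null space of a
  obj <- function(t) { w <- w0 + drop(Z %*% t); sum(w * (S %*% w)) }
  grd <- function(t) { w <- w0 + drop(Z %*% t); drop(2 * t(Z) %*% (S %*% w)) }
  opt <- stats::optim(rep(0, p - 1), obj, grd, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
  w0 + drop(Z %*% opt$par)
}

# two-pass amplitude response of the analog-prototype Butterworth band-pass
# (order N): |H(f)|^2 with |H|^2 = 1 / (1 + Omega^(2N))
butter_bandpass_gain2 <- function(f, low, high, order = 4) {
  w <- 2 * pi * f; wl <- 2 * pi * low; wh <- 2 * pi * high
  omega <- (w^2 - wl * wh) / (w * (wh - wl))
  1 / (1 + omega^(2 * order))
}

# steady-state amplitude of a sinusoid at frequency f in the central part of
# a signal, via single-bin projection over an integer number of cycles
mid_amplitude <- function(x, f, fs) {
  n <- length(x)
  ncyc <- floor(n / 2 * f / fs)
  len <- round(ncyc * fs / f)
  i0 <- floor((n - len) / 2)
  t <- (i0:(i0 + len - 1)) / fs
  seg <- x[(i0 + 1):(i0 + len)]
  2 * Mod(mean(seg * exp(-2i * pi * f * t)))
}
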