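## Synthetic OPM-MEG / EEG session generator.
##
## Emulates the two stimulation paradigms the decoding pipeline targets:
## motion-onset evoked sessions (dipolar N/M200 and P/M300 components over
## the parieto-occipital and centro-parietal scalp) and frequency(-phase)
## coded SSVEP sessions. Everything is seeded and statistically controlled
## so that downstream stages are testable without real recordings.

#' Block-design pseudorandom schedule
#'
#' Repetition scheme in which every contiguous block of `n_items`
#' presentations is a random permutation of all items, so each item occurs
#' exactly once per block.
#'
#' @param n_items number of conditions.
#' @param reps number of blocks.
#' @return Integer vector of length `n_items * reps`.
#' @export
block_schedule <- function(n_items, reps) {
  if (reps < 1) stop("reps must be >= 1")
  unlist(lapply(seq_len(reps), function(i) sample.int(n_items)))
}

#' Training-session cue schedule
#'
#' Cue order for a frequency-phase speller training session: each of the 9
#' targets is cued `reps` times in pseudorandom block design.
#'
#' @param layout a [target_layout].
#' @param reps cues per target (8 in a standard training session, giving 72
#'   trials).
#' @param seed RNG seed.
#' @return Data frame with columns `trial` and `target`.
#' @export
generate_training_schedule <- function(layout, reps = 8, seed = 1) {
  set.seed(seed)
  tg <- block_schedule(nrow(layout), reps)
  data.frame(trial = seq_along(tg), target = tg)
}

#' Mixed white + 1/f Gaussian noise
#'
#' Per-channel independent noise with a flat component of standard deviation
#' `sigma_white` and a `1/f^beta`-shaped component of standard deviation
#' `sigma_pink`, synthesized in the frequency domain. Magnetometer arrays
#' show elevated intrinsic noise at low frequencies, which the `1/f`
#' component emulates.
#'
#' @param n_samples,n_channels output dimensions.
#' @param noise list with elements `sigma_white`, `sigma_pink`, `beta`.
#' @return numeric matrix, channels x samples.
#' @export
colored_noise <- function(n_samples, n_channels,
                          noise = list(sigma_white = 1, sigma_pink = 1,
                                       beta = 1)) {
  out <- matrix(stats::rnorm(n_channels * n_samples, 0, noise$sigma_white),
                n_channels, n_samples)
  if (noise$sigma_pink > 0) {
    # synthesize on a 2-3-5-smooth length (fast mixed-radix FFT), truncate
    nfft <- stats::nextn(n_samples, c(2, 3, 5))
    nh <- floor(nfft / 2)
    shape <- (seq_len(nh))^(-noise$beta / 2)
    for (ch in seq_len(n_channels)) {
      z <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) *
        shape
      spec <- complex(length.out = nfft)
      spec[2:(nh + 1)] <- z
      spec[nfft:(nfft - nh + 1)] <- Conj(z)
      if (nfft %% 2 == 0) spec[nh + 1] <- Re(spec[nh + 1])    # Nyquist real
      x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n_samples)] / nfft
      out[ch, ] <- out[ch, ] + noise$sigma_pink * x / stats::sd(x)
    }
  }
  out
}

#' Signed dipolar spatial gain
#'
#' Tangential neural currents produce a dipolar magnetic field map: a
#' polarity reversal across the dipole with Gaussian falloff,
#' `g(u) = u * exp(-u^2/2)` along the left-right axis. EEG potentials are
#' spatially blurred and single-signed, modelled as a plain Gaussian.
#' Gains are normalized so the best channel has |gain| = 1.
#'
#' @param layout a [sensor_layout].
#' @param center 2-D field-map centre in layout coordinates.
#' @param spread spatial scale (same units as positions).
#' @return numeric gain vector, one entry per channel (0 for gradiometers).
#' @export
spatial_gain <- function(layout, center = c(0, -1), spread = 0.8) {
  ux <- (layout$positions[, 1] - center[1]) / spread
  uy <- (layout$positions[, 2] - center[2]) / spread
  g <- numeric(n_channels(layout))
  mag <- layout$kinds == "magnetometer"
  eeg <- layout$kinds == "eeg"
  g[mag] <- ux[mag] * exp(-(ux[mag]^2 + uy[mag]^2) / 2)
  g[eeg] <- exp(-(ux[eeg]^2 + uy[eeg]^2) / 2)
  m <- max(abs(g))
  if (m > 0) g <- g / m
  g
}

#' Evoked component specification
#'
#' A Gaussian-windowed half-sine transient with compact support
#' `[latency - width/2, latency + width/2]`, peaking exactly at `latency`
#' with value `amplitude`, projected to the sensors through [spatial_gain].
#'
#' @param latency_ms peak latency after stimulus onset.
#' @param width_ms full support width of the half-sine.
#' @param amplitude peak amplitude at the best channel (fT or uV; negative
#'   for the typical motion-onset N/M200 deflection).
#' @param center,spread spatial field-map parameters (see [spatial_gain]).
#' @return list of class `erp_component`.
#' @export
erp_component <- function(latency_ms, width_ms, amplitude,
                          center = c(0, -1), spread = 0.8) {
  if (!is.finite(amplitude)) stop("amplitude must be finite")
  structure(list(latency_ms = latency_ms, width_ms = width_ms,
                 amplitude = amplitude, center = center, spread = spread),
            class = "erp_component")
}

component_waveform <- function(comp, fs_hz) {
  half <- comp$width_ms / 2
  t <- seq(comp$latency_ms - half, comp$latency_ms + half, by = 1000 / fs_hz)
  sig <- comp$width_ms / 4
  w <- sin(pi * (t - comp$latency_ms + half) / comp$width_ms) *
    exp(-(t - comp$latency_ms)^2 / (2 * sig^2))
  list(offsets = round(t * fs_hz / 1000), w = comp$amplitude * w)
}

#' Motion-onset (ERP/ERF) session configuration
#'
#' Defaults reproduce a standard 45-trial motion-onset run: 9 crosses each
#' stimulated 5 times per trial in block design, 150-ms expansions with a
#' jittered 150 +/- 75 ms inter-stimulus interval, and two evoked
#' components -- a parieto-occipital N/M200 (-567.34 fT at 191 ms) and a
#' centro-parietal P/M300 (-1103.38 fT at 347 ms) -- on a mixed white + 1/f
#' noise floor.
#'
#' @param n_trials number of trials (each cueing one cross).
#' @param n_targets number of crosses.
#' @param reps_per_target stimulations of each cross within a trial.
#' @param isi_ms,isi_jitter_ms inter-stimulus interval mean and uniform
#'   half-range (ms).
#' @param stim_duration_ms duration of one expansion/contraction.
#' @param components list of [erp_component]s added at cued-target onsets.
#' @param noise list(`sigma_white`, `sigma_pink`, `beta`).
#' @param trial_gap_s silent gap between trials (cue period).
#' @param fs_hz sampling rate.
#' @param seed RNG seed.
#' @return list of class `erp_session_config`.
#' @export
erp_session_config <- function(n_trials = 45, n_targets = 9,
                               reps_per_target = 5,
                               isi_ms = 150, isi_jitter_ms = 75,
                               stim_duration_ms = 150,
                               components = list(
                                 erp_component(191, 100, -567.34,
                                               center = c(0, -1.2)),
                                 erp_component(347, 200, -1103.38,
                                               center = c(0, -0.6),
                                               spread = 1)),
                               noise = list(sigma_white = 300,
                                            sigma_pink = 300, beta = 1),
                               trial_gap_s = 2, fs_hz = 1000, seed = 1) {
  if (isi_jitter_ms < 0) stop("jitter must be >= 0")
  if (isi_ms - isi_jitter_ms <= 0)
    stop("invalid config: jitter allows inter-stimulus interval <= 0")
  if (reps_per_target < 1) stop("reps_per_target must be >= 1")
  structure(as.list(environment()), class = "erp_session_config")
}

#' Simulate a motion-onset evoked session
#'
#' Generates the continuous recording of a full session: per trial one
#' cross is cued, then all crosses expand `reps_per_target` times each in
#' block design; expansions of the cued (gazed) cross evoke the configured
#' components, others contribute nothing beyond the noise floor. One event
#' is emitted per stimulation, labelled with trial, stimulated and cued
#' cross.
#'
#' @param config an [erp_session_config].
#' @param layout a [sensor_layout].
#' @return A [continuous_recording] whose events have columns `sample`,
#'   `trial`, `target` (stimulated cross) and `cued` (cued cross).
#' @export
generate_erp_session <- function(config, layout) {
  stopifnot(inherits(config, "erp_session_config"))
  if (n_channels(layout) < 1) stop("layout must have at least one channel")
  set.seed(config$seed)
  fs <- config$fs_hz
  n_stim <- config$n_targets * config$reps_per_target

  cued <- block_schedule(config$n_targets,
                         ceiling(config$n_trials / config$n_targets))
  cued <- cued[seq_len(config$n_trials)]

  ev <- vector("list", config$n_trials)
  t_cursor <- 1.0                                    # lead-in seconds
  for (tr in seq_len(config$n_trials)) {
    stim <- block_schedule(config$n_targets, config$reps_per_target)
    isi <- config$isi_ms +
      stats::runif(n_stim, -config$isi_jitter_ms, config$isi_jitter_ms)
    onsets <- t_cursor + c(0, cumsum((config$stim_duration_ms +
                                        isi[-n_stim]) / 1000))
    ev[[tr]] <- data.frame(sample = round(onsets * fs), trial = tr,
                           target = stim, cued = cued[tr])
    t_cursor <- onsets[n_stim] +
      (config$stim_duration_ms + isi[n_stim]) / 1000 + config$trial_gap_s
  }
  events <- do.call(rbind, ev)
  n_total <- round((t_cursor + 1.0) * fs)

  data <- colored_noise(n_total, n_channels(layout), config$noise)
  gains <- lapply(config$components, function(cmp)
    spatial_gain(layout, cmp$center, cmp$spread))
  waves <- lapply(config$components, component_waveform, fs_hz = fs)
  hit <- which(events$target == events$cued)
  for (i in hit) {
    s0 <- events$sample[i]
    for (k in seq_along(waves)) {
      idx <- s0 + waves[[k]]$offsets + 1          # 1-based column indices
      keep <- idx >= 1 & idx <= n_total
      data[, idx[keep]] <- data[, idx[keep]] +
        gains[[k]] %o% waves[[k]]$w[keep]
    }
  }
  continuous_recording(data, fs, layout, events)
}

#' SSVEP session configuration
#'
#' Covers both session types: the single-square frequency sweep (pass
#' `frequencies`, e.g. the ten integers 8-12 and 25-29 Hz, 10 repetitions,
#' 4-s flicker) and the 9-target frequency-phase training/spelling sessions
#' (pass a [target_layout]).
#'
#' @param frequencies flicker frequencies (Hz) for single-square sessions;
#'   ignored when `layout` is given.
#' @param layout optional [target_layout] assigning (frequency, phase) to 9
#'   targets.
#' @param reps presentations per frequency/target.
#' @param trial_s flicker duration in seconds (4 for training, 2 for
#'   spelling).
#' @param amplitude steady-state response amplitude at the best channel.
#' @param response_center,response_spread spatial field map of the response
#'   (see [spatial_gain]); `gain_map` overrides with an explicit per-channel
#'   gain vector.
#' @param gain_map optional per-channel gain vector.
#' @param phase_lag_s latency of the visual system: the response phase at
#'   frequency f is the stimulus phase minus `2*pi*f*phase_lag_s`, giving
#'   the characteristic negative phase-vs-frequency trend.
#' @param noise list(`sigma_white`, `sigma_pink`, `beta`).
#' @param inter_trial_s,inter_trial_jitter_s inter-trial interval mean and
#'   uniform half-range (s).
#' @param fs_hz sampling rate.
#' @param seed RNG seed.
#' @return list of class `ssvep_session_config`.
#' @export
ssvep_session_config <- function(frequencies = c(8:12, 25:29), layout = NULL,
                                 reps = 10, trial_s = 4, amplitude = 50,
                                 response_center = c(0, -1.2),
                                 response_spread = 0.8, gain_map = NULL,
                                 phase_lag_s = 0.05,
                                 noise = list(sigma_white = 300,
                                              sigma_pink = 300, beta = 1),
                                 inter_trial_s = 1.75,
                                 inter_trial_jitter_s = 0.25,
                                 fs_hz = 1000, seed = 1) {
  if (reps < 1) stop("reps must be >= 1")
  f <- if (is.null(layout)) frequencies else layout$frequency_hz
  if (any(f <= 0)) stop("frequencies must be positive")
  if (any(f >= fs_hz / 2)) stop("frequencies must be below Nyquist")
  structure(as.list(environment())[names(formals(ssvep_session_config))],
            class = "ssvep_session_config")
}

#' Simulate a steady-state (SSVEP) session
#'
#' Each trial flickers for `trial_s` seconds at one frequency(-phase); the
#' responsive channels carry
#' `gain * amplitude * sin(2*pi*f*t + phase - 2*pi*f*phase_lag_s)` with `t`
#' measured from trial onset, on top of the noise floor. Trials follow a
#' block-design schedule; an optional `schedule` (vector of target or
#' frequency indices) overrides it, which the simulated speller uses to
#' stream single gaze trials.
#'
#' @param config an [ssvep_session_config].
#' @param layout a [sensor_layout].
#' @param schedule optional integer vector of condition indices.
#' @return A [continuous_recording] whose events have columns `sample`,
#'   `trial`, `target`, `frequency_hz`, `phase_rad`.
#' @export
generate_ssvep_session <- function(config, layout, schedule = NULL) {
  stopifnot(inherits(config, "ssvep_session_config"))
  set.seed(config$seed)
  fs <- config$fs_hz
  if (is.null(config$layout)) {
    freqs <- config$frequencies
    phases <- rep(0, length(freqs))
  } else {
    freqs <- config$layout$frequency_hz
    phases <- config$layout$phase_rad
  }
  if (is.null(schedule))
    schedule <- block_schedule(length(freqs), config$reps)
  n_trials <- length(schedule)

  gaps <- config$inter_trial_s + stats::runif(n_trials,
                                              -config$inter_trial_jitter_s,
                                              config$inter_trial_jitter_s)
  onsets <- 1.0 + cumsum(c(0, (config$trial_s + gaps[-n_trials])))
  events <- data.frame(sample = round(onsets * fs),
                       trial = seq_len(n_trials), target = schedule,
                       frequency_hz = freqs[schedule],
                       phase_rad = phases[schedule])
  n_total <- round((onsets[n_trials] + config$trial_s + 1.0) * fs)

  data <- colored_noise(n_total, n_channels(layout), config$noise)
  g <- if (is.null(config$gain_map))
    spatial_gain(layout, config$response_center, config$response_spread)
  else config$gain_map
  n_trial_samp <- round(config$trial_s * fs)
  t_rel <- (seq_len(n_trial_samp) - 1) / fs
  for (i in seq_len(n_trials)) {
    f <- events$frequency_hz[i]
    ph <- events$phase_rad[i] - 2 * pi * f * config$phase_lag_s
    s <- config$amplitude * sin(2 * pi * f * t_rel + ph)
    idx <- events$sample[i] + seq_len(n_trial_samp)
    data[, idx] <- data[, idx] + g %o% s
  }
  continuous_recording(data, fs, layout, events)
}
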