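test_that("motion-onset schedule matches the closed-form event count", {
  cfg <- erp_session_config(seed = 3, noise = list(sigma_white = 1,
                                                   sigma_pink = 0, beta = 1))
  rec <- generate_erp_session(cfg, default_sensor_layout())
  # 45 trials x 9 crosses x 5 stimulations
  expect_equal(nrow(rec$events), 45 * 9 * 5)
  # each cross cued 5 times; within a trial each cross stimulated 5 times
  ev <- rec$events
  cued_per_trial <- unique(ev[, c("trial", "cued")])
  expect_equal(unname(table(cued_per_trial$cued)), rep(5L, 9),
               ignore_attr = TRUE)
  tr1 <- ev[ev$trial == 1, ]
  expect_equal(unname(table(tr1$target)), rep(5L, 9), ignore_attr = TRUE)
  # block design within a trial: every block of 9 stimulations is a
  # permutation of the 9 crosses
  for (b in seq_len(5))
    expect_setequal(tr1$target[(9 * (b - 1) + 1):(9 * b)], 1:9)
})

test_that("noiseless cued-event epochs carry the component exactly", {
  cfg <- erp_session_config(n_trials = 9, seed = 5,
                            components = list(erp_component(191, 100, -450)),
                            noise = list(sigma_white = 0, sigma_pink = 0,
                                         beta = 1))
  rec <- generate_erp_session(cfg, default_sensor_layout())
  ep <- extract_epochs(rec, -200, 600,
                       function(ev) ev$target == ev$cued)
  t <- epoch_times_ms(ep)
  ev <- average_evoked(ep, "all")
  i <- arrayInd(which.min(ev$mean), dim(ev$mean))
  expect_equal(ev$mean[i[1], i[2]], -450)
  expect_equal(t[i[2]], 191)
  # non-cued events contribute nothing themselves; epochs of non-cued
  # events far enough from any cued stimulation are exactly zero
  cued_samp <- rec$events$sample[rec$events$target == rec$events$cued]
  far <- function(ev) {
    ev$target != ev$cued &
      vapply(ev$sample, function(s0)
        all(abs(cued_samp - s0) > 900), logical(1))
  }
  ep0 <- extract_epochs(rec, -200, 600, far)
  expect_gt(dim(ep0$data)[1], 0)
  expect_equal(max(abs(ep0$data)), 0)
})

test_that("same seed gives bit-identical sessions; invalid ISI errors", {
  cfg <- erp_session_config(n_trials = 2, seed = 8)
  lay <- default_sensor_layout()
  r1 <- generate_erp_session(cfg, lay)
  r2 <- generate_erp_session(cfg, lay)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  expect_error(erp_session_config(isi_ms = 50, isi_jitter_ms = 75),
               "invalid config")
})

test_that("single-square SSVEP session: 10 frequencies x 10 reps = 100 trials", {
  cfg <- ssvep_session_config(seed = 4, fs_hz = 250)
  rec <- generate_ssvep_session(cfg, default_sensor_layout())
  expect_equal(nrow(rec$events), 100)
  expect_equal(unname(table(rec$events$frequency_hz)), rep(10L, 10),
               ignore_attr = TRUE)
  # block design over trials
  for (b in seq_len(10))
    expect_setequal(rec$events$target[(10 * (b - 1) + 1):(10 * b)], 1:10)
  expect_error(ssvep_session_config(frequencies = 130, fs_hz = 250),
               "Nyquist")
})

test_that("noiseless SSVEP trial is a pure sinusoid with the lagged phase", {
  lag <- 0.06
  cfg <- ssvep_session_config(frequencies = 12, reps = 1, seed = 9,
                              amplitude = 80, phase_lag_s = lag,
                              noise = list(sigma_white = 0, sigma_pink = 0,
                                           beta = 1))
  rec <- generate_ssvep_session(cfg, default_sensor_layout())
  ep <- extract_epochs(rec, 0, 4000)
  best <- which.max(spatial_gain(rec$layout, c(0, -1.2), 0.8))  # gain +1
  x <- ep$data[1, best, ]
  amp <- Mod(stats::fft(x)) / length(x)
  expect_equal(which.max(amp[2:(length(x) / 2)]),
               unname(12 * length(x) / 1000))  # max exactly at the 12 Hz bin
  # generated phase (sine convention) = -2*pi*f*lag; cosine-reference DFT
  # phase is that minus pi/2
  ph <- phase_at(x, 1000, 12)
  expected <- (-2 * pi * 12 * lag - pi / 2)
  expect_lt(abs(Arg(exp(1i * (ph - expected)))), 1e-6)
})

test_that("training schedule is a block design with 9 x reps cues", {
  tl <- default_target_layout()
  sch <- generate_training_schedule(tl, reps = 8, seed = 2)
  expect_equal(nrow(sch), 72)
  for (b in seq_len(8))
    expect_setequal(sch$target[(9 * (b - 1) + 1):(9 * b)], 1:9)
  expect_equal(sort(generate_training_schedule(tl, 1, 3)$target), 1:9)
})

test_that("noise spectrum follows the configured 1/f exponent", {
  set.seed(31)
  n <- 2048
  psd <- numeric(n %/% 2)
  reps <- 120
  for (r in seq_len(reps)) {
    x <- colored_noise(n, 1, list(sigma_white = 0, sigma_pink = 1,
                                  beta = 1))[1, ]
    psd <- psd + Mod(stats::fft(x)[2:(n %/% 2 + 1)])^2 / reps
  }
  bins <- 4:400
  slope <- stats::coef(stats::lm(log(psd[bins]) ~ log(bins)))[2]
  expect_lt(abs(slope - (-1)), 0.12)
})

test_that("evoked average converges to the template as 1/sqrt(N)", {
  set.seed(17)
  tmpl <- 5 * sin(pi * (0:99) / 100)
  rmse_at <- function(N) {
    mean(replicate(30, {
      x <- matrix(rep(tmpl, each = N), N) + stats::rnorm(N * 100)
      sqrt(mean((colMeans(x) - tmpl)^2))
    }))
  }
  r <- vapply(c(5, 20, 80), rmse_at, numeric(1))
  expect_gt(r[1] / r[2], 1.6); expect_lt(r[1] / r[2], 2.5)
  expect_gt(r[2] / r[3], 1.6); expect_lt(r[2] / r[3], 2.5)
})

test_that("recordings round-trip through the text bundle", {
  cfg <- ssvep_session_config(frequencies = c(8, 10), reps = 1, seed = 12,
                              trial_s = 1, fs_hz = 200)
  rec <- generate_ssvep_session(cfg, tiny_layout(3))
  path <- file.path(tempdir(), "rec_bundle")
  write_recording(rec, path)
  back <- read_recording(path)
  expect_equal(back$fs_hz, rec$fs_hz)
  expect_equal(back$data, rec$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$events$sample, rec$events$sample)
  expect_identical(back$layout$channel_names, rec$layout$channel_names)
  unlink(path, recursive = TRUE)
})
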