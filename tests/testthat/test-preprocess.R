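test_that("zero-phase filtering leaves a centred impulse symmetric", {
  n <- 4001
  x <- numeric(n); x[2001] <- 1
  rec <- continuous_recording(matrix(x, 1), 1000, tiny_layout(1))
  y <- bandpass_filter(rec, 4, 40)$data[1, ]
  asym <- max(abs(y[2001 + 1:1500] - y[2001 - 1:1500]))
  # symmetric to the numerical precision of the order-8 IIR recursion
  expect_lt(asym / max(abs(y)), 1e-7)
})

test_that("filter magnitude matches the analog Butterworth prototype", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  for (f in c(10, 30)) {
    rec <- continuous_recording(matrix(sin(2 * pi * f * t), 1), fs,
                                tiny_layout(1))
    y <- bandpass_filter(rec, 4, 40)$data[1, ]
    ratio <- mid_amplitude(y, f, fs)
    expect_equal(ratio, butter_bandpass_gain2(f, 4, 40), tolerance = 0.01)
  }
  # strong stop-band suppression at 2 Hz
  rec <- continuous_recording(matrix(sin(2 * pi * 2 * t), 1), fs,
                              tiny_layout(1))
  y <- bandpass_filter(rec, 4, 40)$data[1, ]
  expect_equal(mid_amplitude(y, 2, fs), butter_bandpass_gain2(2, 4, 40),
               tolerance = 0.05)
  expect_error(bandpass_filter(rec, 4, 600), "Nyquist|band edges")
})

test_that("mastoid re-referencing does the channel arithmetic", {
  lay <- sensor_layout(c("C1", "M1", "M2", "MEG1"),
                       c("eeg", "eeg", "eeg", "magnetometer"),
                       matrix(0, 4, 2))
  a <- sin(1:100); b <- cos(1:100); c0 <- (1:100) / 50; m <- rnorm(100)
  rec <- continuous_recording(rbind(c0, a, b, m), 100, lay)
  out <- rereference_mastoids(rec, "M1", "M2")
  expect_equal(out$data[1, ], c0 - (a + b) / 2)
  expect_equal(out$data[4, ], m)          # magnetometer untouched
  # common-mode removal: all EEG equal -> zero
  rec2 <- continuous_recording(rbind(a, a, a, m), 100, lay)
  expect_equal(max(abs(rereference_mastoids(rec2, "M1", "M2")$data[1:3, ])),
               0)
  expect_error(rereference_mastoids(rec, "M1", "nope"), "not found")
})

test_that("epoch extraction follows the half-open window convention", {
  lay <- tiny_layout(1)
  x <- seq_len(5000)
  ev <- data.frame(sample = c(50, 1000, 2000, 4700), trial = 1:4)
  rec <- continuous_recording(matrix(x, 1), 1000, lay, ev)
  expect_message(ep <- extract_epochs(rec, -200, 600),
                 "2 event\\(s\\) skipped")
  expect_equal(dim(ep$data), c(2, 1, 800))        # 800 samples per epoch
  # samples are exact slices of the original recording (no resampling)
  expect_equal(ep$data[1, 1, ], x[(1000 - 200 + 1):(1000 + 600)])
  expect_equal(ep$labels$trial, c(2, 3))
  expect_error(extract_epochs(rec, 600, -200), "tmin")
})

test_that("baseline correction zeroes the baseline window mean", {
  set.seed(2)
  x <- matrix(rnorm(5 * 160), 5)
  ep <- toy_epochs(x, fs = 200, t0_ms = -200)
  out <- baseline_correct(ep, -200, 0)
  t <- epoch_times_ms(out)
  base <- apply(out$data[, 1, t < 0], 1, mean)
  expect_lt(max(abs(base)), 1e-12)
  # linear ramp toy: subtracts the ramp's baseline mean
  ramp <- toy_epochs(matrix(1:10, 1), fs = 10, t0_ms = -500)
  out2 <- baseline_correct(ramp, -500, 0)
  expect_equal(out2$data[1, 1, ], 1:10 - mean(1:5))
  expect_error(baseline_correct(ep, -400, 0), "outside epoch")
  # constant epochs become all-zero
  cst <- baseline_correct(toy_epochs(matrix(7, 2, 100), 100, -200), -200, 0)
  expect_equal(max(abs(cst$data)), 0)
})

test_that("downsampling preserves in-band content at the right length", {
  fs <- 1000
  t <- seq(0, 4 - 1 / fs, by = 1 / fs)
  ep <- toy_epochs(matrix(sin(2 * pi * 12 * t), 1), fs = fs)
  out <- downsample(ep, 150)
  expect_equal(dim(out$data)[3], 600)              # 4 s x 150 Hz
  amp <- mid_amplitude(out$data[1, 1, ], 12, 150)
  expect_equal(amp, 1, tolerance = 0.01)
  # DC unchanged
  dc <- downsample(toy_epochs(matrix(3.7, 1, 1000), fs = 1000), 150)
  expect_lt(max(abs(dc$data - 3.7)), 1e-9)
  expect_error(downsample(ep, 2000), "fs_new")
})

test_that("gradiometer synthesis differences magnetometer pairs", {
  lay <- sensor_layout(paste0("M", 1:10), "magnetometer",
                       cbind(seq(-1, 1, length.out = 10), -1))
  set.seed(3)
  d <- array(rnorm(2 * 10 * 50), c(2, 10, 50))
  ep <- epoch_set(d, 100, 0, data.frame(trial = 1:2), lay)
  g <- make_gradiometers(ep, pairs = "all")
  expect_equal(dim(g$data)[2], 10 + choose(10, 2))  # 45 gradiometers
  expect_equal(sum(g$layout$kinds == "gradiometer"), 45)
  expect_equal(g$data[1, 11, ], d[1, 1, ] - d[1, 2, ])  # first pair M1-M2
  # identical pair -> zero channel
  z <- make_gradiometers(ep, pairs = list(c("M1", "M1")))
  expect_equal(max(abs(z$data[, 11, ])), 0)
  expect_error(make_gradiometers(ep, pairs = list(c("M1", "XX"))),
               "unknown channel")
})

test_that("antiphase gradiometer gains sqrt(2) in amplitude SNR", {
  set.seed(6)
  n <- 20000
  s <- sin(2 * pi * 10 * (0:(n - 1)) / 1000)
  lay <- sensor_layout(c("A", "B"), "magnetometer", matrix(0, 2, 2))
  d <- array(0, c(1, 2, n))
  d[1, 1, ] <- s + rnorm(n)
  d[1, 2, ] <- -s + rnorm(n)
  ep <- epoch_set(d, 1000, 0, data.frame(trial = 1), lay)
  g <- make_gradiometers(ep, pairs = list(c("A", "B")),
                         keep_magnetometers = FALSE)
  x <- g$data[1, 1, ]
  snr_grad <- mid_amplitude(x, 10, 1000) / sqrt(2)   # noise sd ~ sqrt(2)
  snr_mag <- mid_amplitude(d[1, 1, ], 10, 1000) / 1
  expect_equal(snr_grad / snr_mag, sqrt(2), tolerance = 0.1)
  # and directly: noise variance doubles, signal amplitude doubles
  expect_equal(stats::var(x - 2 * s), 2, tolerance = 0.05)
})

test_that("two-period segmentation enumerates the stated grid", {
  ep <- toy_epochs(matrix(0, 1, 600), fs = 150)     # 4 s at 150 Hz
  s10 <- segment_two_periods(ep, 10)
  expect_equal(s10$n, 30)
  expect_equal(dim(s10$data)[1], 39)
  expect_equal(segment_two_periods(ep, 12)$n, 25)   # 2*150/12
  # spelling rule: 2-s epoch, discard 150 ms -> first start at sample >= 23
  ep2 <- toy_epochs(matrix(0, 1, 300), fs = 150)
  s <- opmbci:::segment_starts(300, 30, 10, 150, 0.5,
                               discard_before_ms = 150)
  expect_true(all(s >= 23))
  expect_equal(min(s), 30)
  full <- opmbci:::segment_starts(300, 30, 10, 150, 0.5, 0)
  expect_equal(setdiff(full, s), c(0, 15))          # exactly the early ones
  expect_error(segment_two_periods(toy_epochs(matrix(0, 1, 20), fs = 150),
                                   10), "shorter than two periods")
  # every retained segment lies within its parent epoch
  s8 <- segment_two_periods(ep, 8)
  expect_true(all(dim(s8$data)[3] == s8$n))
})

test_that("preprocessing operations are linear", {
  set.seed(9)
  n <- 1200
  x <- matrix(rnorm(2 * n), 2); y <- matrix(rnorm(2 * n), 2)
  lay <- tiny_layout(2)
  fl <- function(m) bandpass_filter(
    continuous_recording(m, 400, lay), 4, 40)$data
  expect_equal(fl(2 * x + 3 * y), 2 * fl(x) + 3 * fl(y), tolerance = 1e-9)
  bc <- function(m) baseline_correct(
    toy_epochs(m, fs = 400, t0_ms = -200), -200, 0)$data
  expect_equal(bc(2 * x[1, , drop = FALSE] + 3 * y[1, , drop = FALSE]),
               2 * bc(x[1, , drop = FALSE]) + 3 * bc(y[1, , drop = FALSE]),
               tolerance = 1e-12)
})
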