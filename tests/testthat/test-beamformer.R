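test_that("regularized covariance interpolates between data and identity", {
  set.seed(1)
  segs <- array(rnorm(20 * 2 * 5), c(20, 2, 5))
  # alpha = 0: identity regardless of the data
  pc0 <- build_pattern_and_covariance(segs, segs, alpha = 0)
  expect_equal(pc0$sigma_hat, diag(10))
  # identical segments: zero covariance -> (1 - alpha) I
  one <- array(rep(segs[1, , ], each = 4), c(4, 2, 5))
  pc1 <- build_pattern_and_covariance(one, one, alpha = 0.95)
  expect_equal(pc1$sigma_hat, diag(0.05, 10))
  expect_equal(pc1$a, as.vector(t(segs[1, , ])))   # channel-major
  # symmetric positive definite with min eigenvalue >= 1 - alpha
  for (s in 1:20) {
    set.seed(s)
    x <- array(rnorm(8 * 3 * 4), c(8, 3, 4))
    S <- build_pattern_and_covariance(x, x, alpha = 0.95)$sigma_hat
    expect_equal(S, t(S))
    expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
               0.05 - 1e-9)
  }
  expect_error(build_pattern_and_covariance(segs, segs[, , 1:3]),
               "dimensions differ")
})

test_that("LCMV weights satisfy the closed form and the unit gain", {
  # identity covariance: w = a / (a.a), responds with c to x = c a
  a <- c(1, -2, 3, 0.5)
  w <- train_beamformer(a, diag(4))
  expect_equal(w, a / sum(a^2))
  expect_equal(sum(w * (4.2 * a)), 4.2)
  expect_error(train_beamformer(rep(0, 4), diag(4)), "zero")
  # unit-gain constraint on random problems
  for (s in 1:100) {
    set.seed(s)
    p <- sample(3:12, 1)
    a <- rnorm(p)
    R <- matrix(rnorm(p * p), p)
    S <- 0.95 * crossprod(R) / p + diag(0.05, p)
    w <- train_beamformer(a, S)
    expect_lt(abs(sum(a * w) - 1), 1e-9)
  }
})

test_that("LCMV equals the brute-force constrained variance minimizer", {
  worst <- 0
  for (s in 1:50) {
    set.seed(200 + s)
    p <- sample(4:12, 1)
    a <- rnorm(p)
    R <- matrix(rnorm(2 * p * p), 2 * p) %*% diag(runif(p, 0.5, 2))
    S <- 0.95 * stats::cov(R) + diag(0.05, p)
    w <- train_beamformer(a, S)
    w_ref <- lcmv_oracle(a, S)
    worst <- max(worst, sqrt(sum((w - w_ref)^2)) / sqrt(sum(w_ref^2)))
    # achieved variance is the constrained minimum
    expect_lte(drop(w %*% S %*% w), drop(w_ref %*% S %*% w_ref) + 1e-10)
  }
  expect_lt(worst, 1e-6)
})

test_that("alpha = 1 with a well-conditioned covariance is unregularized", {
  set.seed(77)
  p <- 8
  R <- matrix(rnorm(40 * p), 40)
  S <- crossprod(R) / 40 + diag(0.5, p)    # well-conditioned
  a <- rnorm(p)
  w1 <- train_beamformer(a, 1 * S + 0 * diag(p))
  w_direct <- drop(solve(S, a)) / drop(crossprod(a, solve(S, a)))
  expect_lt(sqrt(sum((w1 - w_direct)^2)) / sqrt(sum(w_direct^2)), 1e-6)
})

test_that("beamformer scores its own pattern at one and is linear", {
  ep <- synth_fp_epochs(n_per_target = 3, amplitude = 6, sigma = 0.8,
                        seed = 5)
  m <- beamformer(ep, "ssvep")
  # unit gain for every trained target
  for (tg in m$targets) expect_lt(abs(sum(tg$a * tg$w) - 1), 1e-6)
  # linearity of the score
  set.seed(6)
  x <- matrix(rnorm(3 * 600), 3); y <- matrix(rnorm(3 * 600), 3)
  s <- function(M) score_target(m, M, 5)
  expect_equal(s(2 * x + 3 * y), 2 * s(x) + 3 * s(y), tolerance = 1e-9)
})

test_that("an epoch tiled with a target's own pattern scores exactly one", {
  # noiseless training at 10 Hz (a whole 15-sample period at 150 Hz): the
  # learned pattern is exactly periodic, so every 50%-overlap segment of
  # the tiled epoch reproduces it
  ep <- synth_fp_epochs(n_per_target = 3, amplitude = 6, sigma = 0,
                        seed = 5)
  m <- beamformer(ep, "ssvep")
  tg <- m$targets[[8]]                  # a 10-Hz target
  expect_equal(tg$frequency_hz, 10)
  tiled <- matrix(rep(tg$A, 20), nrow(tg$A))[, 1:600]
  expect_equal(score_target(m, tiled, 8), 1, tolerance = 1e-9)
  expect_equal(score_target(m, -tiled, 8), -1, tolerance = 1e-9)
  # classification picks the pattern's own target
  d <- array(0, c(1, 3, 600)); d[1, , ] <- tiled
  ep1 <- epoch_set(d, 150, 0, data.frame(trial = 1), ep$layout)
  expect_equal(unname(predict(m, ep1)), 8)
})

test_that("cross-target scores vanish on orthogonalized patterns", {
  # two orthogonal patterns on one channel; covariance = identity via alpha 0
  fs <- 100
  n <- 20
  A1 <- matrix(sin(2 * pi * 5 * (0:(n - 1)) / fs), 1)     # 5 Hz
  A2 <- matrix(cos(2 * pi * 5 * (0:(n - 1)) / fs), 1)
  w1 <- train_beamformer(as.vector(A1), diag(n))
  expect_lt(abs(sum(as.vector(A2) * w1)), 1e-9)
})

test_that("zero-signal epochs classify at chance", {
  ep <- synth_fp_epochs(n_per_target = 8, amplitude = 4, sigma = 1,
                        seed = 21)
  m <- beamformer(ep, "ssvep")
  set.seed(22)
  noise <- array(rnorm(180 * 3 * 600), c(180, 3, 600))
  epn <- epoch_set(noise, 150, 0, data.frame(trial = 1:180), ep$layout)
  pred <- predict(m, epn)
  truth <- rep(1:9, 20)
  # accuracy against arbitrary labels sits at chance (binomial 3-sigma band)
  expect_lt(abs(mean(pred == truth) - 1 / 9), 0.07)
  expect_true(all(table(factor(pred, 1:9)) < 180 * 0.35))
})

test_that("ERP beamformer identifies the cross whose average is the pattern", {
  # 9 candidate crosses, one trial: candidate 4's average equals the
  # trained pattern, others are zero
  set.seed(9)
  n_ch <- 2; ns <- 40
  tmpl <- matrix(rnorm(n_ch * ns), n_ch)
  build <- function(k_signal) {
    d <- array(rnorm(18 * n_ch * ns, 0, 0.05), c(18, n_ch, ns))
    lb <- data.frame(trial = rep(1:2, each = 9), target = rep(1:9, 2),
                     cued = k_signal)
    for (e in which(lb$target == k_signal))
      d[e, , ] <- d[e, , ] + tmpl
    epoch_set(d, 100, 0, lb, tiny_layout(n_ch))
  }
  ep <- build(4)
  m <- beamformer(ep, "erp")
  expect_lt(abs(sum(m$targets[[1]]$a * m$targets[[1]]$w) - 1), 1e-9)
  pred <- predict(m, ep)
  expect_equal(unname(pred), c(4, 4))
  sc <- predict(m, ep, type = "score")
  expect_equal(unname(sc[1, "cand4"]), 1, tolerance = 0.2)
  expect_error(predict(m, ep, k_reps = 3), "insufficient repetitions")
})

test_that("decoding accuracy rises with response amplitude", {
  accs <- vapply(c(0.05, 0.15, 0.4), function(a) {
    ep <- synth_fp_epochs(n_per_target = 4, amplitude = a, sigma = 1,
                          seed = 31)
    crossval_accuracy(ep, "ssvep", k_folds = 4, seed = 31)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gt(accs[3], accs[1])
})
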