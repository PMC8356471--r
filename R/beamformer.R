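## Spatiotemporal LCMV beamformer classifier.
##
## For a vectorized spatiotemporal activation pattern a (1 x mn, channel-
## major: channel 1's n samples, then channel 2's, ...) and the regularized
## covariance S = alpha*Sigma + (1-alpha)*I of vectorized data segments, the
## linearly-constrained minimum-variance weights are
##
##     w = a S^-1 / (a S^-1 a^T),
##
## the unique minimizer of the output variance w S w^T under the unit-gain
## constraint a w^T = 1. Applied to a data segment the beamformer estimates
## the contribution of the pattern to that segment.

## channel-major vectorization of a channels x samples matrix
vec_cm <- function(M) as.vector(t(M))

## symmetric pseudo-inverse; eigenvalues below tol * max are discarded
pinv_sym <- function(S, tol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  keep <- e$values > tol * max(abs(e$values))
  if (!any(keep)) stop("matrix is numerically zero")
  e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
}

#' Activation pattern and regularized covariance
#'
#' The activation pattern is the channel-major vectorization of the mean
#' pattern segment; the covariance is estimated from all covariance-source
#' segments (mean-centred, 1/(N-1)) and shrunk towards the identity:
#' `S = alpha * Sigma + (1 - alpha) * I`.
#'
#' @param pattern_segments a `segment_set` (or segments x channels x n
#'   array) defining the pattern (e.g. segments of the epochs cued to the
#'   target).
#' @param cov_segments segments of *all* epochs, cut to the same length.
#' @param alpha regularization constant in `[0, 1]` (default 0.95).
#' @return list with `a` (pattern vector), `A` (channels x n mean segment),
#'   `sigma_hat` (regularized covariance), `n_cov` (covariance sample
#'   count).
#' @export
build_pattern_and_covariance <- function(pattern_segments, cov_segments,
                                         alpha = 0.95) {
  pat <- if (inherits(pattern_segments, "segment_set"))
    pattern_segments$data else pattern_segments
  cov <- if (inherits(cov_segments, "segment_set"))
    cov_segments$data else cov_segments
  if (!identical(dim(pat)[2:3], dim(cov)[2:3]))
    stop("pattern and covariance segment dimensions differ")
  if (dim(cov)[1] < 2) stop("need >= 2 covariance segments")
  if (!(alpha >= 0 && alpha <= 1)) stop("alpha must be in [0, 1]")
  A <- apply(pat, c(2, 3), mean)
  X <- t(apply(cov, 1, function(s) vec_cm(s)))
  dim(X) <- c(dim(cov)[1], dim(cov)[2] * dim(cov)[3])
  sigma <- stats::cov(X)
  sigma_hat <- alpha * sigma + diag(1 - alpha, ncol(X))
  list(a = vec_cm(A), A = A, sigma_hat = sigma_hat, n_cov = dim(cov)[1])
}

#' LCMV weights from pattern and covariance
#'
#' `w = a S^-1 / (a S^-1 a^T)` with `S^-1` the (symmetric) pseudo-inverse;
#' the result satisfies the unit-gain constraint `sum(a * w) = 1` and
#' minimizes the output variance among all unit-gain linear filters.
#'
#' @param a activation pattern vector.
#' @param sigma_hat regularized covariance matrix.
#' @return weight vector of the same length as `a`.
#' @export
train_beamformer <- function(a, sigma_hat) {
  if (all(a == 0)) stop("activation pattern is zero")
  sa <- pinv_sym(sigma_hat) %*% a
  denom <- drop(crossprod(a, sa))
  if (abs(denom) < 1e-300) stop("singular projection: a S^-1 a^T ~ 0")
  drop(sa) / denom
}

#' Fit a spatiotemporal LCMV beamformer classifier
#'
#' The single fitting entry point for both paradigms.
#'
#' For `paradigm = "ssvep"` one beamformer per frequency-phase target is
#' trained: the epochs cued to target i are cut into two-period 50%-overlap
#' segments of its frequency to form the activation pattern, while the
#' covariance uses segments of the same length from *all* training epochs.
#'
#' For `paradigm = "erp"` a single beamformer is trained on whole epochs:
#' the pattern is the vectorized average target response (epochs whose
#' stimulated cross equals the cued cross) and the covariance comes from
#' all vectorized training epochs.
#'
#' @param epochs an [epoch_set]. SSVEP labels need columns `target` and
#'   `frequency_hz`; ERP labels need `target` (stimulated) and `cued`.
#' @param paradigm `"ssvep"` or `"erp"`.
#' @param alpha covariance regularization constant (default 0.95).
#' @param channels optional channel subset (names or indices).
#' @param overlap segment overlap for the SSVEP paradigm.
#' @return An object of class `beamformer` with per-target weights,
#'   patterns and metadata. Methods: [print.beamformer()],
#'   [summary.beamformer()], [coef.beamformer()], [predict.beamformer()],
#'   [plot.beamformer()].
#' @export
beamformer <- function(epochs, paradigm = c("ssvep", "erp"), alpha = 0.95,
                       channels = NULL, overlap = 0.5) {
  paradigm <- match.arg(paradigm)
  if (!is.null(channels)) epochs <- subset_epochs(epochs, channels = channels)
  fit <- list(paradigm = paradigm, alpha = alpha, fs_hz = epochs$fs_hz,
              channel_names = epochs$layout$channel_names,
              overlap = overlap)
  if (paradigm == "ssvep") {
    tab <- unique(epochs$labels[, c("target", "frequency_hz")])
    tab <- tab[order(tab$target), ]
    fit$targets <- lapply(seq_len(nrow(tab)), function(r) {
      tg <- tab$target[r]; f <- tab$frequency_hz[r]
      pat <- segment_two_periods(
        subset_epochs(epochs, epochs$labels$target == tg), f, overlap)
      cv <- segment_two_periods(epochs, f, overlap)
      pc <- build_pattern_and_covariance(pat, cv, alpha)
      w <- train_beamformer(pc$a, pc$sigma_hat)
      list(target = tg, frequency_hz = f, n = pat$n, a = pc$a, A = pc$A,
           w = w, n_cov = pc$n_cov)
    })
  } else {
    d <- dim(epochs$data)
    tgt <- epochs$labels$target == epochs$labels$cued
    if (!any(tgt)) stop("no target epochs (stimulated == cued) to train on")
    pc <- build_pattern_and_covariance(
      epochs$data[tgt, , , drop = FALSE], epochs$data, alpha)
    w <- train_beamformer(pc$a, pc$sigma_hat)
    fit$targets <- list(list(target = NA, frequency_hz = NA, n = d[3],
                             a = pc$a, A = pc$A, w = w, n_cov = pc$n_cov))
    fit$t0_ms <- epochs$t0_ms
  }
  class(fit) <- "beamformer"
  fit
}

#' @export
print.beamformer <- function(x, ...) {
  cat(sprintf("<beamformer> %s paradigm, alpha = %g, %d channel(s), fs = %g Hz\n",
              x$paradigm, x$alpha, length(x$channel_names), x$fs_hz))
  if (x$paradigm == "ssvep") {
    f <- vapply(x$targets, `[[`, numeric(1), "frequency_hz")
    cat("  targets:", length(x$targets), "| frequencies:",
        paste(unique(f), collapse = ", "), "Hz\n")
  } else {
    cat(sprintf("  spatiotemporal pattern: %d channels x %d samples\n",
                length(x$channel_names), x$targets[[1]]$n))
  }
  invisible(x)
}

#' @export
summary.beamformer <- function(object, ...) {
  gain <- vapply(object$targets,
                 function(tg) sum(tg$a * tg$w), numeric(1))
  out <- data.frame(
    target = vapply(object$targets, `[[`, numeric(1), "target"),
    frequency_hz = vapply(object$targets, `[[`, numeric(1), "frequency_hz"),
    n_samples = vapply(object$targets, `[[`, numeric(1), "n"),
    dim = vapply(object$targets, function(tg) length(tg$w), numeric(1)),
    unit_gain = gain,
    weight_norm = vapply(object$targets,
                         function(tg) sqrt(sum(tg$w^2)), numeric(1)))
  print(object)
  print(out, row.names = FALSE)
  invisible(out)
}

#' @export
coef.beamformer <- function(object, ...) {
  w <- lapply(object$targets, `[[`, "w")
  names(w) <- paste0("target", vapply(object$targets, `[[`, numeric(1),
                                      "target"))
  if (object$paradigm == "erp") w[[1]] else w
}

#' @export
plot.beamformer <- function(x, target = 1, ...) {
  tg <- x$targets[[target]]
  t <- (seq_len(ncol(tg$A)) - 1) * 1000 / x$fs_hz
  graphics::matplot(t, t(tg$A), type = "l", lty = 1, xlab = "time (ms)",
                    ylab = "pattern amplitude",
                    main = if (x$paradigm == "ssvep")
                      sprintf("target %s (%g Hz)", tg$target,
                              tg$frequency_hz)
                    else "average target response", ...)
  invisible(x)
}

## beamformer output for one epoch (channels x samples matrix) and one
## trained target: segment, average, vectorize, project.
## Returns -Inf when the epoch is shorter than one segment. When the
## discard rule removes every segment (very short epochs in the post hoc
## length sweep), it is waived for that epoch.
score_epoch_target <- function(model, M, tg, discard_before_ms = 0) {
  len <- ncol(M)
  if (len < tg$n) return(-Inf)
  starts <- segment_starts(len, tg$n, tg$frequency_hz, model$fs_hz,
                           model$overlap, discard_before_ms)
  if (length(starts) == 0)
    starts <- segment_starts(len, tg$n, tg$frequency_hz, model$fs_hz,
                             model$overlap, 0)
  avg <- matrix(0, nrow(M), tg$n)
  for (s in starts) avg <- avg + M[, (s + 1):(s + tg$n), drop = FALSE]
  sum(tg$w * vec_cm(avg / length(starts)))
}

#' Apply a single target's beamformer to one epoch
#'
#' Cuts the epoch into two-period overlapping segments of the target's
#' frequency, averages them (after the real-time discard rule, if any),
#' vectorizes, and returns the beamformer output `w_i . x`.
#'
#' @param model a fitted [beamformer] (ssvep paradigm).
#' @param epoch channels x samples matrix, channels matching the model.
#' @param target target id.
#' @param discard_before_ms drop segments starting before this time.
#' @return scalar score.
#' @export
score_target <- function(model, epoch, target, discard_before_ms = 0) {
  ids <- vapply(model$targets, `[[`, numeric(1), "target")
  tg <- model$targets[[match(target, ids)]]
  score_epoch_target(model, epoch, tg, discard_before_ms)
}

#' Classify epochs with a fitted beamformer
#'
#' SSVEP paradigm: each epoch is scored by all nine per-target beamformers
#' (two-period segmentation at each target's own frequency) and the target
#' with maximal output wins; ties break to the lowest target id.
#'
#' ERP paradigm: epochs are grouped (by trial, by default); within a group
#' the first `k_reps` epochs of each stimulated cross are averaged,
#' vectorized and projected on the beamformer, and the cross with maximal
#' output is predicted as the gazed one.
#'
#' @param object a fitted [beamformer].
#' @param newdata an [epoch_set] with channels matching the fit.
#' @param type `"class"` for predicted target ids, `"score"` for the score
#'   matrix (rows = epochs or trials, columns = targets/candidates).
#' @param k_reps (ERP) stimulus repetitions used per candidate; all
#'   available if `NULL`. Groups with fewer repetitions raise an error.
#' @param discard_before_ms (SSVEP) real-time discard rule: segments
#'   starting before this time are dropped (150 ms during online spelling).
#' @param group_by (ERP) label column defining prediction groups.
#' @param ... unused.
#' @return `type = "class"`: integer vector of predicted targets (one per
#'   epoch, or per group for ERP, named by group). `type = "score"`: the
#'   score matrix.
#' @export
predict.beamformer <- function(object, newdata, type = c("class", "score"),
                               k_reps = NULL, discard_before_ms = 0,
                               group_by = "trial", ...) {
  type <- match.arg(type)
  ep <- newdata
  if (!identical(ep$layout$channel_names, object$channel_names)) {
    ep <- subset_epochs(ep, channels = object$channel_names)
  }
  if (object$paradigm == "ssvep") {
    ne <- dim(ep$data)[1]
    ids <- vapply(object$targets, `[[`, numeric(1), "target")
    sc <- matrix(NA_real_, ne, length(ids),
                 dimnames = list(NULL, paste0("target", ids)))
    for (e in seq_len(ne)) {
      M <- matrix(ep$data[e, , ], dim(ep$data)[2], dim(ep$data)[3])
      sc[e, ] <- vapply(object$targets, function(tg)
        score_epoch_target(object, M, tg, discard_before_ms), numeric(1))
    }
    if (type == "score") return(sc)
    ids[apply(sc, 1, which.max)]
  } else {
    groups <- ep$labels[[group_by]]
    gid <- unique(groups)
    cand <- sort(unique(ep$labels$target))
    w <- object$targets[[1]]$w
    sc <- matrix(NA_real_, length(gid), length(cand),
                 dimnames = list(gid, paste0("cand", cand)))
    for (g in seq_along(gid)) {
      in_g <- which(groups == gid[g])
      for (j in seq_along(cand)) {
        rows <- in_g[ep$labels$target[in_g] == cand[j]]
        if (!is.null(k_reps)) {
          if (length(rows) < k_reps)
            stop("insufficient repetitions for candidate ", cand[j],
                 " in group ", gid[g])
          rows <- rows[seq_len(k_reps)]
        }
        if (length(rows) == 0)
          stop("no epochs for candidate ", cand[j], " in group ", gid[g])
        avg <- apply(ep$data[rows, , , drop = FALSE], c(2, 3), mean)
        sc[g, j] <- sum(w * vec_cm(avg))
      }
    }
    if (type == "score") return(sc)
    out <- cand[apply(sc, 1, which.max)]
    names(out) <- gid
    out
  }
}
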