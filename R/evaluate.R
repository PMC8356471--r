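## Cross-validated decoding accuracy and greedy forward channel selection.

#' Confusion matrix from true/predicted target labels
#'
#' @param true,predicted vectors of target ids.
#' @param levels target id universe (default: union observed).
#' @return An object of class `confusion_matrix` (integer matrix, rows =
#'   true, columns = predicted) with an `accuracy` attribute
#'   (trace / total).
#' @export
confusion_matrix <- function(true, predicted, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(c(true, predicted)))
  m <- table(factor(true, levels), factor(predicted, levels))
  m <- unclass(as.matrix(m))
  structure(m, accuracy = sum(diag(m)) / sum(m), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> accuracy %.2f%% (%d/%d)\n",
              100 * attr(x, "accuracy"), sum(diag(unclass(x))),
              sum(unclass(x))))
  print(unclass(x))
  invisible(x)
}

## seeded stratified fold assignment: units of each class are shuffled and
## dealt round-robin over k folds
stratified_folds <- function(classes, k, seed = 1) {
  set.seed(seed)
  fold <- integer(length(classes))
  for (cl in unique(classes)) {
    i <- which(classes == cl)
    if (length(i) < k)
      stop("class ", cl, " has fewer units (", length(i),
           ") than folds (", k, ")")
    fold[i] <- (sample(seq_along(i)) %% k) + 1
  }
  fold
}

#' Cross-validated decoding accuracy
#'
#' Stratified k-fold cross-validation of the beamformer classifier: the
#' model is refit on k-1 folds and predicts the held-out fold; predictions
#' are accumulated into one confusion matrix, and the accuracy is the ratio
#' of correct predictions. SSVEP sessions are stratified at the epoch level
#' by gazed target; ERP sessions at the trial level by cued cross (so all
#' epochs of a trial stay in the same fold, avoiding leakage).
#'
#' @param epochs an [epoch_set].
#' @param paradigm `"ssvep"` or `"erp"`.
#' @param k_folds number of folds (5 for ERP decoding, 4 for speller
#'   channel selection, matching the respective protocols).
#' @param k_reps (ERP) stimulus repetitions per candidate at predict time;
#'   a vector evaluates every repetition count against the same fold fits
#'   and returns one accuracy (and confusion matrix) per entry.
#' @param alpha,channels,overlap passed to [beamformer()].
#' @param discard_before_ms (SSVEP) passed to [predict.beamformer()].
#' @param seed seed for the fold assignment.
#' @return list of class `bci_cv`: `confusion` (a [confusion_matrix], or a
#'   list of them for vector `k_reps`), `accuracy` (scalar or vector named
#'   by repetition count), `k_folds`.
#' @export
crossval_accuracy <- function(epochs, paradigm = c("ssvep", "erp"),
                              k_folds = if (match.arg(paradigm) == "erp")
                                5 else 4,
                              k_reps = NULL, alpha = 0.95, channels = NULL,
                              overlap = 0.5, discard_before_ms = 0,
                              seed = 1) {
  paradigm <- match.arg(paradigm)
  if (!is.null(channels))
    epochs <- subset_epochs(epochs, channels = channels)
  lab <- epochs$labels
  if (paradigm == "ssvep") {
    fold <- stratified_folds(lab$target, k_folds, seed)
    unit_true <- lab$target
  } else {
    trials <- unique(lab$trial)
    cued_of <- lab$cued[match(trials, lab$trial)]
    tf <- stratified_folds(cued_of, k_folds, seed)
    fold <- tf[match(lab$trial, trials)]
    unit_true <- cued_of
  }
  n_k <- if (is.null(k_reps)) 1L else length(k_reps)
  true_all <- integer(0)
  pred_all <- replicate(n_k, integer(0), simplify = FALSE)
  for (k in seq_len(k_folds)) {
    train <- subset_epochs(epochs, fold != k)
    test <- subset_epochs(epochs, fold == k)
    fit <- beamformer(train, paradigm, alpha = alpha, overlap = overlap)
    if (paradigm == "ssvep") {
      pred_all[[1]] <- c(pred_all[[1]],
                         predict(fit, test,
                                 discard_before_ms = discard_before_ms))
      true_all <- c(true_all, test$labels$target)
    } else {
      for (j in seq_len(n_k))
        pred_all[[j]] <- c(pred_all[[j]],
                           unname(predict(fit, test,
                                          k_reps = k_reps[j])))
      tt <- unique(test$labels$trial)
      true_all <- c(true_all,
                    test$labels$cued[match(tt, test$labels$trial)])
    }
  }
  cms <- lapply(pred_all, confusion_matrix, true = true_all,
                levels = sort(unique(unit_true)))
  acc <- vapply(cms, attr, numeric(1), "accuracy")
  if (n_k > 1) names(acc) <- paste0("k", k_reps)
  structure(list(confusion = if (n_k == 1) cms[[1]] else cms,
                 accuracy = acc, k_folds = k_folds),
            class = "bci_cv")
}

#' @export
print.bci_cv <- function(x, ...) {
  cat(sprintf("<bci_cv> %d-fold CV accuracy: %s\n", x$k_folds,
              paste(sprintf("%.2f%%", 100 * x$accuracy), collapse = ", ")))
  invisible(x)
}

#' Greedy forward channel selection
#'
#' Starting from the empty set, each iteration tentatively extends the
#' current selection with every remaining candidate channel, scores each
#' candidate set by cross-validated decoding accuracy, and keeps the best.
#' Selection stops when the score no longer strictly improves or reaches
#' 100%. The ERP score is the mean fivefold-CV accuracy over one to five
#' stimulus repetitions; the SSVEP score is the fourfold-CV accuracy.
#'
#' @param epochs an [epoch_set] containing all candidate channels.
#' @param candidates channel names to select from (default: all).
#' @param paradigm `"ssvep"` or `"erp"`.
#' @param max_channels optional cap on the selection size.
#' @param alpha,overlap,discard_before_ms,seed as in [crossval_accuracy()].
#' @return list of class `channel_selection`: `selected` (ordered names),
#'   `accuracy_trace` (score after each retained iteration),
#'   `termination_reason` (`"perfect"`, `"no_improvement"` or
#'   `"exhausted"`).
#' @export
greedy_forward_selection <- function(epochs, candidates = NULL,
                                     paradigm = c("ssvep", "erp"),
                                     max_channels = Inf, alpha = 0.95,
                                     overlap = 0.5, discard_before_ms = 0,
                                     seed = 1) {
  paradigm <- match.arg(paradigm)
  if (is.null(candidates)) candidates <- epochs$layout$channel_names
  score_set <- function(chs) {
    if (paradigm == "ssvep") {
      crossval_accuracy(epochs, "ssvep", k_folds = 4, alpha = alpha,
                        channels = chs, overlap = overlap,
                        discard_before_ms = discard_before_ms,
                        seed = seed)$accuracy
    } else {
      mean(crossval_accuracy(epochs, "erp", k_folds = 5, k_reps = 1:5,
                             alpha = alpha, channels = chs,
                             seed = seed)$accuracy)
    }
  }
  selected <- character(0)
  trace <- numeric(0)
  best <- -Inf
  reason <- "exhausted"
  while (length(selected) < min(length(candidates), max_channels)) {
    remaining <- setdiff(candidates, selected)
    scores <- vapply(remaining, function(ch) score_set(c(selected, ch)),
                     numeric(1))
    if (max(scores) <= best) { reason <- "no_improvement"; break }
    best <- max(scores)
    selected <- c(selected, remaining[which.max(scores)])
    trace <- c(trace, best)
    if (best >= 1) { reason <- "perfect"; break }
  }
  structure(list(selected = selected, accuracy_trace = trace,
                 termination_reason = reason),
            class = "channel_selection")
}

#' @export
print.channel_selection <- function(x, ...) {
  cat("<channel_selection> ", length(x$selected), " channel(s): ",
      paste(x$selected, collapse = ", "), "\n  score trace: ",
      paste(sprintf("%.1f%%", 100 * x$accuracy_trace), collapse = " -> "),
      " (", x$termination_reason, ")\n", sep = "")
  invisible(x)
}
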