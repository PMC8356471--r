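## Simulated real-time mind-spelling session, backspace correction logic,
## post hoc stimulation-length analysis and the end-to-end orchestration.

#' Spelling log
#'
#' Ordered record of a spelling session. Each selection holds the intended
#' and decoded target characters; a decoded backspace removes the last
#' character of the working text, any other character is appended. Session
#' accuracy is the fraction of correct selections.
#'
#' @param intended,decoded character vectors (per selection).
#' @param backspace_char the character playing the backspace role.
#' @param words optional target words (metadata).
#' @param scores optional per-selection score matrices/rows.
#' @return An object of class `spelling_log` with fields `selections`
#'   (data frame: `intended`, `decoded`, `correct`, `backspace`),
#'   `session_accuracy`, `words`.
#' @export
spelling_log <- function(intended, decoded, backspace_char = "<",
                         words = NULL, scores = NULL) {
  if (length(intended) != length(decoded))
    stop("intended and decoded must have equal length")
  sel <- data.frame(intended = intended, decoded = decoded,
                    correct = intended == decoded,
                    backspace = decoded == backspace_char,
                    stringsAsFactors = FALSE)
  structure(list(selections = sel,
                 session_accuracy = mean(sel$correct),
                 backspace_char = backspace_char, words = words,
                 scores = scores),
            class = "spelling_log")
}

#' @export
print.spelling_log <- function(x, ...) {
  n <- nrow(x$selections)
  cat(sprintf("<spelling_log> %d selections, %d correct: accuracy %.2f%%\n",
              n, sum(x$selections$correct), 100 * x$session_accuracy))
  invisible(x)
}

#' Reconstruct the working text from a selection log
#'
#' Pure left fold over the decoded selections: a backspace removes the last
#' character (no-op on empty text), anything else is appended.
#'
#' @param log a [spelling_log], or a character vector of decoded characters.
#' @param backspace_char backspace character when `log` is a plain vector.
#' @return The final text (single string).
#' @export
spelled_text <- function(log, backspace_char = "<") {
  decoded <- if (inherits(log, "spelling_log")) {
    backspace_char <- log$backspace_char
    log$selections$decoded
  } else log
  buf <- character(0)
  for (ch in decoded) {
    if (ch == backspace_char) {
      if (length(buf) > 0) buf <- buf[-length(buf)]
    } else buf <- c(buf, ch)
  }
  paste(buf, collapse = "")
}

## assign the word's characters (plus seeded fillers and one backspace) to
## the 9 targets of a layout; returns the per-target character vector
assign_characters <- function(word, layout, backspace_char = "<",
                              alphabet = letters) {
  chars <- unique(strsplit(word, "")[[1]])
  if (length(chars) > 8)
    stop("word has more than 8 unique characters")
  fill <- setdiff(alphabet, chars)
  n_fill <- 8 - length(chars)
  chars <- c(chars, sample(fill, n_fill), backspace_char)
  chars[sample.int(9)]                       # random placement on the grid
}

#' Simulated real-time spelling session
#'
#' For each word, its characters (with seeded random fillers up to eight,
#' plus a backspace icon) are assigned to the nine flickering targets. The
#' simulated user gazes the next needed character -- or the backspace after
#' a decoding error -- and for every selection one fresh 2-s stimulation
#' epoch is synthesized, band-pass filtered 4-40 Hz, downsampled to the
#' model rate and classified with the initial-150-ms segment discard. A
#' word ends when the working text has as many characters as the word.
#'
#' @param model a fitted ssvep [beamformer].
#' @param layout the [target_layout] (frequency-phase code of the targets).
#' @param sensor_layout the [sensor_layout] used by the generator.
#' @param words character vector of words to spell (lower-case letters, at
#'   most 8 unique characters each).
#' @param config an [ssvep_session_config] describing the spelling-session
#'   signal conditions (`trial_s` is forced to `stim_s`).
#' @param stim_s stimulation length in seconds (2 in the real-time
#'   protocol).
#' @param discard_before_ms online discard of the initial segments.
#' @param classify_fn optional override of the decoder: a function taking
#'   an [epoch_set] with one epoch and returning a target id (used to
#'   script decoding errors in tests).
#' @param seed RNG seed for character placement and signal generation.
#' @return A [spelling_log]; its `epochs` field holds the preprocessed 2-s
#'   epochs with gazed-target labels (for [posthoc_length_sweep()]).
#' @export
run_spelling_session <- function(model, layout, sensor_layout, words,
                                 config = NULL, stim_s = 2,
                                 discard_before_ms = 150,
                                 classify_fn = NULL, seed = 1) {
  if (is.null(config))
    config <- ssvep_session_config(layout = layout, reps = 1,
                                   trial_s = stim_s, seed = seed)
  set.seed(seed)
  backspace_char <- "<"
  intended <- decoded <- character(0)
  ep_list <- list()
  gazed <- integer(0)
  trial_seed <- seed
  for (word in words) {
    chars <- assign_characters(word, layout, backspace_char)
    target_of <- function(ch) which(chars == ch)
    goal <- strsplit(word, "")[[1]]
    working <- character(0)
    while (length(working) < length(goal)) {
      next_char <- if (identical(working,
                                 goal[seq_along(working)]))
        goal[length(working) + 1] else backspace_char
      tgt <- target_of(next_char)
      trial_seed <- trial_seed + 1
      cfg <- config
      cfg$layout <- layout; cfg$trial_s <- stim_s; cfg$seed <- trial_seed
      rec <- generate_ssvep_session(cfg, sensor_layout, schedule = tgt)
      rec <- bandpass_filter(rec, 4, 40)
      ep <- extract_epochs(rec, 0, stim_s * 1000)
      if (ep$fs_hz != model$fs_hz) ep <- downsample(ep, model$fs_hz)
      pred <- if (is.null(classify_fn))
        unname(predict(model, ep,
                       discard_before_ms = discard_before_ms))
      else classify_fn(ep)
      dec_char <- chars[pred]
      intended <- c(intended, next_char)
      decoded <- c(decoded, dec_char)
      ep_list[[length(ep_list) + 1]] <- ep
      gazed <- c(gazed, tgt)
      if (dec_char == backspace_char) {
        if (length(working) > 0) working <- working[-length(working)]
      } else working <- c(working, dec_char)
    }
  }
  log <- spelling_log(intended, decoded, backspace_char, words = words)
  log$final_texts <- NULL
  ## stack the per-selection epochs into one epoch_set for the length sweep
  if (length(ep_list) > 0) {
    d <- dim(ep_list[[1]]$data)
    all <- array(0, c(length(ep_list), d[2], d[3]))
    for (i in seq_along(ep_list)) all[i, , ] <- ep_list[[i]]$data[1, , ]
    log$epochs <- epoch_set(all, ep_list[[1]]$fs_hz, 0,
                            data.frame(trial = seq_along(gazed),
                                       target = gazed),
                            ep_list[[1]]$layout)
  }
  log
}

#' Post hoc stimulation-length analysis
#'
#' Re-classifies the spelling-session epochs after truncating each to its
#' initial `n` seconds, for `n` from 0.25 to 2 s in steps of 0.25 s,
#' and reports the decoding accuracy against the gazed targets per length.
#'
#' @param epochs an [epoch_set] of 2-s spelling epochs with `target` labels
#'   (the `epochs` field of a [spelling_log]).
#' @param model the trained ssvep [beamformer].
#' @param lengths_s truncation grid in seconds.
#' @param discard_before_ms the online discard rule (waived per epoch when
#'   it would leave no segment).
#' @return An object of class `length_sweep`: data frame with columns
#'   `length_s` and `accuracy`.
#' @export
posthoc_length_sweep <- function(epochs, model,
                                 lengths_s = seq(0.25, 2, by = 0.25),
                                 discard_before_ms = 150) {
  d <- dim(epochs$data)
  if (d[3] < max(lengths_s) * epochs$fs_hz)
    stop("epochs shorter than the longest truncation")
  acc <- vapply(lengths_s, function(len) {
    ns <- round(len * epochs$fs_hz)
    trunc <- epoch_set(epochs$data[, , seq_len(ns), drop = FALSE],
                       epochs$fs_hz, 0, epochs$labels, epochs$layout)
    pred <- predict(model, trunc, discard_before_ms = discard_before_ms)
    mean(pred == epochs$labels$target)
  }, numeric(1))
  structure(data.frame(length_s = lengths_s, accuracy = acc),
            class = c("length_sweep", "data.frame"))
}

#' Default end-to-end experiment configuration
#'
#' Study conditions of a full speller run: a 72-trial (9 targets x 8 cues)
#' 4-s training session, preprocessing to 150 Hz in the 4-40 Hz band,
#' optional greedy channel selection, beamformer training (alpha = 0.95),
#' a 2-s-per-selection spelling session and the post hoc length sweep.
#'
#' @param words words to spell.
#' @param select_channels run greedy forward channel selection (fourfold
#'   CV) before training.
#' @return nested configuration list.
#' @export
default_experiment_config <- function(words = c("ball", "tree", "house",
                                                "cloud", "stone"),
                                      select_channels = FALSE) {
  list(target_layout = default_target_layout(),
       sensor_layout = default_sensor_layout(),
       training = list(reps = 8, trial_s = 4),
       preprocess = list(band = c(4, 40), fs_new = 150),
       decoder = list(alpha = 0.95),
       select_channels = select_channels,
       spelling = list(words = words, stim_s = 2, discard_before_ms = 150))
}

#' Run the full simulated speller experiment
#'
#' Orchestrates the pipeline end to end: synthesize the training session,
#' preprocess (band-pass, 4-s epochs, downsample), optionally select
#' channels, train the nine frequency-phase beamformers, run the simulated
#' real-time spelling session, sweep stimulation lengths post hoc, and
#' collect a report. Fully seeded and deterministic.
#'
#' @param config configuration list (see [default_experiment_config()]).
#' @param seed master seed.
#' @param out_dir optional directory: writes `report.json`, `sweep.csv`,
#'   `confusion.csv` and `selections.csv`.
#' @return list of class `bci_report` with elements `training_trials`,
#'   `selected_channels`, `cv` (fourfold training CV), `spelling`
#'   ([spelling_log]), `sweep` ([posthoc_length_sweep] result), `seed`.
#' @export
run_full_experiment <- function(config = default_experiment_config(),
                                seed = 1, out_dir = NULL) {
  tl <- config$target_layout
  sl <- config$sensor_layout
  tr_cfg <- ssvep_session_config(layout = tl, reps = config$training$reps,
                                 trial_s = config$training$trial_s,
                                 seed = seed)
  rec <- generate_ssvep_session(tr_cfg, sl)
  rec <- bandpass_filter(rec, config$preprocess$band[1],
                         config$preprocess$band[2])
  ep <- extract_epochs(rec, 0, config$training$trial_s * 1000)
  ep <- downsample(ep, config$preprocess$fs_new)

  selection <- NULL
  channels <- ep$layout$channel_names
  if (isTRUE(config$select_channels)) {
    selection <- greedy_forward_selection(ep, paradigm = "ssvep",
                                          alpha = config$decoder$alpha,
                                          seed = seed)
    channels <- selection$selected
  }
  cv <- crossval_accuracy(ep, "ssvep", k_folds = 4,
                          alpha = config$decoder$alpha, channels = channels,
                          seed = seed)
  model <- beamformer(subset_epochs(ep, channels = channels), "ssvep",
                      alpha = config$decoder$alpha)

  sp_cfg <- tr_cfg
  sp_cfg$trial_s <- config$spelling$stim_s
  log <- run_spelling_session(model, tl, sl, config$spelling$words,
                              config = sp_cfg,
                              stim_s = config$spelling$stim_s,
                              discard_before_ms =
                                config$spelling$discard_before_ms,
                              seed = seed + 1000)
  sweep <- posthoc_length_sweep(log$epochs, model,
                                discard_before_ms =
                                  config$spelling$discard_before_ms)

  report <- structure(
    list(training_trials = nrow(ep$labels),
         selected_channels = channels, selection = selection, cv = cv,
         spelling = log, sweep = sweep, seed = seed),
    class = "bci_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sweep, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
    utils::write.csv(log$selections, file.path(out_dir, "selections.csv"),
                     row.names = FALSE)
    utils::write.csv(unclass(cv$confusion),
                     file.path(out_dir, "confusion.csv"))
    jsonlite::write_json(
      list(seed = seed, training_trials = report$training_trials,
           selected_channels = channels,
           training_cv_accuracy = cv$accuracy,
           session_accuracy = log$session_accuracy,
           selections = log$selections,
           sweep = as.data.frame(sweep)),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.bci_report <- function(x, ...) {
  cat(sprintf("<bci_report> seed %d: %d training trials, %d channel(s)\n",
              x$seed, x$training_trials, length(x$selected_channels)))
  cat(sprintf("  training fourfold CV accuracy: %.2f%%\n",
              100 * x$cv$accuracy))
  cat(sprintf("  spelling session accuracy: %.2f%% (%d selections)\n",
              100 * x$spelling$session_accuracy,
              nrow(x$spelling$selections)))
  cat("  length sweep accuracies:",
      paste(sprintf("%.0f%%", 100 * x$sweep$accuracy), collapse = " "),
      "\n")
  invisible(x)
}
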