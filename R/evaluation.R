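# Evaluation: KNN on output-neuron weight vectors, leave-one-subject-out
# cross-validation, feature- and decision-level fusion, accuracy/F1.

#' Evaluation parameters
#'
#' @param k Neighbour count for KNN; odd and >= 1 (default 3).
#' @param distance Distance metric on weight vectors (`"euclidean"` or
#'   `"manhattan"`).
#' @param fusion_mode One of `"feature"` (all 16 features in one reservoir),
#'   `"decision"` (per-subject choice between the facial-only and
#'   peripheral-only pipelines based on their accuracy on the training
#'   subjects), `"facial_only"`, `"peripheral_only"`.
#' @param pool_all Fit the spike-encoding receptive fields on all subjects
#'   (including the held-out one) instead of the training subjects only.
#'   The pooled variant mirrors a fit on the full cohort; the default avoids
#'   test-set leakage.
#' @param seed Integer seed governing reservoir construction per fold.
#' @return An object of class `eval_params`.
#' @export
eval_params <- function(k = 3L, distance = c("euclidean", "manhattan"),
                        fusion_mode = c("feature", "decision", "facial_only",
                                        "peripheral_only"),
                        pool_all = FALSE, seed = 1L) {
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L)
    stop_invalid("`k` must be odd and >= 1 (got %d)", k)
  structure(list(k = k, distance = match.arg(distance),
                 fusion_mode = match.arg(fusion_mode),
                 pool_all = isTRUE(pool_all),
                 seed = as.integer(seed)), class = "eval_params")
}

#' Classify a test output neuron by K nearest neighbours
#'
#' Majority label among the `k` training output neurons whose weight vectors
#' are closest to the test neuron's. Distance ties are broken by training
#' order; a (hypothetical) vote tie falls back to the single nearest
#' neighbour's label.
#'
#' @param test An `output_neuron` (its label, if any, is ignored).
#' @param training List of labelled `output_neuron`s, at least `k` of them.
#' @param params An [eval_params()].
#' @return Predicted label, `"low"` or `"high"`.
#' @export
knn_classify <- function(test, training, params = eval_params()) {
  if (length(training) < params$k)
    stop_invalid("need at least k = %d training neurons (got %d)",
                 params$k, length(training))
  tw <- test$weights
  d <- vapply(training, function(o) {
    if (params$distance == "euclidean") sqrt(sum((o$weights - tw)^2))
    else sum(abs(o$weights - tw))
  }, numeric(1))
  nn <- order(d, seq_along(d))[seq_len(params$k)]
  votes <- table(vapply(training[nn], `[[`, "", "label"))
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1L) top else training[[nn[1L]]]$label
}

#' Accuracy and F1 for a prediction vector
#'
#' @param predictions,labels Equal-length character vectors of `"low"`/
#'   `"high"` labels.
#' @param positive Positive class for F1 (default `"high"`).
#' @return List with `accuracy` (percent, 0-100), `f1`, and the 2 x 2
#'   `confusion` table (rows = truth, columns = prediction).
#' @export
compute_metrics <- function(predictions, labels, positive = "high") {
  if (length(predictions) == 0L || length(predictions) != length(labels))
    stop_invalid("predictions and labels must be non-empty and aligned")
  lv <- c("low", "high")
  confusion <- table(truth = factor(labels, lv),
                     prediction = factor(predictions, lv))
  acc <- 100 * sum(diag(confusion)) / sum(confusion)
  tp <- confusion[positive, positive]
  fp <- sum(confusion[, positive]) - tp
  fn <- sum(confusion[positive, ]) - tp
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  list(accuracy = acc, f1 = as.numeric(f1), confusion = confusion)
}

features_for_mode <- function(mode) {
  switch(mode,
         feature = valence_features(),
         facial_only = facial_features(),
         peripheral_only = peripheral_features(),
         stop_invalid("no fixed feature set for fusion mode `%s`", mode))
}

# One LOSO fold: fit encoders, build + STDP-train a fresh reservoir on the
# training rasters, create training output neurons, classify the test trials.
run_fold <- function(train_trials, test_trials, features, reservoir_params,
                     readout_params, ev, fold_seed, bank_trials = NULL) {
  bank <- fit_receptive_fields(if (is.null(bank_trials)) train_trials
                               else bank_trials, features = features)
  rp <- reservoir_params
  rp$seed <- fold_seed
  net <- build_reservoir(rp, features = features)
  train_rasters <- lapply(train_trials, encode_trial, bank = bank,
                          features = features)
  net <- train_unsupervised(net, train_rasters)
  train_neurons <- mapply(function(tr, ra)
    create_output_neuron(net, ra, label = tr$label, params = readout_params,
                         subject_id = tr$subject_id, trial_id = tr$trial_id),
    train_trials, train_rasters, SIMPLIFY = FALSE)
  vapply(test_trials, function(tr) {
    ra <- encode_trial(tr, bank, features = features)
    test_neuron <- create_output_neuron(net, ra, label = NULL,
                                        params = readout_params,
                                        subject_id = tr$subject_id,
                                        trial_id = tr$trial_id)
    knn_classify(test_neuron, train_neurons, ev)
  }, character(1))
}

subject_ids <- function(trials) vapply(trials, `[[`, "", "subject_id")

#' Leave-one-subject-out evaluation of the full pipeline
#'
#' For every subject in turn, all of that subject's trials are held out; the
#' receptive fields are fitted, a fresh reservoir is built and STDP-trained,
#' and training output neurons are created from the remaining subjects'
#' trials only. The held-out trials are then classified via test output
#' neurons and KNN. Per-subject and pooled accuracy/F1 are reported; totals
#' are computed over the pooled predictions.
#'
#' With `fusion_mode = "decision"` each fold first estimates, by an internal
#' leave-one-subject-out loop restricted to the training subjects, the
#' accuracy of the facial-only and peripheral-only pipelines, and classifies
#' the held-out subject with whichever modality scored higher (ties go to
#' facial).
#'
#' @param trials List of [labeled_trial()]s covering at least two subjects.
#' @param reservoir_params A [reservoir_params()].
#' @param readout_params A [readout_params()].
#' @param ev An [eval_params()].
#' @param verbose Print per-fold progress.
#' @return An object of class `eval_report`: `per_subject` data frame
#'   (`subject`, `n`, `accuracy`, `f1`, and for decision fusion the chosen
#'   `modality`), `total` metrics, pooled `confusion`, `predictions` data
#'   frame and the `fusion_mode`.
#' @export
loso_evaluate <- function(trials, reservoir_params = reservoir_params(),
                          readout_params = readout_params(),
                          ev = eval_params(), verbose = FALSE) {
  subj <- subject_ids(trials)
  subjects <- unique(subj)
  if (length(subjects) < 2L)
    stop_invalid("leave-one-subject-out needs >= 2 subjects (got %d)",
                 length(subjects))
  mode <- ev$fusion_mode
  preds <- data.frame(subject = character(0), trial = character(0),
                      label = character(0), prediction = character(0),
                      stringsAsFactors = FALSE)
  modality_choice <- character(0)
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    test_trials <- trials[subj == s]
    train_trials <- trials[subj != s]
    stopifnot(!s %in% subject_ids(train_trials))  # no-leakage assertion
    fold_seed <- derive_seed(ev$seed, 1000L + i)
    bank_trials <- if (ev$pool_all) trials else NULL
    if (mode == "decision") {
      inner_ev <- ev
      inner_acc <- vapply(c("facial_only", "peripheral_only"), function(m) {
        inner_ev$fusion_mode <- m
        inner_ev$seed <- derive_seed(ev$seed, 5000L + i)
        rep <- loso_evaluate(train_trials, reservoir_params, readout_params,
                             inner_ev, verbose = FALSE)
        rep$total$accuracy
      }, numeric(1))
      chosen <- if (inner_acc[["peripheral_only"]] > inner_acc[["facial_only"]])
        "peripheral_only" else "facial_only"
      modality_choice <- c(modality_choice, chosen)
      p <- run_fold(train_trials, test_trials, features_for_mode(chosen),
                    reservoir_params, readout_params, ev, fold_seed,
                    bank_trials)
    } else {
      p <- run_fold(train_trials, test_trials, features_for_mode(mode),
                    reservoir_params, readout_params, ev, fold_seed,
                    bank_trials)
    }
    preds <- rbind(preds, data.frame(
      subject = s, trial = vapply(test_trials, `[[`, "", "trial_id"),
      label = vapply(test_trials, `[[`, "", "label"), prediction = p,
      stringsAsFactors = FALSE))
    if (verbose)
      message(sprintf("fold %d/%d (subject %s): %d/%d correct", i,
                      length(subjects), s,
                      sum(p == vapply(test_trials, `[[`, "", "label")),
                      length(test_trials)))
  }
  per_subject <- do.call(rbind, lapply(seq_along(subjects), function(i) {
    s <- subjects[i]
    sel <- preds$subject == s
    m <- compute_metrics(preds$prediction[sel], preds$label[sel])
    data.frame(subject = s, n = sum(sel), accuracy = m$accuracy, f1 = m$f1,
               stringsAsFactors = FALSE)
  }))
  if (mode == "decision") per_subject$modality <- modality_choice
  total <- compute_metrics(preds$prediction, preds$label)
  structure(list(per_subject = per_subject,
                 total = list(accuracy = total$accuracy, f1 = total$f1),
                 confusion = total$confusion, predictions = preds,
                 fusion_mode = mode),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> fusion mode: %s\n", x$fusion_mode))
  print(x$per_subject, row.names = FALSE)
  cat(sprintf("Total: accuracy %.2f%%, F1 %.3f (%d trials)\n",
              x$total$accuracy, x$total$f1, nrow(x$predictions)))
  invisible(x)
}
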