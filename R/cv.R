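#' Cross-validation configuration
#'
#' @param folds Number of folds (default 10).
#' @param repeats Number of repetitions with fresh random partitions
#'   (default 10).
#' @param stratified Preserve class balance within folds (default `TRUE`).
#' @param seed Integer seed controlling all partitions.
#' @return A `cv_config` object.
#' @export
cv_config <- function(folds = 10L, repeats = 10L, stratified = TRUE,
                      seed = 1L) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 stratified = isTRUE(stratified), seed = as.integer(seed)),
            class = "cv_config")
}

#' Assemble the per-trial feature inputs for classification
#'
#' Computes, once per participant, everything the cross-validation engine
#' needs: per-band per-trial EEG covariance matrices (the filter bank applied
#' to each epoch; CSP models are later fitted per fold from training-trial
#' covariances only) and the per-trial fNIRS temporal-window features (a
#' fixed per-trial transform involving no fitting, hence leakage-free to
#' precompute).
#'
#' @param eeg_epochs EEG `epoch_set` (0-10 s task epochs).
#' @param hbr_epochs,hbo_epochs Baseline-corrected hemoglobin `epoch_set`s.
#' @param bank Filter bank (default [filter_bank()]).
#' @param windows fNIRS temporal windows (default 0-5/5-10/10-15 s).
#' @return A `trial_set` object.
#' @export
prepare_trials <- function(eeg_epochs, hbr_epochs, hbo_epochs,
                           bank = filter_bank(),
                           windows = list(c(0, 5), c(5, 10), c(10, 15))) {
  stopifnot(identical(eeg_epochs$labels, hbr_epochs$labels),
            identical(eeg_epochs$labels, hbo_epochs$labels))
  nirs <- nirs_features(hbr_epochs, hbo_epochs, windows)
  structure(list(labels = eeg_epochs$labels,
                 band_covs = band_covariances(eeg_epochs, bank),
                 bank = bank,
                 eeg_channels = eeg_epochs$channel_labels,
                 nirs_x = nirs,
                 nirs_provenance = attr(nirs, "provenance"),
                 nirs_channels = hbr_epochs$channel_labels),
            class = "trial_set")
}

#' @export
print.trial_set <- function(x, ...) {
  cat(sprintf("<trial_set> %d trials, %d EEG channels x %d bands, %d fNIRS features\n",
              length(x$labels), length(x$eeg_channels), length(x$band_covs),
              ncol(x$nirs_x)))
  invisible(x)
}

# restrict a trial_set to EEG channel / fNIRS channel subsets
subset_trial_set <- function(trials, eeg_channels = NULL, nirs_channels = NULL) {
  if (!is.null(eeg_channels)) {
    idx <- match(eeg_channels, trials$eeg_channels)
    if (anyNA(idx)) stop("unknown EEG channel(s): ",
                         paste(eeg_channels[is.na(idx)], collapse = ", "))
    trials$band_covs <- lapply(trials$band_covs,
                               function(a) a[idx, idx, , drop = FALSE])
    trials$eeg_channels <- trials$eeg_channels[idx]
  }
  if (!is.null(nirs_channels)) {
    if (is.numeric(nirs_channels))
      nirs_channels <- trials$nirs_channels[nirs_channels]
    keep <- trials$nirs_provenance$channel %in% nirs_channels
    if (!any(keep)) stop("no fNIRS features left after channel selection")
    trials$nirs_x <- trials$nirs_x[, keep, drop = FALSE]
    trials$nirs_provenance <- trials$nirs_provenance[keep, ]
    trials$nirs_channels <- intersect(trials$nirs_channels, nirs_channels)
  }
  trials
}

# fit CSP (per band) + base/meta classifiers for the three class pairs on the
# training trials only; returns per-pair models plus feature builders
fit_fold <- function(trials, train_idx, mode, classes, n_stack_folds = 5L) {
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  labels <- trials$labels
  lapply(pairs, function(pair) {
    tr_pair <- train_idx[labels[train_idx] %in% pair]
    y <- factor(labels[tr_pair], levels = pair)
    csp_models <- NULL
    eeg_feats <- function(idx) NULL
    if (mode != "nirs_only") {
      csp_models <- lapply(trials$band_covs, function(covs) {
        c_a <- class_mean_cov(covs, tr_pair[y == pair[1]])
        c_b <- class_mean_cov(covs, tr_pair[y == pair[2]])
        csp_from_cov(c_a, c_b, class_pair = pair,
                     channel_labels = trials$eeg_channels)
      })
      eeg_feats <- function(idx) {
        do.call(cbind, lapply(names(trials$band_covs), function(bn)
          logvar_from_covs(csp_models[[bn]]$W, trials$band_covs[[bn]], idx)))
      }
    }
    nirs_feats <- function(idx) trials$nirs_x[idx, , drop = FALSE]

    if (mode == "hybrid") {
      entry <- train_binary_hybrid(eeg_feats(tr_pair), nirs_feats(tr_pair),
                                   y, pair, n_stack_folds)
    } else if (mode == "eeg_only") {
      entry <- structure(list(eeg_model = slda_fit(eeg_feats(tr_pair), y),
                              nirs_model = NULL, meta_model = NULL,
                              class_pair = pair), class = "hybrid_pair")
    } else {
      entry <- structure(list(eeg_model = NULL,
                              nirs_model = slda_fit(nirs_feats(tr_pair), y),
                              meta_model = NULL, class_pair = pair),
                         class = "hybrid_pair")
    }
    list(pair = pair, entry = entry, csp_models = csp_models,
         eeg_feats = eeg_feats, nirs_feats = nirs_feats)
  })
}

predict_fold <- function(fits, test_idx, mode) {
  decisions <- lapply(fits, function(f)
    hybrid_pair_decision(f$entry,
                         if (mode != "nirs_only") f$eeg_feats(test_idx) else NULL,
                         if (mode != "eeg_only") f$nirs_feats(test_idx) else NULL,
                         mode))
  pairs <- lapply(fits, `[[`, "pair")
  list(predicted = ovo_predict(decisions, pairs), decisions = decisions,
       pairs = pairs)
}

# seeded stratified partitions: one fold-assignment vector per repeat
make_partitions <- function(labels, cv) {
  withr::with_seed(cv$seed, {
    lapply(seq_len(cv$repeats), function(r) {
      fold <- integer(length(labels))
      if (cv$stratified) {
        for (cl in unique(labels)) {
          idx <- sample(which(labels == cl))
          fold[idx] <- rep_len(seq_len(cv$folds), length(idx))
        }
      } else {
        fold <- rep_len(seq_len(cv$folds), length(labels))[sample(length(labels))]
      }
      fold
    })
  })
}

#' Repeated stratified cross-validation of the classification pipeline
#'
#' For each repeat, a fresh seeded stratified partition of the trials is
#' drawn; within each fold, all fitting (per-band CSP spatial filters, the
#' modality classifiers and the meta-classifier) uses training trials only,
#' and accuracy is measured on the held-out trials. Accuracies are averaged
#' per fold, then per repeat; the reported standard deviation is across the
#' repeat means.
#'
#' @param trials A `trial_set` from [prepare_trials()].
#' @param mode `"hybrid"` (EEG + fNIRS meta-classification), `"eeg_only"` or
#'   `"nirs_only"`.
#' @param cv A [cv_config()].
#' @param eeg_channels,nirs_channels Optional channel subsets.
#' @param classes Classes entering the one-versus-one problem; the default
#'   uses all three, a length-2 vector gives a binary problem (used by the
#'   sensor-selection criteria).
#' @return A `cv_result`: per-repeat per-fold accuracies (percent), their
#'   mean and standard deviation, the 3x3 confusion matrix (per-repeat
#'   average, rows = true class), and per-pair binary accuracies.
#' @export
cross_validate <- function(trials, mode = c("hybrid", "eeg_only", "nirs_only"),
                           cv = cv_config(),
                           eeg_channels = NULL, nirs_channels = NULL,
                           classes = c("MA", "MI", "IS")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trials, "trial_set"), inherits(cv, "cv_config"))
  trials <- subset_trial_set(trials, eeg_channels, nirs_channels)
  keep <- which(trials$labels %in% classes)
  labels <- trials$labels[keep]
  if (min(table(labels)) < cv$folds)
    stop("each class needs at least `folds` trials for stratified CV")
  partitions <- make_partitions(labels, cv)

  per_fold <- list()
  confusion <- matrix(0, length(classes), length(classes),
                      dimnames = list(classes, classes))
  pair_hits <- pair_tot <- NULL
  for (r in seq_len(cv$repeats)) {
    fold <- partitions[[r]]
    for (f in seq_len(cv$folds)) {
      test_loc <- which(fold == f)
      train_loc <- which(fold != f)
      fits <- fit_fold_on(trials, keep[train_loc], mode, classes)
      pred <- predict_fold(fits, keep[test_loc], mode)
      truth <- labels[test_loc]
      acc <- 100 * mean(pred$predicted == truth)
      per_fold[[length(per_fold) + 1]] <-
        tibble::tibble(repeat_id = r, fold = f, accuracy = acc)
      for (i in seq_along(truth))
        confusion[truth[i], pred$predicted[i]] <-
          confusion[truth[i], pred$predicted[i]] + 1
      # per-pair binary accuracy on held-out trials of the pair's classes
      if (is.null(pair_hits)) {
        pair_hits <- pair_tot <- numeric(length(pred$pairs))
        names(pair_hits) <- names(pair_tot) <-
          vapply(pred$pairs, paste, character(1), collapse = "-")
      }
      for (j in seq_along(pred$pairs)) {
        in_pair <- truth %in% pred$pairs[[j]]
        if (!any(in_pair)) next
        d <- pred$decisions[[j]][in_pair]
        lab <- pred$pairs[[j]][(d > 0) + 1L]
        pair_hits[j] <- pair_hits[j] + sum(lab == truth[in_pair])
        pair_tot[j] <- pair_tot[j] + sum(in_pair)
      }
    }
  }
  folds_tbl <- dplyr::bind_rows(per_fold)
  repeat_means <- dplyr::summarise(dplyr::group_by(folds_tbl, .data$repeat_id),
                                   accuracy = mean(.data$accuracy))
  structure(list(
    folds = folds_tbl,
    mean = mean(repeat_means$accuracy),
    sd = stats::sd(repeat_means$accuracy),
    confusion = confusion / cv$repeats,
    pair_accuracy = tibble::tibble(pair = names(pair_hits),
                                   accuracy = 100 * pair_hits / pair_tot),
    mode = mode, classes = classes, cv = cv,
    n_trials = length(labels)), class = "cv_result")
}

# wrapper so fit_fold() sees global trial indices
fit_fold_on <- function(trials, train_idx, mode, classes) {
  fit_fold(trials, train_idx, mode, classes)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d-class: %.1f +/- %.1f %% (%d x %d-fold CV, %d trials)\n",
              x$mode, length(x$classes), x$mean,
              ifelse(is.na(x$sd), 0, x$sd), x$cv$repeats, x$cv$folds,
              x$n_trials))
  invisible(x)
}

#' Binary criterion accuracy for sensor selection
#'
#' Cross-validated accuracy of a single class pair under one modality,
#' the criterion used by the channel- and SD-pair-selection searches.
#'
#' @param trials A `trial_set`.
#' @param pair Character vector of the two classes (e.g. `c("MI", "IS")`).
#' @param modality `"eeg_only"`, `"nirs_only"` or `"hybrid"`.
#' @param cv A [cv_config()].
#' @param eeg_channels,nirs_channels Optional channel subsets.
#' @return Mean accuracy in percent.
#' @export
pair_accuracy <- function(trials, pair, modality = "eeg_only",
                          cv = cv_config(), eeg_channels = NULL,
                          nirs_channels = NULL) {
  cross_validate(trials, mode = modality, cv = cv,
                 eeg_channels = eeg_channels, nirs_channels = nirs_channels,
                 classes = pair)$mean
}
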