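# deterministic stratified fold assignment (round-robin within class, in
# index order) used for internal stacking splits: no RNG, so refitting the
# same training trials always yields bit-identical models
stacking_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
  }
  fold
}

#' Train one hybrid class-pair entry (EEG + fNIRS + meta-classifier)
#'
#' Fits a shrinkage-LDA classifier per modality, obtains out-of-fold decision
#' values from an internal stratified split of the training trials (stacking,
#' so the meta-classifier never sees optimistic in-sample decision values),
#' fits the meta shrinkage-LDA on the stacked 2-dimensional decision values,
#' and refits the base classifiers on all training trials.
#'
#' @param eeg_x,nirs_x Trials x features matrices for the two modalities
#'   (aligned rows, training trials of the two classes only).
#' @param labels Class labels (two classes).
#' @param class_pair Character vector `c(first, second)`; decision values are
#'   positive for the second class.
#' @param n_stack_folds Internal stacking folds (default 5).
#' @return A `hybrid_pair` with `eeg_model`, `nirs_model`, `meta_model`.
#' @export
train_binary_hybrid <- function(eeg_x, nirs_x, labels, class_pair = NULL,
                                n_stack_folds = 5L) {
  labels <- as.character(labels)
  if (is.null(class_pair)) class_pair <- unique(labels)
  stopifnot(length(class_pair) == 2, all(labels %in% class_pair))
  labels <- factor(labels, levels = class_pair)
  k <- min(n_stack_folds, min(table(labels)))
  fold <- stacking_folds(as.character(labels), k)
  d_eeg <- d_nirs <- numeric(length(labels))
  for (f in seq_len(k)) {
    tr <- fold != f
    m_e <- slda_fit(eeg_x[tr, , drop = FALSE], labels[tr])
    m_n <- slda_fit(nirs_x[tr, , drop = FALSE], labels[tr])
    d_eeg[!tr] <- predict(m_e, eeg_x[!tr, , drop = FALSE])
    d_nirs[!tr] <- predict(m_n, nirs_x[!tr, , drop = FALSE])
  }
  meta <- slda_fit(cbind(eeg = d_eeg, nirs = d_nirs), labels)
  structure(list(eeg_model = slda_fit(eeg_x, labels),
                 nirs_model = slda_fit(nirs_x, labels),
                 meta_model = meta, class_pair = class_pair),
            class = "hybrid_pair")
}

# decision values of one pair entry for new trials under a given mode
hybrid_pair_decision <- function(entry, eeg_x, nirs_x,
                                 mode = c("hybrid", "eeg_only", "nirs_only")) {
  mode <- match.arg(mode)
  if (mode == "eeg_only") return(predict(entry$eeg_model, eeg_x))
  if (mode == "nirs_only") return(predict(entry$nirs_model, nirs_x))
  d <- cbind(predict(entry$eeg_model, eeg_x),
             predict(entry$nirs_model, nirs_x))
  predict(entry$meta_model, d)
}

#' One-versus-one majority-vote prediction
#'
#' Each class pair's decision value casts one vote; the class with the most
#' votes wins. A 1-1-1 cyclic tie is broken deterministically in favor of the
#' class whose winning vote has the largest absolute decision value.
#'
#' @param decisions Named list of numeric decision-value vectors, one per
#'   class pair; each name is ignored, the pair is taken from the
#'   `class_pair` attribute or the `pairs` argument.
#' @param pairs List of `c(first, second)` character vectors aligned with
#'   `decisions`; positive decision means the second class.
#' @return Character vector of predicted classes.
#' @export
ovo_predict <- function(decisions, pairs) {
  stopifnot(length(decisions) == length(pairs), length(pairs) >= 1)
  n <- length(decisions[[1]])
  classes <- unique(unlist(pairs))
  votes <- matrix(0L, n, length(classes), dimnames = list(NULL, classes))
  margin <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  for (j in seq_along(pairs)) {
    d <- decisions[[j]]
    winner <- pairs[[j]][(d > 0) + 1L]
    for (i in seq_len(n)) {
      votes[i, winner[i]] <- votes[i, winner[i]] + 1L
      margin[i, winner[i]] <- margin[i, winner[i]] + abs(d[i])
    }
  }
  vapply(seq_len(n), function(i) {
    top <- which(votes[i, ] == max(votes[i, ]))
    if (length(top) == 1L) return(classes[top])
    classes[top[which.max(margin[i, top])]]       # cyclic tie: largest margin
  }, character(1))
}
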