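#' Sequential backward selection of EEG channels
#'
#' Greedy backward elimination under a binary criterion (default MI vs. IS
#' accuracy): starting from all channels, the channel whose removal maximizes
#' the criterion's cross-validated accuracy is dropped at each step, down to
#' `stop` channels (CSP needs at least two). The full per-size trace is
#' returned.
#'
#' @param trials A `trial_set` for one participant.
#' @param criterion_pair Class pair defining the criterion accuracy.
#' @param stop Smallest channel count to reach (>= 2).
#' @param cv A [cv_config()] for the criterion evaluations.
#' @param modality Modality used for the criterion (default `"eeg_only"`).
#' @return A `selection_result` with a `trace` tibble (size, channels,
#'   accuracy) and the chosen final subset.
#' @export
sbs_channels <- function(trials, criterion_pair = c("MI", "IS"), stop = 2L,
                         cv = cv_config(), modality = "eeg_only") {
  stopifnot(inherits(trials, "trial_set"))
  if (stop < 2) stop("CSP filters require at least two EEG channels")
  current <- trials$eeg_channels
  if (length(current) < stop) stop("fewer channels available than `stop`")
  acc_full <- pair_accuracy(trials, criterion_pair, modality, cv,
                            eeg_channels = current)
  trace <- list(tibble::tibble(size = length(current),
                               channels = list(current),
                               accuracy = acc_full))
  while (length(current) > stop) {
    accs <- vapply(seq_along(current), function(i)
      pair_accuracy(trials, criterion_pair, modality, cv,
                    eeg_channels = current[-i]), numeric(1))
    drop_i <- which.max(accs)
    current <- current[-drop_i]
    trace[[length(trace) + 1]] <- tibble::tibble(
      size = length(current), channels = list(current),
      accuracy = accs[drop_i])
  }
  structure(list(trace = dplyr::bind_rows(trace), chosen = current,
                 criterion_pair = criterion_pair, method = "sbs"),
            class = "selection_result")
}

#' Exhaustive evaluation of all EEG channel pairs
#'
#' Evaluates every two-channel combination under the criterion pair, for one
#' participant or a list of participants, ranked by the mean criterion
#' accuracy across participants.
#'
#' @param trials A `trial_set` or a list of them (one per participant).
#' @param criterion_pair Class pair (default MI vs. IS).
#' @param cv A [cv_config()].
#' @param modality Criterion modality (default `"eeg_only"`).
#' @return A `selection_result`; `trace` has one row per channel pair with
#'   per-participant accuracies (list column) and their mean, sorted
#'   decreasing.
#' @export
exhaustive_pairs <- function(trials, criterion_pair = c("MI", "IS"),
                             cv = cv_config(), modality = "eeg_only") {
  if (inherits(trials, "trial_set")) trials <- list(trials)
  chans <- trials[[1]]$eeg_channels
  if (length(chans) < 2) stop("need at least two EEG channels")
  pairs <- utils::combn(chans, 2, simplify = FALSE)
  rows <- lapply(pairs, function(p) {
    accs <- vapply(trials, function(tr)
      pair_accuracy(tr, criterion_pair, modality, cv, eeg_channels = p),
      numeric(1))
    tibble::tibble(channels = list(p),
                   label = paste(p, collapse = "-"),
                   accuracy = mean(accs), per_participant = list(accs))
  })
  trace <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$accuracy))
  structure(list(trace = trace, chosen = trace$channels[[1]],
                 criterion_pair = criterion_pair, method = "exhaustive_pairs"),
            class = "selection_result")
}

#' Common sensor subset across participants
#'
#' Given per-participant criterion accuracies over the same candidate
#' subsets, returns the size-`m` subset maximizing the cross-participant mean
#' accuracy.
#'
#' @param results Tibble with columns `participant`, `channels` (list column)
#'   and `accuracy` — e.g. stacked `trace`s of per-participant searches.
#' @param m Subset size wanted.
#' @return Character vector of the chosen channel labels.
#' @export
common_subset <- function(results, m) {
  stopifnot(all(c("participant", "channels", "accuracy") %in% names(results)))
  results$key <- vapply(results$channels,
                        function(ch) paste(sort(ch), collapse = "|"),
                        character(1))
  results$size <- lengths(results$channels)
  sub <- results[results$size == m, ]
  if (nrow(sub) == 0) stop("no candidate subsets of size ", m)
  n_participants <- length(unique(sub$participant))
  means <- dplyr::summarise(dplyr::group_by(sub, .data$key),
                            accuracy = mean(.data$accuracy),
                            n = dplyr::n(),
                            channels = .data$channels[1])
  means <- means[means$n == n_participants, ]  # evaluated by everyone
  if (nrow(means) == 0) stop("candidate subsets are inconsistent across participants")
  means$channels[[which.max(means$accuracy)]]
}

#' Default fNIRS source-detector pair arrangements
#'
#' Plausible lattice arrangements of 1 to 6 source-detector pairs over the 16
#' prefrontal channels, including the left- and right-DLPFC-centered two-pair
#' options (channels 5/10/11/16 and 1/6/7/12). Synthetic stand-ins for real
#' optode-geometry tables, shipped as a YAML fixture.
#'
#' @return Tibble with columns `name`, `n_pairs`, `channels` (list column of
#'   channel indices).
#' @export
default_sd_arrangements <- function() {
  path <- system.file("extdata", "sd_arrangements_synthetic.yaml",
                      package = "hybridbci")
  raw <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(raw$arrangements, function(a)
    tibble::tibble(name = a$name, n_pairs = a$n_pairs,
                   channels = list(as.integer(a$channels)))))
}

#' Search over source-detector pair arrangements
#'
#' Evaluates each arrangement's induced fNIRS channel set under a binary
#' criterion (default MA vs. IS, fNIRS only), flags arrangements below the
#' effective-BCI threshold, and reports the best arrangement per pair count.
#'
#' @param trials A `trial_set` or list of them (participants).
#' @param arrangements Tibble as from [default_sd_arrangements()].
#' @param criterion_pair Class pair (default MA vs. IS).
#' @param cv A [cv_config()].
#' @param threshold Effective-BCI accuracy threshold in percent (default 70).
#' @return A `selection_result`; `trace` has one row per arrangement with the
#'   mean and sd of the criterion accuracy across participants, a
#'   `meets_threshold` flag and a `best_of_size` flag.
#' @export
sd_pair_search <- function(trials, arrangements = default_sd_arrangements(),
                           criterion_pair = c("MA", "IS"),
                           cv = cv_config(), threshold = 70) {
  if (inherits(trials, "trial_set")) trials <- list(trials)
  if (nrow(arrangements) == 0) stop("empty arrangement list")
  n_ch <- length(trials[[1]]$nirs_channels)
  rows <- lapply(seq_len(nrow(arrangements)), function(i) {
    ch <- arrangements$channels[[i]]
    if (any(ch < 1 | ch > n_ch))
      stop(sprintf("arrangement '%s' references missing channels",
                   arrangements$name[i]))
    accs <- vapply(trials, function(tr)
      pair_accuracy(tr, criterion_pair, "nirs_only", cv, nirs_channels = ch),
      numeric(1))
    tibble::tibble(name = arrangements$name[i],
                   n_pairs = arrangements$n_pairs[i],
                   channels = list(ch), accuracy = mean(accs),
                   sd = if (length(accs) > 1) stats::sd(accs) else NA_real_,
                   per_participant = list(accs))
  })
  trace <- dplyr::bind_rows(rows)
  trace$meets_threshold <- trace$accuracy >= threshold
  trace <- dplyr::arrange(trace, .data$n_pairs, dplyr::desc(.data$accuracy))
  trace$best_of_size <- !duplicated(trace$n_pairs)
  best <- dplyr::arrange(trace, dplyr::desc(.data$accuracy))
  structure(list(trace = trace, chosen = best$channels[[1]],
                 chosen_name = best$name[1],
                 criterion_pair = criterion_pair, threshold = threshold,
                 method = "sd_pair_search"),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s under %s criterion\n", x$method,
              paste(x$criterion_pair, collapse = " vs ")))
  print(x$trace, n = 10)
  invisible(x)
}
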