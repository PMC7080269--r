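toy_select_set <- function(seed = 21) {
  eeg <- make_toy_epochs(n_per_class = 10, channels = c("C3", "Cz", "C4", "CP4"),
                         classes = c("MI", "IS"), b_scale = 0.4,
                         effect_channels = c("C3", "Cz"), seed = seed)
  ma <- make_toy_epochs(n_per_class = 10, channels = c("C3", "Cz", "C4", "CP4"),
                        classes = c("MA", "MA"), b_scale = 1, seed = seed + 1)
  labels <- c(eeg$labels, ma$labels[1:10])
  data <- array(0, dim = c(30, 4, dim(eeg$data)[3]))
  data[1:20, , ] <- eeg$data
  data[21:30, , ] <- ma$data[1:10, , ]
  eeg_all <- hybridbci:::new_epoch_set(data, labels, eeg$t, eeg$fs, "EEG",
                                       eeg$channel_labels)
  hbr <- make_toy_hb(labels, n_channels = 16, shift_class = "MA", sign = -1,
                     seed = seed + 2)
  hbo <- make_toy_hb(labels, n_channels = 16, shift_class = "MA", sign = 1,
                     seed = seed + 3)
  prepare_trials(eeg_all, hbr, hbo)
}

fast_cv <- cv_config(folds = 5, repeats = 1, seed = 2)

test_that("backward selection records the full per-size trace", {
  tr <- toy_select_set()
  sel <- sbs_channels(tr, stop = 2, cv = fast_cv)
  expect_s3_class(sel, "selection_result")
  expect_equal(sel$trace$size, 4:2)
  expect_length(sel$chosen, 2)
  expect_true(all(sel$chosen %in% tr$eeg_channels))
  # chosen channels must come from the previous step's subset (nesting)
  for (i in 2:nrow(sel$trace))
    expect_true(all(sel$trace$channels[[i]] %in% sel$trace$channels[[i - 1]]))
})

test_that("backward selection with start equal to stop is the identity", {
  tr <- toy_select_set()
  sub <- hybridbci:::subset_trial_set(tr, eeg_channels = c("C3", "Cz"))
  sel <- sbs_channels(sub, stop = 2, cv = fast_cv)
  expect_equal(nrow(sel$trace), 1)
  expect_setequal(sel$chosen, c("C3", "Cz"))
  expect_error(sbs_channels(tr, stop = 1, cv = fast_cv), "at least two")
})

test_that("exhaustive pair search enumerates all combinations", {
  tr <- toy_select_set()
  sel <- exhaustive_pairs(tr, cv = fast_cv)
  expect_equal(nrow(sel$trace), choose(4, 2))
  expect_true(all(diff(sel$trace$accuracy) <= 1e-9))   # sorted decreasing
  sub <- hybridbci:::subset_trial_set(tr, eeg_channels = c("C3", "Cz"))
  sel2 <- exhaustive_pairs(sub, cv = fast_cv)
  expect_equal(nrow(sel2$trace), 1)
})

test_that("planted informative channels win the pair ranking", {
  tr <- toy_select_set()
  sel <- exhaustive_pairs(tr, cv = fast_cv)
  expect_setequal(sel$chosen, c("C3", "Cz"))
  sbs <- sbs_channels(tr, stop = 2, cv = fast_cv)
  # the exhaustive best is an upper bound on the greedy result
  sbs_final_acc <- sbs$trace$accuracy[nrow(sbs$trace)]
  expect_lte(sbs_final_acc, sel$trace$accuracy[1] + 1e-9)
})

test_that("the common subset maximizes the cross-participant mean", {
  results <- tibble::tibble(
    participant = rep(c("P1", "P2"), each = 3),
    channels = rep(list(c("C3", "Cz"), c("C3", "C4"), c("Cz", "C4")), 2),
    accuracy = c(90, 80, 70,   60, 85, 75))
  # brute force: mean accuracies are 75, 82.5, 72.5
  expect_setequal(common_subset(results, 2), c("C3", "C4"))
  # single participant: that participant's best subset
  expect_setequal(common_subset(results[1:3, ], 2), c("C3", "Cz"))
  # identical rankings: the shared top subset
  res2 <- results; res2$accuracy <- rep(c(90, 80, 70), 2)
  expect_setequal(common_subset(res2, 2), c("C3", "Cz"))
  expect_error(common_subset(results, 5), "no candidate subsets")
})

test_that("SD arrangement search evaluates induced channel sets", {
  tr <- toy_select_set()
  arr <- default_sd_arrangements()
  expect_true(all(lengths(arr$channels[arr$n_pairs == 2]) == 4))
  expect_equal(length(arr$channels[arr$name == "full-6pair"][[1]]), 16)
  sel <- sd_pair_search(tr, arr[arr$n_pairs <= 2, ], cv = fast_cv)
  expect_true(all(c("meets_threshold", "best_of_size") %in% names(sel$trace)))
  expect_equal(sum(sel$trace$best_of_size), 2)  # one best per pair count
  expect_error(sd_pair_search(tr, arr[0, ], cv = fast_cv), "empty")
  bad <- tibble::tibble(name = "bad", n_pairs = 1, channels = list(c(40L)))
  expect_error(sd_pair_search(tr, bad, cv = fast_cv), "missing channels")
})

test_that("arrangements covering the planted response rank higher", {
  # plant the MA hemodynamic response only in the left-DLPFC channels
  labels <- rep(c("MA", "IS"), each = 12)
  hbr <- make_toy_hb(labels, n_channels = 16, shift_class = "MA", sign = -1,
                     shift = 0, seed = 31)
  hbo <- make_toy_hb(labels, n_channels = 16, shift_class = "MA", sign = 1,
                     shift = 0, seed = 32)
  bump_ch <- c(5, 10, 11, 16)
  bump <- pmax(0, sin(pi * pmax(hbo$t, 0) / max(hbo$t)))
  for (i in which(labels == "MA")) {
    for (j in bump_ch) {
      hbo$data[i, j, ] <- hbo$data[i, j, ] + bump
      hbr$data[i, j, ] <- hbr$data[i, j, ] - 0.4 * bump
    }
  }
  eeg <- make_toy_epochs(n_per_class = 12, channels = c("C3", "Cz"),
                         classes = c("MA", "IS"), b_scale = 1, seed = 33)
  tr <- prepare_trials(eeg, hbr, hbo)
  arr <- default_sd_arrangements()
  sel <- sd_pair_search(tr, arr[arr$n_pairs == 2, ], cv = fast_cv)
  expect_identical(sel$trace$name[1], "left-dlpfc-2pair")
})
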