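test_that("every trial is tested exactly once per repeat", {
  labels <- rep(c("MA", "MI", "IS"), each = 12)
  parts <- hybridbci:::make_partitions(labels, cv_config(folds = 4, repeats = 3,
                                                         seed = 5))
  expect_length(parts, 3)
  for (p in parts) {
    expect_length(p, 36)
    expect_setequal(unique(p), 1:4)
    # stratified: each fold holds 3 trials of each class
    for (cl in unique(labels))
      expect_true(all(table(p[labels == cl]) == 3))
  }
})

test_that("cross-validation is reproducible under a fixed seed", {
  tr <- make_toy_trial_set()
  cvc <- cv_config(folds = 5, repeats = 2, seed = 11)
  r1 <- cross_validate(tr, "hybrid", cvc)
  r2 <- cross_validate(tr, "hybrid", cvc)
  expect_identical(r1$folds, r2$folds)
  expect_identical(r1$confusion, r2$confusion)
  # different seeds give different partitions
  p_a <- hybridbci:::make_partitions(tr$labels, cvc)
  p_b <- hybridbci:::make_partitions(tr$labels,
                                     cv_config(folds = 5, repeats = 2, seed = 12))
  expect_false(identical(p_a, p_b))
})

test_that("corrupting held-out trials never changes fitted models", {
  tr <- make_toy_trial_set()
  train_idx <- which(seq_along(tr$labels) %% 5 != 0)
  test_idx <- setdiff(seq_along(tr$labels), train_idx)
  fit1 <- hybridbci:::fit_fold(tr, train_idx, "hybrid", c("MA", "MI", "IS"))
  tr2 <- tr
  tr2$nirs_x[test_idx, ] <- 1e6                     # corrupt held-out trials
  for (b in names(tr2$band_covs)) tr2$band_covs[[b]][, , test_idx] <- 1e6
  fit2 <- hybridbci:::fit_fold(tr2, train_idx, "hybrid", c("MA", "MI", "IS"))
  for (j in seq_along(fit1)) {
    expect_identical(fit1[[j]]$entry$eeg_model, fit2[[j]]$entry$eeg_model)
    expect_identical(fit1[[j]]$entry$nirs_model, fit2[[j]]$entry$nirs_model)
    expect_identical(fit1[[j]]$entry$meta_model, fit2[[j]]$entry$meta_model)
    expect_identical(lapply(fit1[[j]]$csp_models, `[[`, "W"),
                     lapply(fit2[[j]]$csp_models, `[[`, "W"))
  }
})

test_that("accuracy bookkeeping is consistent", {
  tr <- make_toy_trial_set()
  res <- cross_validate(tr, "hybrid", cv_config(folds = 5, repeats = 2, seed = 3))
  expect_equal(nrow(res$folds), 10)
  expect_gte(res$mean, 0); expect_lte(res$mean, 100)
  # confusion rows sum to the per-class trial counts (per-repeat average)
  expect_equal(unname(rowSums(res$confusion)), rep(10, 3))
  expect_equal(nrow(res$pair_accuracy), 3)
  rm <- tapply(res$folds$accuracy, res$folds$repeat_id, mean)
  expect_equal(res$mean, mean(rm), ignore_attr = TRUE)
})

test_that("binary criterion mode restricts to the class pair", {
  tr <- make_toy_trial_set()
  res <- cross_validate(tr, "eeg_only", cv_config(folds = 5, repeats = 1, seed = 2),
                        classes = c("MI", "IS"))
  expect_equal(res$n_trials, 20)
  expect_equal(dim(res$confusion), c(2L, 2L))
  acc <- pair_accuracy(tr, c("MI", "IS"), "eeg_only",
                       cv_config(folds = 5, repeats = 1, seed = 2))
  expect_identical(acc, res$mean)
})

test_that("too few trials per class is an error", {
  tr <- make_toy_trial_set(n_per_class = 4)
  expect_error(cross_validate(tr, "hybrid", cv_config(folds = 10)), "folds")
})

test_that("channel subsetting restricts covariances and features", {
  tr <- make_toy_trial_set()
  sub <- hybridbci:::subset_trial_set(tr, eeg_channels = "C3",
                                      nirs_channels = c(1, 2))
  expect_equal(dim(sub$band_covs$alpha)[1:2], c(1L, 1L))
  expect_equal(ncol(sub$nirs_x), 2 * 2 * 3)
  expect_error(hybridbci:::subset_trial_set(tr, eeg_channels = "Pz"),
               "unknown EEG channel")
})

test_that("tidy and glance summarize cross-validation results", {
  tr <- make_toy_trial_set()
  res <- cross_validate(tr, "nirs_only", cv_config(folds = 5, repeats = 2, seed = 4))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("repeat_id", "fold", "accuracy"))
  gl <- glance(res)
  expect_equal(gl$mean_accuracy, res$mean)
  expect_equal(gl$mode, "nirs_only")
})
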