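test_that("Fisher-z intervals reproduce the published correlation CIs", {
  ci <- fisher_ci(0.944, 27)
  expect_equal(round(unname(ci), 2), c(0.88, 0.97))
  ci2 <- fisher_ci(0.857, 6)
  expect_equal(round(unname(ci2), 2), c(0.15, 0.98))
})

test_that("the interval is symmetric in z-space and centered on arctanh(r)", {
  ci <- fisher_ci(0, 103)
  expect_equal(ci[["lo"]], -ci[["hi"]], tolerance = 1e-12)
  expect_equal(ci[["hi"]], tanh(1.96 / 10), tolerance = 1e-3)
  r <- 0.6; n <- 30
  ci3 <- fisher_ci(r, n)
  expect_equal((atanh(ci3[["lo"]]) + atanh(ci3[["hi"]])) / 2, atanh(r),
               tolerance = 1e-12)
})

test_that("the interval is monotone in r and narrows with n", {
  cis <- vapply(c(0.1, 0.3, 0.5, 0.7), function(r) fisher_ci(r, 30),
                numeric(2))
  expect_true(all(diff(cis["lo", ]) > 0))
  expect_true(all(diff(cis["hi", ]) > 0))
  widths <- vapply(c(10, 30, 100, 1000),
                   function(n) diff(fisher_ci(0.5, n)), numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(fisher_ci(1, 30), "degenerate")
  expect_error(fisher_ci(0.5, 3), "at least 4")
})

test_that("the signed-rank effect size is Z over root N", {
  expect_identical(wilcoxon_effect_size(0, 36), 0)
  expect_equal(wilcoxon_effect_size(1.96, 36), 1.96 / 6, tolerance = 1e-12)
  expect_equal(wilcoxon_effect_size(3, 9), 1)
  expect_error(wilcoxon_effect_size(1, 0), "at least 1")
})

test_that("identical configurations are not significant", {
  acc <- matrix(rep(c(70, 75, 80, 72), times = 3), nrow = 3, byrow = TRUE,
                dimnames = list(paste0("cfg", 1:3), NULL))
  cmp <- compare_configurations(acc)
  expect_gt(cmp$omnibus$p_value, 0.99)
  expect_true(all(cmp$pairwise$p_value == 1))
  expect_false(any(cmp$pairwise$significant))
})

test_that("a uniform ten-point advantage is detected after FDR correction", {
  base <- withr::with_seed(1, runif(18, 60, 90))
  acc <- rbind(cfgA = base, cfgB = base + 10, cfgC = base + rnorm(18, 0, 0.5))
  cmp <- compare_configurations(acc)
  expect_lt(cmp$omnibus$p_value, 0.05)
  row_ab <- cmp$pairwise[cmp$pairwise$config1 == "cfgA" &
                           cmp$pairwise$config2 == "cfgB", ]
  expect_true(row_ab$significant)
  expect_gt(abs(row_ab$effect_size), 0.5)
})

test_that("with two configurations the adjusted p equals the raw p", {
  acc <- withr::with_seed(2, rbind(a = runif(10, 60, 80), b = runif(10, 65, 85)))
  cmp <- compare_configurations(acc)
  expect_equal(cmp$pairwise$p_adjusted, cmp$pairwise$p_value)
  expect_equal(nrow(cmp$pairwise), 1)
})

test_that("BH adjustment never decreases p-values and preserves order", {
  acc <- withr::with_seed(3, matrix(runif(5 * 12, 50, 95), 5,
                                    dimnames = list(paste0("c", 1:5), NULL)))
  cmp <- compare_configurations(acc)
  expect_true(all(cmp$pairwise$p_adjusted >= cmp$pairwise$p_value))
  o <- order(cmp$pairwise$p_value)
  expect_true(all(diff(cmp$pairwise$p_adjusted[o]) >= -1e-12))
})

test_that("long-format accuracy tables are accepted", {
  long <- tidyr::expand_grid(configuration = c("a", "b"),
                             participant = paste0("P", 1:6))
  long$accuracy <- withr::with_seed(4, runif(12, 60, 90))
  cmp <- compare_configurations(long)
  expect_s3_class(cmp, "config_comparison")
  expect_equal(nrow(cmp$pairwise), 1)
})

test_that("missing cells are rejected", {
  acc <- matrix(c(1, 2, NA, 4), 2)
  expect_error(compare_configurations(acc), "missing")
})

test_that("the internal Z statistic matches the normal-approximation p-value", {
  x <- withr::with_seed(5, runif(15, 60, 90))
  y <- x + withr::with_seed(6, rnorm(15, 2, 3))
  z <- hybridbci:::signed_rank_z(x, y)
  p_ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                              correct = FALSE)$p.value
  expect_equal(2 * stats::pnorm(-abs(z)), p_ref, tolerance = 1e-10)
})
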