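test_that("retained component count is min(n, 6) within the valid range", {
  expect_identical(determine_k(2), 2L)
  expect_identical(determine_k(6), 6L)
  expect_identical(determine_k(11), 6L)
  expect_error(determine_k(1), "\\[2, 11\\]")
  expect_error(determine_k(12), "\\[2, 11\\]")
})

test_that("diagonal two-channel problem has closed-form eigenvalues", {
  c_a <- diag(c(4, 1)); c_b <- diag(c(1, 4))
  m <- hybridbci:::csp_from_cov(c_a, c_b)
  expect_equal(m$eigvals, c(0.8, 0.2), tolerance = 1e-12)
  # filters are axis-aligned: one nonzero entry per column
  expect_equal(apply(abs(m$W) > 1e-10, 2, sum), c(1L, 1L))
})

test_that("identical class covariances give all-0.5 eigenvalues", {
  c_a <- random_spd(5, seed = 1)
  m <- hybridbci:::csp_from_cov(c_a, c_a)
  expect_equal(m$eigvals, rep(0.5, 5), tolerance = 1e-10)
})

test_that("CSP filters jointly diagonalize the class covariances", {
  for (s in 1:5) {
    c_a <- random_spd(4, seed = s); c_b <- random_spd(4, seed = s + 100)
    m <- hybridbci:::csp_from_cov(c_a, c_b)
    wt_cc_w <- t(m$W) %*% (c_a + c_b) %*% m$W
    expect_equal(wt_cc_w, diag(4), tolerance = 1e-8, ignore_attr = TRUE)
    wt_ca_w <- t(m$W) %*% c_a %*% m$W
    expect_equal(wt_ca_w, diag(m$eigvals), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("solutions satisfy the generalized eigenproblem on random instances", {
  # independent check: every returned filter w must satisfy
  # C_a w = lambda (C_a + C_b) w, and eigenvalues must match the brute-force
  # nonsymmetric solve of (C_a + C_b)^{-1} C_a
  withr::with_seed(11, {
    for (i in 1:200) {
      c_a <- random_spd(3); c_b <- random_spd(3)
      m <- hybridbci:::csp_from_cov(c_a, c_b)
      for (j in 1:3) {
        resid <- c_a %*% m$W[, j] - m$eigvals[j] * (c_a + c_b) %*% m$W[, j]
        expect_lt(max(abs(resid)), 1e-8)
      }
      brute <- sort(Re(eigen(solve(c_a + c_b) %*% c_a)$values),
                    decreasing = TRUE)
      expect_equal(m$eigvals, brute, tolerance = 1e-8)
    }
  })
})

test_that("swapping the class pair complements the eigenvalues", {
  c_a <- random_spd(6, seed = 2); c_b <- random_spd(6, seed = 3)
  m_ab <- hybridbci:::csp_from_cov(c_a, c_b)
  m_ba <- hybridbci:::csp_from_cov(c_b, c_a)
  expect_equal(m_ab$eigvals, rev(1 - m_ba$eigvals), tolerance = 1e-8)
})

test_that("more than six channels keeps the first and last three components", {
  covs <- withr::with_seed(4, list(random_spd(8), random_spd(8)))
  m <- hybridbci:::csp_from_cov(covs[[1]], covs[[2]])
  full <- sort(Re(eigen(solve(covs[[1]] + covs[[2]]) %*% covs[[1]])$values),
               decreasing = TRUE)
  expect_equal(m$k, 6L)
  expect_equal(m$eigvals, full[c(1:3, 6:8)], tolerance = 1e-8)
})

test_that("csp_fit on constructed epochs recovers the planted contrast", {
  ep <- make_toy_epochs(n_per_class = 20, b_scale = 0.3)
  a <- subset_epochs_for_test(ep, "A"); b <- subset_epochs_for_test(ep, "B")
  m <- csp_fit(a, b)
  expect_s3_class(m, "csp_model")
  expect_equal(nrow(m$W), 3)
  expect_true(all(m$eigvals >= 0 & m$eigvals <= 1))
  # the most discriminative filter loads mainly on the effect channel C3
  top <- m$W[, which.max(abs(m$eigvals - 0.5))]
  expect_equal(unname(which.max(abs(top))), 1L)
})

test_that("rank-deficient composite covariance is reported", {
  x <- withr::with_seed(6, matrix(rnorm(200), 1))
  data <- array(0, c(4, 2, 100))
  for (i in 1:4) data[i, , ] <- rbind(x[1:100], x[1:100])  # duplicated channel
  ep <- hybridbci:::new_epoch_set(data, c("A", "A", "B", "B"), (0:99) / 100,
                                  100, "EEG", c("c1", "c2"))
  expect_error(csp_fit(subset_epochs_for_test(ep, "A"),
                       subset_epochs_for_test(ep, "B")), "rank-deficient")
})

test_that("log-variance features obey the variance scaling law", {
  ep <- make_toy_epochs(n_per_class = 6)
  a <- subset_epochs_for_test(ep, "A"); b <- subset_epochs_for_test(ep, "B")
  m <- csp_fit(a, b)
  f1 <- csp_logvar(m, a)
  scaled <- a; scaled$data <- 3 * a$data
  f2 <- csp_logvar(m, scaled)
  expect_equal(f2, f1 + 2 * log(3), tolerance = 1e-10)
  expect_equal(dim(f1), c(6L, 3L))
})

test_that("log-variance equals the log of the projected sample variance", {
  ep <- make_toy_epochs(n_per_class = 4)
  a <- subset_epochs_for_test(ep, "A"); b <- subset_epochs_for_test(ep, "B")
  m <- csp_fit(a, b)
  f <- csp_logvar(m, a)
  x <- a$data[2, , ]                       # direct projection oracle
  y <- t(m$W) %*% x
  v <- apply(y, 1, function(r) mean((r - mean(r))^2))
  expect_equal(f[2, ], log(v), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("filter-bank features have k x bands columns and reuse fitted models", {
  ep <- make_toy_epochs(n_per_class = 10, channels = c("C3", "Cz"),
                        fs = 100, n_samp = 400)
  fit <- fbcsp_features(ep, class_pair = c("A", "B"))
  expect_equal(ncol(fit$features), 2 * 3)     # k = 2 channels x 3 bands
  expect_length(fit$models, 3)
  # applying the fitted models to new epochs does not refit
  new_ep <- make_toy_epochs(n_per_class = 3, channels = c("C3", "Cz"),
                            fs = 100, n_samp = 400, seed = 99)
  f2 <- fbcsp_features(new_ep, models = fit$models)
  expect_equal(ncol(f2$features), 6)
  expect_identical(f2$models, fit$models)
})
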