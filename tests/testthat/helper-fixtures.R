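# small programmatic fixtures shared across test files

# epoch_set with planted per-class variance scaling on selected channels:
# class "B" trials get their rhythm amplitude scaled by `b_scale` on
# `effect_channels`, mimicking desynchronization at toy scale
make_toy_epochs <- function(n_per_class = 12, channels = c("C3", "Cz", "C4"),
                            fs = 100, n_samp = 300, b_scale = 0.5,
                            effect_channels = "C3", classes = c("A", "B"),
                            seed = 42) {
  withr::with_seed(seed, {
    labels <- rep(classes, each = n_per_class)
    n_tr <- length(labels)
    data <- array(0, dim = c(n_tr, length(channels), n_samp))
    tt <- (seq_len(n_samp) - 1) / fs
    for (i in seq_len(n_tr)) {
      for (j in seq_along(channels)) {
        amp <- 2
        if (labels[i] == classes[2] && channels[j] %in% effect_channels)
          amp <- amp * b_scale
        data[i, j, ] <- amp * sin(2 * pi * 10 * tt + stats::runif(1, 0, 2 * pi)) +
          stats::rnorm(n_samp)
      }
    }
    hybridbci:::new_epoch_set(data, labels, tt, fs, "EEG", channels)
  })
}

# companion hemoglobin epochs with a planted class mean shift for `shift_class`
make_toy_hb <- function(labels, n_channels = 4, fs = 10, window = c(-1, 15),
                        shift_class = "A", shift = 1, sign = 1, seed = 43) {
  withr::with_seed(seed, {
    n_samp <- round(diff(window) * fs)
    tt <- window[1] + (seq_len(n_samp) - 1) / fs
    n_tr <- length(labels)
    data <- array(stats::rnorm(n_tr * n_channels * n_samp, sd = 0.3),
                  dim = c(n_tr, n_channels, n_samp))
    bump <- sign * shift * pmax(0, sin(pi * pmax(tt, 0) / max(tt)))
    for (i in which(labels == shift_class))
      for (j in seq_len(n_channels))
        data[i, j, ] <- data[i, j, ] + bump
    hybridbci:::new_epoch_set(data, labels, tt, fs, "HbO",
                              sprintf("Ch%02d", seq_len(n_channels)))
  })
}

# small three-class trial_set built from toy epochs (fast; for CV mechanics)
make_toy_trial_set <- function(n_per_class = 10, seed = 7) {
  eeg <- make_toy_epochs(n_per_class, channels = c("C3", "Cz"),
                         classes = c("MI", "IS"), seed = seed)
  # add an MA class that looks like IS in EEG
  ma <- make_toy_epochs(n_per_class, channels = c("C3", "Cz"),
                        classes = c("MA", "MA"), b_scale = 1, seed = seed + 1)
  labels <- c(eeg$labels, ma$labels[seq_len(n_per_class)])
  data <- array(0, dim = c(length(labels), 2, dim(eeg$data)[3]))
  data[seq_len(2 * n_per_class), , ] <- eeg$data
  data[2 * n_per_class + seq_len(n_per_class), , ] <-
    ma$data[seq_len(n_per_class), , ]
  eeg_all <- hybridbci:::new_epoch_set(data, labels, eeg$t, eeg$fs, "EEG",
                                       eeg$channel_labels)
  hbr <- make_toy_hb(labels, shift_class = "MA", sign = -1, seed = seed + 2)
  hbo <- make_toy_hb(labels, shift_class = "MA", sign = 1, seed = seed + 3)
  prepare_trials(eeg_all, hbr, hbo)
}

subset_epochs_for_test <- function(epochs, class) {
  hybridbci:::subset_epochs(epochs, trials = which(epochs$labels == class))
}

# brute-force Ledoit-Wolf shrinkage (explicit loops; independent oracle)
lw_brute <- function(x) {
  n <- nrow(x); p <- ncol(x)
  xc <- sweep(x, 2, colMeans(x))
  s <- matrix(0, p, p)
  for (k in seq_len(n)) s <- s + tcrossprod(xc[k, ]) / n
  m <- sum(diag(s)) / p
  d2 <- sum((s - m * diag(p))^2) / p
  b2bar <- 0
  for (k in seq_len(n)) b2bar <- b2bar + sum((tcrossprod(xc[k, ]) - s)^2) / p
  b2bar <- b2bar / n^2
  b2 <- min(b2bar, d2)
  gamma <- if (d2 > 0) b2 / d2 else 0
  list(sigma = (1 - gamma) * s + gamma * m * diag(p), gamma = gamma, nu = m)
}

random_spd <- function(n, seed = NULL) {
  f <- function() {
    a <- matrix(stats::rnorm(n * n), n)
    crossprod(a) + 0.1 * diag(n)
  }
  if (is.null(seed)) f() else withr::with_seed(seed, f())
}
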