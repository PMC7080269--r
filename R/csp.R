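#' Default EEG filter bank
#'
#' Three passbands covering the theta (4-8 Hz), alpha (8-13 Hz) and beta
#' (13-30 Hz) rhythms, each realized as a 6th-order zero-phase Butterworth
#' bandpass.
#'
#' @return Named list of `c(low, high)` band edges in Hz.
#' @export
filter_bank <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Number of CSP components retained
#'
#' `k = min(n, 6)` for `n` EEG channels, valid for `2 <= n <= 11`: all
#' components are kept for up to six channels, otherwise the first and last
#' three by eigenvalue.
#'
#' @param n Number of EEG channels.
#' @return Integer `k`.
#' @export
#' @examples
#' determine_k(2)   # 2
#' determine_k(11)  # 6
determine_k <- function(n) {
  if (n < 2 || n > 11) stop("channel count must lie in [2, 11]")
  as.integer(min(n, 6))
}

# population covariance (denominator N) of one epoch, channels x samples
epoch_cov <- function(x) {
  xc <- x - rowMeans(x)
  tcrossprod(xc) / ncol(x)
}

# per-trial covariance stack for an epoch_set: array [ch, ch, trials]
trial_covariances <- function(epochs) {
  n_tr <- n_trials(epochs)
  n_ch <- dim(epochs$data)[2]
  covs <- array(0, dim = c(n_ch, n_ch, n_tr))
  for (i in seq_len(n_tr)) covs[, , i] <- epoch_cov(epochs$data[i, , ])
  dimnames(covs) <- list(epochs$channel_labels, epochs$channel_labels, NULL)
  covs
}

# trace-normalized class-average covariance
class_mean_cov <- function(covs, idx) {
  n_ch <- dim(covs)[1]
  acc <- matrix(0, n_ch, n_ch)
  for (i in idx) acc <- acc + covs[, , i] / sum(diag(covs[, , i]))
  acc / length(idx)
}

# core CSP solver on class-average covariances: solves C_a w = lambda
# (C_a + C_b) w by whitening the composite covariance, giving eigenvalues in
# [0, 1]. Columns of W satisfy W' (C_a + C_b) W = I and W' C_a W = diag.
csp_from_cov <- function(c_a, c_b, k = NULL, class_pair = NULL, band = NULL,
                         channel_labels = NULL) {
  n <- nrow(c_a)
  if (n < 2) stop("CSP requires at least two channels")
  cc <- (c_a + c_b)
  cc <- (cc + t(cc)) / 2
  e <- eigen(cc, symmetric = TRUE)
  tol <- max(e$values) * 1e-10
  if (any(e$values < tol))
    stop(sprintf(paste("composite covariance is rank-deficient (%d channels);",
                       "more trials or fewer channels are needed"), n))
  p_whiten <- diag(1 / sqrt(e$values), n) %*% t(e$vectors)
  s <- p_whiten %*% ((c_a + t(c_a)) / 2) %*% t(p_whiten)
  s <- (s + t(s)) / 2
  es <- eigen(s, symmetric = TRUE)           # eigenvalues descending
  w_full <- t(p_whiten) %*% es$vectors
  lambda <- pmin(pmax(es$values, 0), 1)
  if (is.null(k)) k <- determine_k(n)
  sel <- if (n <= 6) seq_len(n) else c(1:3, (n - 2):n)  # first & last three
  sel <- sel[seq_len(min(k, length(sel)))]
  w <- w_full[, sel, drop = FALSE]
  # deterministic sign: largest-magnitude entry of each filter positive
  for (j in seq_len(ncol(w))) {
    i_max <- which.max(abs(w[, j]))
    if (w[i_max, j] < 0) w[, j] <- -w[, j]
  }
  rownames(w) <- channel_labels
  structure(list(W = w, eigvals = lambda[sel], k = length(sel),
                 class_pair = class_pair, band = band,
                 channel_labels = channel_labels),
            class = "csp_model")
}

#' Fit common spatial patterns for a class pair
#'
#' Per-trial epoch covariances are trace-normalized, averaged within each
#' class, and the generalized eigenproblem `C_A w = lambda (C_A + C_B) w` is
#' solved by whitening the composite covariance. Eigenvalues lie in `[0, 1]`
#' and are sorted in decreasing order; for more than six channels the first
#' and last three components are retained (`k = min(n, 6)`).
#'
#' @param epochs_a,epochs_b `epoch_set`s of the two classes (same channels and
#'   epoch length, at least two trials each).
#' @param k Number of components (default [determine_k()] of the channel
#'   count).
#' @return A `csp_model` with the spatial filter matrix `W` (channels x k) and
#'   the eigenvalue spectrum of the retained components.
#' @export
csp_fit <- function(epochs_a, epochs_b, k = NULL) {
  stopifnot(inherits(epochs_a, "epoch_set"), inherits(epochs_b, "epoch_set"))
  if (!identical(epochs_a$channel_labels, epochs_b$channel_labels))
    stop("the two classes must share channels")
  if (n_trials(epochs_a) < 2 || n_trials(epochs_b) < 2)
    stop("CSP needs at least two trials per class")
  covs_a <- trial_covariances(epochs_a)
  covs_b <- trial_covariances(epochs_b)
  c_a <- class_mean_cov(covs_a, seq_len(dim(covs_a)[3]))
  c_b <- class_mean_cov(covs_b, seq_len(dim(covs_b)[3]))
  pair <- c(unique(epochs_a$labels)[1], unique(epochs_b$labels)[1])
  csp_from_cov(c_a, c_b, k, class_pair = pair,
               channel_labels = epochs_a$channel_labels)
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d filters over %d channels%s; eigenvalues: %s\n",
              x$k, nrow(x$W),
              if (!is.null(x$band)) sprintf(" (band %g-%g Hz)", x$band[1], x$band[2]) else "",
              paste(signif(x$eigvals, 3), collapse = ", ")))
  invisible(x)
}

# log-variance features from precomputed per-trial covariances:
# var of projected component j = w_j' C_trial w_j (population form)
logvar_from_covs <- function(w, covs, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(dim(covs)[3])
  out <- matrix(0, length(idx), ncol(w))
  for (r in seq_along(idx)) {
    v <- diag(crossprod(w, covs[, , idx[r]]) %*% w)
    out[r, ] <- log(pmax(v, 1e-30))  # floor guards constant projections
  }
  out
}

#' Log-variance CSP features
#'
#' Projects each epoch through the spatial filters and returns the natural
#' log of the per-component sample variance (population form, denominator N)
#' over the epoch.
#'
#' @param model A `csp_model` from [csp_fit()].
#' @param epochs An `epoch_set` on the same channels.
#' @return Trials x k numeric feature matrix.
#' @export
csp_logvar <- function(model, epochs) {
  stopifnot(inherits(model, "csp_model"), inherits(epochs, "epoch_set"))
  if (nrow(model$W) != dim(epochs$data)[2])
    stop("channel count mismatch between model and epochs")
  covs <- trial_covariances(epochs)
  f <- logvar_from_covs(model$W, covs)
  colnames(f) <- sprintf("csp%02d", seq_len(ncol(f)))
  f
}

# zero-phase band filtering of every epoch in an epoch_set
band_filter_epochs <- function(epochs, band, order = 6L) {
  spec <- filter_spec(order = order, band = band)
  sos <- butter_sos(spec, epochs$fs)
  n_samp <- dim(epochs$data)[3]
  pad <- default_pad(spec, epochs$fs, n_samp)
  out <- epochs
  for (i in seq_len(dim(epochs$data)[1]))
    for (j in seq_len(dim(epochs$data)[2]))
      out$data[i, j, ] <- filtfilt_sos(epochs$data[i, j, ], sos, pad)
  out
}

# per-band per-trial covariance stacks for the whole filter bank
band_covariances <- function(epochs, bank = filter_bank()) {
  lapply(bank, function(band) trial_covariances(band_filter_epochs(epochs, band)))
}

#' Filter-bank CSP features
#'
#' Applies the filter bank to each epoch, fits one CSP model per band on the
#' supplied (training) epochs of the two classes, and concatenates the
#' log-variance features across bands. With fitted `models` supplied, the
#' features of new (held-out) epochs are computed without refitting.
#'
#' @param epochs An `epoch_set`; when fitting, it must contain only the two
#'   classes of `class_pair`.
#' @param bank Band list as from [filter_bank()].
#' @param class_pair Character vector of the two class names.
#' @param models Optional list of per-band `csp_model`s from a previous fit.
#' @param k Components per band (default [determine_k()]).
#' @return List with `features` (trials x (k * bands) matrix) and `models`
#'   (per-band `csp_model` list).
#' @export
fbcsp_features <- function(epochs, bank = filter_bank(), class_pair = NULL,
                           models = NULL, k = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  covs <- band_covariances(epochs, bank)
  if (is.null(models)) {
    if (is.null(class_pair)) class_pair <- unique(epochs$labels)
    if (length(class_pair) != 2 || !all(epochs$labels %in% class_pair))
      stop("fitting requires epochs restricted to exactly two classes")
    models <- lapply(names(bank), function(bn) {
      idx_a <- which(epochs$labels == class_pair[1])
      idx_b <- which(epochs$labels == class_pair[2])
      c_a <- class_mean_cov(covs[[bn]], idx_a)
      c_b <- class_mean_cov(covs[[bn]], idx_b)
      csp_from_cov(c_a, c_b, k, class_pair = class_pair, band = bank[[bn]],
                   channel_labels = epochs$channel_labels)
    })
    names(models) <- names(bank)
  }
  feats <- do.call(cbind, lapply(names(bank), function(bn) {
    f <- logvar_from_covs(models[[bn]]$W, covs[[bn]])
    colnames(f) <- sprintf("%s.csp%02d", bn, seq_len(ncol(f)))
    f
  }))
  list(features = feats, models = models)
}
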