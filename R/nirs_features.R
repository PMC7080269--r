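#' Temporal-window mean fNIRS features
#'
#' For every trial, channel, chromophore and temporal window, the temporal
#' mean amplitude of the baseline-corrected hemoglobin epoch is taken. With
#' the default three windows (0-5, 5-10, 10-15 s) and both chromophores the
#' feature count is `channels * 2 * 3`.
#'
#' @param hbr_epochs,hbo_epochs Baseline-corrected `epoch_set`s of dHbR and
#'   dHbO (same trials and channels).
#' @param windows List of `c(start, end)` windows in seconds (half-open) on
#'   the epoch time axis.
#' @return Trials x features matrix with a `provenance` attribute (tibble of
#'   channel, chromophore and window per column).
#' @export
#' @examples
#' # 16 channels x 2 chromophores x 3 windows = 96 features per trial
nirs_features <- function(hbr_epochs, hbo_epochs,
                          windows = list(c(0, 5), c(5, 10), c(10, 15))) {
  stopifnot(inherits(hbr_epochs, "epoch_set"), inherits(hbo_epochs, "epoch_set"))
  if (!identical(dim(hbr_epochs$data), dim(hbo_epochs$data)))
    stop("dHbR and dHbO epochs must have identical dimensions")
  chroms <- list(HbR = hbr_epochs, HbO = hbo_epochs)
  n_tr <- n_trials(hbr_epochs)
  ch_labels <- hbr_epochs$channel_labels
  cols <- list()
  prov <- list()
  for (cn in names(chroms)) {
    ep <- chroms[[cn]]
    for (w in windows) {
      sel <- ep$t >= w[1] & ep$t < w[2]
      if (!any(sel)) stop(sprintf("window [%g, %g) s lies outside the epochs",
                                  w[1], w[2]))
      m <- apply(ep$data[, , sel, drop = FALSE], c(1, 2), mean)
      colnames(m) <- sprintf("%s.%s.w%g-%g", ch_labels, cn, w[1], w[2])
      cols[[length(cols) + 1]] <- m
      prov[[length(prov) + 1]] <- tibble::tibble(
        channel = ch_labels, chromophore = cn, window_start = w[1],
        window_end = w[2])
    }
  }
  out <- do.call(cbind, cols)
  attr(out, "provenance") <- dplyr::bind_rows(prov)
  out
}
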