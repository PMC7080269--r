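#' Construct a continuous multichannel recording
#'
#' The basic container for continuous data: a channels-by-samples matrix with
#' a sampling rate, channel labels, a modality tag and event markers. Events
#' carry both the onset in seconds and the onset sample at this recording's
#' rate; co-registered modalities (EEG and the three optical-density series)
#' share the same onsets in seconds.
#'
#' @param data Channels-by-samples numeric matrix.
#' @param fs Sampling rate in Hz.
#' @param channel_labels Character vector, one label per row of `data`.
#' @param modality One of `"EEG"`, `"OD780"`, `"OD805"`, `"OD830"`, `"HbR"`,
#'   `"HbO"`.
#' @param events Tibble with columns `onset_s` (seconds from record start) and
#'   `class` (one of `"MA"`, `"MI"`, `"IS"`), sorted by onset.
#' @return A `raw_recording` object.
#' @export
raw_recording <- function(data, fs, channel_labels, modality, events) {
  stopifnot(is.matrix(data), fs > 0,
            length(channel_labels) == nrow(data))
  modality <- match.arg(modality,
                        c("EEG", "OD780", "OD805", "OD830", "HbR", "HbO"))
  events <- tibble::as_tibble(events)
  stopifnot(all(c("onset_s", "class") %in% names(events)))
  if (is.unsorted(events$onset_s))
    stop("events must be sorted by onset")
  events$onset_sample <- as.integer(round(events$onset_s * fs)) + 1L
  if (any(events$onset_sample < 1L) || any(events$onset_sample > ncol(data)))
    stop("event onsets must lie inside the recording")
  structure(list(data = data, fs = fs,
                 channel_labels = as.character(channel_labels),
                 modality = modality, events = events),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %s: %d channels x %d samples @ %g Hz, %d events\n",
              x$modality, nrow(x$data), ncol(x$data), x$fs, nrow(x$events)))
  invisible(x)
}

new_epoch_set <- function(data, labels, t, fs, modality, channel_labels) {
  stopifnot(length(dim(data)) == 3L, dim(data)[1] == length(labels),
            dim(data)[3] == length(t))
  structure(list(data = data, labels = as.character(labels), t = t, fs = fs,
                 modality = modality, channel_labels = channel_labels),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %s: %d trials x %d channels x %d samples @ %g Hz (t in [%g, %g] s)\n",
              x$modality, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              x$fs, min(x$t), max(x$t)))
  cat("  classes:", paste(sprintf("%s=%d", names(table(x$labels)),
                                  table(x$labels)), collapse = ", "), "\n")
  invisible(x)
}

n_trials <- function(epochs) dim(epochs$data)[1]

# subset an epoch_set by trial index and/or channel label
subset_epochs <- function(epochs, trials = NULL, channels = NULL) {
  data <- epochs$data
  labels <- epochs$labels
  ch <- epochs$channel_labels
  if (!is.null(trials)) {
    data <- data[trials, , , drop = FALSE]
    labels <- labels[trials]
  }
  if (!is.null(channels)) {
    idx <- match(channels, ch)
    if (anyNA(idx)) stop("unknown channel(s): ",
                         paste(channels[is.na(idx)], collapse = ", "))
    data <- data[, idx, , drop = FALSE]
    ch <- ch[idx]
  }
  new_epoch_set(data, labels, epochs$t, epochs$fs, epochs$modality, ch)
}
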