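#' Downsample a recording by an integer factor
#'
#' Applies a zero-phase anti-aliasing lowpass (8th-order Butterworth with
#' cutoff at 80% of the target Nyquist) before decimation. Event onsets are
#' recomputed at the target rate from their onsets in seconds.
#'
#' @param raw A [raw_recording()].
#' @param target_fs Target sampling rate in Hz (default 200); `raw$fs` must be
#'   an integer multiple of it.
#' @return A [raw_recording()] at `target_fs`.
#' @export
downsample <- function(raw, target_fs = 200) {
  stopifnot(inherits(raw, "raw_recording"))
  if (raw$fs == target_fs) return(raw)
  factor <- raw$fs / target_fs
  if (abs(factor - round(factor)) > 1e-9 || factor < 1)
    stop(sprintf("sampling rate %g Hz is not an integer multiple of %g Hz",
                 raw$fs, target_fs))
  spec <- filter_spec(order = 8L, band = 0.8 * target_fs / 2, type = "low")
  data <- apply_filter(raw$data, spec, raw$fs)
  data <- data[, seq(1, ncol(data), by = round(factor)), drop = FALSE]
  raw_recording(data, target_fs, raw$channel_labels, raw$modality,
                raw$events[, c("onset_s", "class")])
}

#' Zero-phase bandpass filtering of a recording
#'
#' @param raw A [raw_recording()].
#' @param spec A [filter_spec()]; the filter is applied independently per
#'   channel, forward and backward.
#' @return The filtered [raw_recording()].
#' @export
bandpass_zero_phase <- function(raw, spec) {
  stopifnot(inherits(raw, "raw_recording"), inherits(spec, "filter_spec"))
  data <- apply_filter(raw$data, spec, raw$fs)
  out <- raw
  out$data <- data
  out
}

#' Cut a continuous recording into trial epochs
#'
#' Windows are half-open `[start, end)` relative to each event onset, so a
#' 10 s epoch at 200 Hz has exactly 2000 samples.
#'
#' @param raw A [raw_recording()].
#' @param window Numeric `c(start, end)` in seconds relative to task onset.
#' @return An `epoch_set` (trials x channels x samples with labels and a time
#'   axis).
#' @export
epoch_trials <- function(raw, window) {
  stopifnot(inherits(raw, "raw_recording"), length(window) == 2L)
  if (window[2] <= window[1]) stop("epoch window must have positive length")
  n_samp <- round((window[2] - window[1]) * raw$fs)
  off0 <- round(window[1] * raw$fs)
  ev <- raw$events
  n_rec <- ncol(raw$data)
  data <- array(0, dim = c(nrow(ev), nrow(raw$data), n_samp))
  for (i in seq_len(nrow(ev))) {
    idx <- ev$onset_sample[i] + off0 + seq_len(n_samp) - 1L
    if (idx[1] < 1L || idx[n_samp] > n_rec)
      stop(sprintf("epoch window [%g, %g) s exceeds record bounds for trial %d",
                   window[1], window[2], i))
    data[i, , ] <- raw$data[, idx]
  }
  t_axis <- window[1] + (seq_len(n_samp) - 1) / raw$fs
  new_epoch_set(data, ev$class, t_axis, raw$fs, raw$modality,
                raw$channel_labels)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the temporal mean over `base_window`
#' (default the second immediately preceding task onset).
#'
#' @param epochs An `epoch_set`.
#' @param base_window Numeric `c(start, end)` in seconds on the epoch time
#'   axis (half-open).
#' @return The baseline-corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, base_window = c(-1, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- epochs$t >= base_window[1] & epochs$t < base_window[2]
  if (!any(sel)) stop("base_window lies outside the epoch time axis")
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base)  # recycles over samples
  epochs
}

#' Full preprocessing of one synthetic participant
#'
#' Mirrors the analysis pipeline: EEG is downsampled to 200 Hz,
#' bandpass-filtered to 1-50 Hz (6th-order zero-phase Butterworth) and cut
#' into 0-10 s epochs; the optical densities are converted to dHbR/dHbO via
#' the modified Beer-Lambert law, bandpass-filtered to 0.01-0.09 Hz, cut into
#' -1-15 s epochs and baseline-corrected over [-1, 0] s.
#'
#' @param participant A `bci_participant` from [generate_participant()] or
#'   [read_bci_dataset()].
#' @param target_fs EEG target sampling rate (default 200 Hz).
#' @param eeg_band,nirs_band Bandpass edges in Hz.
#' @param eeg_window,nirs_window Epoch windows in seconds.
#' @param base_window fNIRS baseline window in seconds.
#' @return List with `epoch_set` elements `eeg`, `hbr`, `hbo`.
#' @export
preprocess_participant <- function(participant,
                                   target_fs = 200,
                                   eeg_band = c(1, 50),
                                   nirs_band = c(0.01, 0.09),
                                   eeg_window = c(0, 10),
                                   nirs_window = c(-1, 15),
                                   base_window = c(-1, 0)) {
  stopifnot(inherits(participant, "bci_participant"))
  eeg <- participant$eeg
  if (eeg$fs > target_fs) eeg <- downsample(eeg, target_fs)
  eeg <- bandpass_zero_phase(eeg, filter_spec(band = eeg_band))
  eeg_ep <- epoch_trials(eeg, eeg_window)

  hb <- od_to_hemoglobin(participant$od780$data, participant$od805$data,
                         participant$od830$data)
  fs_n <- participant$od780$fs
  ev <- participant$od780$events[, c("onset_s", "class")]
  labs <- participant$od780$channel_labels
  spec_n <- filter_spec(band = nirs_band)
  hbr <- bandpass_zero_phase(raw_recording(hb$hbr, fs_n, labs, "HbR", ev), spec_n)
  hbo <- bandpass_zero_phase(raw_recording(hb$hbo, fs_n, labs, "HbO", ev), spec_n)
  hbr_ep <- baseline_correct(epoch_trials(hbr, nirs_window), base_window)
  hbo_ep <- baseline_correct(epoch_trials(hbo, nirs_window), base_window)

  list(eeg = eeg_ep, hbr = hbr_ep, hbo = hbo_ep)
}
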