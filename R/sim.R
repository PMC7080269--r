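#' Configuration for the synthetic-participant generator
#'
#' Defines the study conditions emulated by [generate_participant()]: three
#' task classes (mental arithmetic MA, right-hand motor imagery MI, idle
#' state IS), 30 trials each, 10 s task periods separated by 16-18 s rests,
#' 11 central EEG channels and 16 prefrontal fNIRS channels recorded as
#' optical densities at 780/805/830 nm.
#'
#' The planted class effects are:
#' * MI trials attenuate the mu (~10 Hz) and beta (~20 Hz) rhythm amplitude
#'   on motor channels by `erd_depth`, strongest over the left (contralateral)
#'   motor cortex for right-hand imagery;
#' * MA trials add a canonical double-gamma hemodynamic response (dHbO up,
#'   dHbR down) on prefrontal channels, strongest over the left DLPFC;
#' * IS trials carry no planted effect.
#'
#' @param n_trials_per_class Trials per class (default 30).
#' @param eeg_channels EEG channel labels (default: 11 central channels).
#' @param n_nirs_channels Number of prefrontal fNIRS channels (default 16).
#' @param eeg_fs,nirs_fs Sampling rates in Hz (defaults 1000 and 10).
#' @param task_dur Task period duration in seconds (default 10).
#' @param rest_range Inter-trial rest drawn uniformly from this range in
#'   seconds (default `c(16, 18)`).
#' @param instruction_dur Instruction period before task onset, seconds.
#' @param erd_depth Fractional mu/beta amplitude attenuation during MI in
#'   `[0, 1]`.
#' @param erd_weights Named per-channel multipliers of `erd_depth` for the mu
#'   rhythm; defaults to a right-hand-MI topography peaking at C3/CP3.
#'   Channels missing from the vector get weight 0.
#' @param erd_weights_beta Named per-channel multipliers for the beta rhythm;
#'   defaults to `erd_weights`. Mu and beta desynchronization have distinct
#'   topographies in real recordings, so they can be planted independently.
#' @param mu_amp,beta_amp Baseline rhythm amplitudes in microvolts.
#' @param rhythm_weights Optional named per-channel multipliers of the
#'   baseline rhythm amplitude. Default `NULL` puts the rhythms on every
#'   channel; if supplied, channels missing from the vector get no rhythm at
#'   all (useful for planting signal on selected channels only).
#' @param hrf_amp_hbo,hrf_amp_hbr Peak hemodynamic effect amplitudes during
#'   MA in mM*cm (HbO positive, HbR negative).
#' @param hrf_weights Per-channel multipliers of the hemodynamic amplitudes
#'   (length `n_nirs_channels`); defaults to a prefrontal topography peaking
#'   over the left DLPFC (channels 5, 10, 11, 16).
#' @param noise_sd_eeg Standard deviation of the 1/f EEG background in
#'   microvolts.
#' @param noise_sd_od Scale of the physiological optical-density noise
#'   (drift, low-frequency oscillations, Mayer waves, respiration, cardiac,
#'   white noise).
#' @param amp_variability Trial-to-trial and slow physiological variability
#'   of the planted effects in `[0, 1)`: rhythm power fluctuates slowly by
#'   `exp(amp_variability * z(t))`, and the per-trial ERD depth and
#'   hemodynamic amplitude are jittered multiplicatively by
#'   `U(1 - amp_variability, 1 + amp_variability)`. Set to 0 for the exact
#'   noise-free limit (default 0.5, typical of session-level variability in
#'   real recordings).
#' @param env_global_share Fraction of the slow rhythm-power fluctuation
#'   variance that is global (shared across channels, arousal-like) rather
#'   than channel-local (default 0.25: band-power dynamics are dominated by
#'   local cortical excitability with a smaller global component).
#' @param seed Integer seed; identical seed and configuration give
#'   bit-identical output.
#' @return A `sim_config` object (a validated list).
#' @export
sim_config <- function(n_trials_per_class = 30L,
                       eeg_channels = c("C3", "C1", "Cz", "C2", "C4",
                                        "CP3", "CPz", "CP4",
                                        "FC3", "FCz", "FC4"),
                       n_nirs_channels = 16L,
                       eeg_fs = 1000, nirs_fs = 10,
                       task_dur = 10, rest_range = c(16, 18),
                       instruction_dur = 2,
                       erd_depth = 0.4, erd_weights = NULL,
                       erd_weights_beta = NULL,
                       mu_amp = 8, beta_amp = 4,
                       rhythm_weights = NULL,
                       hrf_amp_hbo = 0.04, hrf_amp_hbr = -0.015,
                       hrf_weights = NULL,
                       noise_sd_eeg = 10, noise_sd_od = 0.04,
                       amp_variability = 0.5,
                       env_global_share = 0.25,
                       seed = 1L) {
  if (length(eeg_channels) < 1L) stop("eeg_channels must not be empty")
  if (task_dur <= 0 || instruction_dur < 0 || any(rest_range <= 0))
    stop("durations must be positive")
  if (rest_range[1] > rest_range[2])
    stop("rest_range low must not exceed high")
  if (erd_depth < 0 || erd_depth > 1)
    stop("erd_depth must lie in [0, 1]")
  if (amp_variability < 0 || amp_variability >= 1)
    stop("amp_variability must lie in [0, 1)")
  if (env_global_share < 0 || env_global_share > 1)
    stop("env_global_share must lie in [0, 1]")
  if (n_trials_per_class < 1L) stop("need at least one trial per class")
  if (eeg_fs <= 0 || nirs_fs <= 0) stop("sampling rates must be positive")
  if (is.null(erd_weights)) erd_weights <- default_erd_weights()
  if (is.null(erd_weights_beta)) erd_weights_beta <- erd_weights
  if (is.null(hrf_weights)) hrf_weights <- default_hrf_weights(n_nirs_channels)
  if (length(hrf_weights) != n_nirs_channels)
    stop("hrf_weights must have one entry per fNIRS channel")
  structure(list(n_trials_per_class = as.integer(n_trials_per_class),
                 eeg_channels = eeg_channels,
                 n_nirs_channels = as.integer(n_nirs_channels),
                 eeg_fs = eeg_fs, nirs_fs = nirs_fs,
                 task_dur = task_dur, rest_range = rest_range,
                 instruction_dur = instruction_dur,
                 erd_depth = erd_depth, erd_weights = erd_weights,
                 erd_weights_beta = erd_weights_beta,
                 mu_amp = mu_amp, beta_amp = beta_amp,
                 rhythm_weights = rhythm_weights,
                 hrf_amp_hbo = hrf_amp_hbo, hrf_amp_hbr = hrf_amp_hbr,
                 hrf_weights = hrf_weights,
                 noise_sd_eeg = noise_sd_eeg, noise_sd_od = noise_sd_od,
                 amp_variability = amp_variability,
                 env_global_share = env_global_share,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# right-hand MI desynchronization topography: contralateral (left) motor
# channels strongest, midline intermediate, ipsilateral weak
default_erd_weights <- function() {
  c(C3 = 1, CP3 = 1, C1 = 0.8, FC3 = 0.7,
    Cz = 0.5, CPz = 0.5, FCz = 0.4,
    C2 = 0.3, C4 = 0.15, CP4 = 0.15, FC4 = 0.1)
}

# mental-arithmetic hemodynamic topography over the 16 prefrontal channels:
# left DLPFC (5, 10, 11, 16) strongest, right DLPFC (1, 6, 7, 12) next
default_hrf_weights <- function(n = 16L) {
  w <- rep(0.6, n)
  w[intersect(c(5, 10, 11, 16), seq_len(n))] <- 1
  w[intersect(c(1, 6, 7, 12), seq_len(n))] <- 0.8
  w
}

#' Canonical double-gamma hemodynamic response function
#'
#' Peak at 6 s, undershoot at 16 s, undershoot-to-peak ratio 1/6; each gamma
#' lobe is normalized to unit height at its mode.
#'
#' @param t Time in seconds (non-negative).
#' @return HRF values at `t`.
#' @export
hrf_double_gamma <- function(t) {
  h <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  h[pos] <- (tp / 6)^6 * exp(6 - tp) - (1 / 6) * (tp / 16)^16 * exp(16 - tp)
  h
}

# task-evoked response: boxcar of task_dur convolved with the HRF,
# normalized to unit peak (so planted amplitudes are exact peak values)
hrf_task_response <- function(task_dur, fs, total_dur = task_dur + 30) {
  tt <- seq(0, total_dur, by = 1 / fs)
  h <- hrf_double_gamma(tt)
  box <- as.numeric(tt < task_dur)
  r <- stats::convolve(box, rev(h), type = "open")[seq_along(tt)] / fs
  r / max(r)
}

# 1/f (pink) background noise via spectral shaping, unit variance
pink_noise <- function(n, fs) {
  nfft <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(nfft)
  x_f <- stats::fft(w)
  k <- seq_len(nfft) - 1
  f <- pmin(k, nfft - k) * fs / nfft      # symmetric frequency magnitudes
  s <- ifelse(f > 0, 1 / sqrt(f), 0)
  x <- Re(stats::fft(x_f * s, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

# smooth task gate: `height` inside [onset, onset+dur], raised-cosine ramps
add_smooth_gate <- function(g, onset_s, dur, fs, height = 1, ramp = 0.5) {
  n_ramp <- max(1L, round(ramp * fs))
  up <- (1 - cos(pi * seq_len(n_ramp) / n_ramp)) / 2
  i0 <- round(onset_s * fs) + 1L
  i1 <- i0 + round(dur * fs) - 1L
  prof <- height * c(up, rep(1, max(0L, i1 - i0 + 1L - 2L * n_ramp)), rev(up))
  idx <- seq(i0, length.out = length(prof))
  keep <- idx >= 1L & idx <= length(g)
  g[idx[keep]] <- g[idx[keep]] + prof[keep]
  g
}

#' Generate one synthetic participant
#'
#' Produces co-registered continuous EEG and fNIRS optical-density recordings
#' with event markers for the three task classes. EEG is 1/f background noise
#' plus mu and beta rhythms whose amplitude is attenuated by
#' `config$erd_depth` (weighted by the channel topography) during MI task
#' windows. The fNIRS optical densities are synthesized by planting dHbR/dHbO
#' trajectories (double-gamma response convolved with the MA task boxcar,
#' peak-normalized and scaled by the configured amplitudes) and mapping them
#' through the Moore-Penrose right inverse of the Beer-Lambert conversion
#' matrix, so [od_to_hemoglobin()] recovers the planted trajectories exactly
#' in the noise-free limit. Physiological noise (slow drift, low-frequency
#' oscillations, Mayer waves, respiration, cardiac pulsation, white noise) is
#' added in optical-density space.
#'
#' @param config A [sim_config()].
#' @return A `bci_participant`: list with elements `eeg` (a
#'   [raw_recording()]), `od780`, `od805`, `od830` (co-registered
#'   [raw_recording()]s), `events` (tibble of onsets and classes) and
#'   `config`.
#' @export
#' @examples
#' p <- generate_participant(sim_config(n_trials_per_class = 2, eeg_fs = 200))
#' p$eeg
generate_participant <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_participant_impl(config))
}

generate_participant_impl <- function(cfg) {
  classes <- c("MA", "MI", "IS")
  labels <- sample(rep(classes, cfg$n_trials_per_class))
  n_tr <- length(labels)
  rests <- stats::runif(n_tr, cfg$rest_range[1], cfg$rest_range[2])

  lead_in <- 5
  onsets <- lead_in + cfg$instruction_dur +
    c(0, cumsum(cfg$instruction_dur + cfg$task_dur + rests))[seq_len(n_tr)]
  total_dur <- onsets[n_tr] + cfg$task_dur + cfg$rest_range[2] + 5

  events <- tibble::tibble(trial = seq_len(n_tr),
                           class = labels, onset_s = onsets)

  # shared physiological state: per-trial multiplicative jitter of the
  # planted effects and a slow rhythm-power envelope, common to all channels
  av <- cfg$amp_variability
  trial_mult <- if (av > 0) stats::runif(n_tr, 1 - av, 1 + av) else rep(1, n_tr)

  ## ---- EEG ----
  fs_e <- cfg$eeg_fs
  n_e <- as.integer(ceiling(total_dur * fs_e))
  t_e <- (seq_len(n_e) - 1) / fs_e

  # MI desynchronization gate: per-trial depth, smooth ramps, shared by all
  # channels (weighted per channel below)
  gate <- numeric(n_e)
  for (i in which(labels == "MI"))
    gate <- add_smooth_gate(gate, onsets[i], cfg$task_dur, fs_e,
                            height = min(1, cfg$erd_depth * trial_mult[i]))
  gate <- pmin(gate, 1)

  # slow log-amplitude fluctuation of the background rhythms (knots every
  # 2 s), drawn independently per channel and band apart from a global
  # (arousal-like) component: real band-power dynamics mix a common drive
  # with band- and site-specific cortical excitability
  knots_t <- seq(0, total_dur + 2, by = 2)
  z_global <- stats::rnorm(length(knots_t))
  slow_env_ch <- function() {
    if (av == 0) return(rep(1, n_e))
    z <- sqrt(cfg$env_global_share) * z_global +
      sqrt(1 - cfg$env_global_share) * stats::rnorm(length(knots_t))
    exp(av * stats::approx(knots_t, z, xout = t_e)$y)
  }

  n_ch <- length(cfg$eeg_channels)
  eeg <- matrix(0, n_ch, n_e)
  w_mu <- cfg$erd_weights[cfg$eeg_channels]
  w_mu[is.na(w_mu)] <- 0
  w_be <- cfg$erd_weights_beta[cfg$eeg_channels]
  w_be[is.na(w_be)] <- 0
  w_rhy <- if (is.null(cfg$rhythm_weights)) rep(1, n_ch) else {
    w <- cfg$rhythm_weights[cfg$eeg_channels]
    w[is.na(w)] <- 0
    w
  }
  for (c_i in seq_len(n_ch)) {
    phase_mu <- stats::runif(1, 0, 2 * pi)
    phase_be <- stats::runif(1, 0, 2 * pi)
    rhythm <- w_rhy[c_i] *
      (cfg$mu_amp * slow_env_ch() * (1 - w_mu[c_i] * gate) *
         sin(2 * pi * 10 * t_e + phase_mu) +
       cfg$beta_amp * slow_env_ch() * (1 - w_be[c_i] * gate) *
         sin(2 * pi * 20 * t_e + phase_be))
    eeg[c_i, ] <- cfg$noise_sd_eeg * pink_noise(n_e, fs_e) + rhythm
  }

  ## ---- fNIRS ----
  fs_n <- cfg$nirs_fs
  n_n <- as.integer(ceiling(total_dur * fs_n))
  t_n <- (seq_len(n_n) - 1) / fs_n

  resp <- numeric(n_n)  # MA-evoked response time course, unit peak per trial
  kernel <- hrf_task_response(cfg$task_dur, fs_n)
  for (i in which(labels == "MA")) {
    i0 <- round(onsets[i] * fs_n) + 1L
    idx <- seq(i0, length.out = length(kernel))
    keep <- idx <= n_n
    resp[idx[keep]] <- resp[idx[keep]] + trial_mult[i] * kernel[keep]
  }

  a_fwd <- mbll_forward_matrix()
  od <- lapply(1:3, function(i) matrix(0, cfg$n_nirs_channels, n_n))
  for (c_i in seq_len(cfg$n_nirs_channels)) {
    w <- cfg$hrf_weights[c_i]
    hbr <- cfg$hrf_amp_hbr * w * resp
    hbo <- cfg$hrf_amp_hbo * w * resp
    for (lam in 1:3) {
      noise <- od_physio_noise(t_n, cfg$noise_sd_od)
      od[[lam]][c_i, ] <- a_fwd[lam, 1] * hbr + a_fwd[lam, 2] * hbo + noise
    }
  }

  ev <- events[, c("onset_s", "class")]
  nirs_labels <- sprintf("Ch%02d", seq_len(cfg$n_nirs_channels))
  structure(list(
    eeg = raw_recording(eeg, fs_e, cfg$eeg_channels, "EEG", ev),
    od780 = raw_recording(od[[1]], fs_n, nirs_labels, "OD780", ev),
    od805 = raw_recording(od[[2]], fs_n, nirs_labels, "OD805", ev),
    od830 = raw_recording(od[[3]], fs_n, nirs_labels, "OD830", ev),
    events = events, config = cfg), class = "bci_participant")
}

# physiological optical-density noise: slow drift, in-band low-frequency
# oscillation, Mayer wave (~0.1 Hz), respiration (~0.25 Hz), cardiac
# (~1.1 Hz), plus white sensor noise; overall scale set by `sd`
od_physio_noise <- function(t, sd) {
  if (sd == 0) return(numeric(length(t)))
  f_lfo <- stats::runif(1, 0.02, 0.08)
  f_resp <- stats::runif(1, 0.2, 0.3)
  f_card <- stats::runif(1, 1.0, 1.2)
  ph <- stats::runif(5, 0, 2 * pi)
  sd * (0.4 * sin(2 * pi * 0.002 * t + ph[1]) +
        0.3 * sin(2 * pi * f_lfo * t + ph[2]) +
        0.5 * sin(2 * pi * 0.1 * t + ph[3]) +
        0.4 * sin(2 * pi * f_resp * t + ph[4]) +
        0.5 * sin(2 * pi * f_card * t + ph[5]) +
        0.4 * stats::rnorm(length(t)))
}

#' @export
print.bci_participant <- function(x, ...) {
  cat(sprintf("<bci_participant> %d trials (%s), EEG %d ch @ %g Hz, fNIRS %d ch @ %g Hz\n",
              nrow(x$events),
              paste(sprintf("%s=%d", names(table(x$events$class)),
                            table(x$events$class)), collapse = ", "),
              nrow(x$eeg$data), x$eeg$fs, nrow(x$od780$data), x$od780$fs))
  invisible(x)
}
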