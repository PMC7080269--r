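small_cfg <- function(...) {
  sim_config(n_trials_per_class = 4L, eeg_fs = 200, ...)
}

test_that("generation is bit-identical under a fixed seed", {
  p1 <- generate_participant(small_cfg(seed = 1))
  p2 <- generate_participant(small_cfg(seed = 1))
  expect_identical(p1$eeg$data, p2$eeg$data)
  expect_identical(p1$od780$data, p2$od780$data)
  expect_identical(p1$events, p2$events)
  p3 <- generate_participant(small_cfg(seed = 2))
  expect_false(identical(p1$eeg$data, p3$eeg$data))
})

test_that("trial structure follows the configured timing", {
  p <- generate_participant(small_cfg(seed = 3))
  ev <- p$events
  expect_equal(nrow(ev), 12)
  expect_equal(as.integer(table(ev$class)), rep(4L, 3))
  gaps <- diff(ev$onset_s)
  # consecutive onsets are instruction + task + rest apart
  expect_true(all(gaps >= 2 + 10 + 16 - 1e-9 & gaps <= 2 + 10 + 18 + 1e-9))
  # shared events across modalities
  expect_identical(p$eeg$events$onset_s, p$od805$events$onset_s)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(erd_depth = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(rest_range = c(18, 16)), "low")
  expect_error(sim_config(task_dur = 0), "positive")
  expect_error(sim_config(eeg_channels = character(0)), "empty")
  expect_error(sim_config(amp_variability = 1), "\\[0, 1\\)")
})

test_that("noise-free generation round-trips the planted hemodynamics exactly", {
  amp <- 0.05
  cfg <- small_cfg(seed = 4, noise_sd_od = 0, amp_variability = 0,
                   hrf_amp_hbo = amp, hrf_amp_hbr = -0.02)
  p <- generate_participant(cfg)
  hb <- od_to_hemoglobin(p$od780$data, p$od805$data, p$od830$data)
  # peak planted dHbO across MA epochs equals the configured amplitude
  # (the response kernel is peak-normalized, topography peaks at weight 1)
  fs <- p$od780$fs
  ma <- p$events[p$events$class == "MA", ]
  peaks <- vapply(seq_len(nrow(ma)), function(i) {
    idx <- round(ma$onset_s[i] * fs) + seq_len(16 * fs)
    max(hb$hbo[, idx])
  }, numeric(1))
  expect_equal(max(peaks), amp, tolerance = 1e-9)
  # HbR is planted downward, scaled by the same kernel
  troughs <- vapply(seq_len(nrow(ma)), function(i) {
    idx <- round(ma$onset_s[i] * fs) + seq_len(16 * fs)
    min(hb$hbr[, idx])
  }, numeric(1))
  expect_equal(min(troughs), -0.02, tolerance = 1e-9)
  # and idle-state epochs carry no planted effect
  is_ev <- p$events[p$events$class == "IS", ]
  idx0 <- round(is_ev$onset_s[1] * fs) + seq_len(5 * fs)
  expect_lt(max(abs(hb$hbo[, idx0])), amp / 2)
})

test_that("zero ERD depth leaves MI and IS mu power indistinguishable", {
  cfg <- sim_config(n_trials_per_class = 30L, eeg_fs = 200, erd_depth = 0,
                    seed = 5)
  p <- generate_participant(cfg)
  ep <- epoch_trials(p$eeg, c(0, 10))
  mu <- hybridbci:::band_filter_epochs(
    hybridbci:::subset_epochs(ep, channels = "C3"), c(8, 13))
  pow <- log(apply(mu$data[, 1, ], 1, var))
  pv <- t.test(pow[mu$labels == "MI"], pow[mu$labels == "IS"])$p.value
  expect_gt(pv, 0.01)
})

test_that("planted desynchronization lateralizes to left motor channels", {
  cfg <- sim_config(n_trials_per_class = 20L, eeg_fs = 200, erd_depth = 0.8,
                    amp_variability = 0, seed = 6)
  p <- generate_participant(cfg)
  ep <- epoch_trials(p$eeg, c(0, 10))
  mu <- hybridbci:::band_filter_epochs(ep, c(8, 13))
  med_pow <- function(ch, cl) {
    i <- match(ch, mu$channel_labels)
    median(log(apply(mu$data[mu$labels == cl, i, ], 1, var)))
  }
  erd_c3 <- med_pow("C3", "IS") - med_pow("C3", "MI")
  erd_c4 <- med_pow("C4", "IS") - med_pow("C4", "MI")
  expect_gt(erd_c3, erd_c4)     # contralateral dominance
  expect_gt(erd_c3, 0.5)        # strong attenuation on C3
})

test_that("the double-gamma response peaks at 6 s with a 1/6 undershoot", {
  tt <- seq(0, 40, by = 0.01)
  h <- hrf_double_gamma(tt)
  expect_equal(tt[which.max(h)], 6, tolerance = 0.02)
  expect_equal(max(h), 1 - (1 / 6) * (6 / 16)^16 * exp(10), tolerance = 1e-6)
  expect_lt(min(h), 0)                       # undershoot exists
  expect_equal(tt[which.min(h)], 16, tolerance = 0.5)
  expect_equal(hrf_double_gamma(0), 0)
})
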