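#' Configuration of a full synthetic study
#'
#' Bundles everything that determines a [run_study()] run: the cohort size,
#' the participant simulation settings (participant seeds are derived from
#' `sim$seed`), the cross-validation scheme, the EEG channel pair and the
#' source-detector arrangements evaluated for the hybrid system.
#'
#' @param n_participants Cohort size (default 18). Per-participant effect
#'   sizes are drawn around the configured values to mimic between-subject
#'   variability (see `heterogeneity`).
#' @param sim A [sim_config()]; participant `i` uses seed `sim$seed + i`.
#' @param cv A [cv_config()].
#' @param eeg_channel_pair EEG channels of the compact system (default
#'   Cz, C3).
#' @param sd_pair_counts Which SD-pair counts to evaluate (default 2:6); for
#'   each, the first arrangement of that size in `arrangements` is used.
#' @param arrangements Tibble as from [default_sd_arrangements()].
#' @param heterogeneity Relative spread of per-participant effect sizes
#'   (multiplicative jitter of `erd_depth` and HRF amplitudes; default 0.25).
#' @param run_selection Also run the channel/SD selection searches per
#'   participant (default `FALSE`; they dominate runtime).
#' @return A `study_config` list.
#' @export
study_config <- function(n_participants = 18L, sim = sim_config(),
                         cv = cv_config(), eeg_channel_pair = c("Cz", "C3"),
                         sd_pair_counts = 2:6,
                         arrangements = default_sd_arrangements(),
                         heterogeneity = 0.25,
                         run_selection = FALSE) {
  stopifnot(n_participants >= 1, inherits(sim, "sim_config"),
            inherits(cv, "cv_config"))
  structure(list(n_participants = as.integer(n_participants), sim = sim,
                 cv = cv, eeg_channel_pair = eeg_channel_pair,
                 sd_pair_counts = sd_pair_counts,
                 arrangements = arrangements,
                 heterogeneity = heterogeneity,
                 run_selection = isTRUE(run_selection)),
            class = "study_config")
}

# per-participant simulation config: derived seed plus jittered effect sizes
participant_sim_config <- function(config, i) {
  sim <- config$sim
  sim$seed <- sim$seed + i
  if (config$heterogeneity > 0) {
    jit <- withr::with_seed(sim$seed * 7L + 13L,
                            stats::runif(3, 1 - config$heterogeneity,
                                         1 + config$heterogeneity))
    sim$erd_depth <- min(1, sim$erd_depth * jit[1])
    sim$hrf_amp_hbo <- sim$hrf_amp_hbo * jit[2]
    sim$hrf_amp_hbr <- sim$hrf_amp_hbr * jit[3]
  }
  sim
}

#' Run a full synthetic study end to end
#'
#' Simulates a cohort, preprocesses every participant, and evaluates the
#' hybrid classifier for each configured SD-pair count (with the compact EEG
#' channel pair) plus the EEG-only system, via repeated stratified
#' cross-validation. With at least two participants the configurations are
#' compared with a Friedman test and FDR-corrected Wilcoxon post-hocs.
#' The report contains no timestamps, so identical configurations (including
#' seeds) give identical reports.
#'
#' @param config A [study_config()].
#' @return A `study_report`: list with `accuracies` (tibble: participant,
#'   configuration, accuracy, sd), `cv_results` (nested list), `comparison`
#'   (a [compare_configurations()] result or `NULL`), `selection` (per
#'   participant, if requested) and the `config`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  arr <- config$arrangements
  arr_by_count <- lapply(config$sd_pair_counts, function(np) {
    cand <- arr[arr$n_pairs == np, ]
    if (nrow(cand) == 0) stop("no arrangement with ", np, " SD pairs")
    cand[1, ]
  })
  rows <- list(); cv_results <- list(); selection <- list()
  for (i in seq_len(config$n_participants)) {
    sim_i <- participant_sim_config(config, i)
    part <- generate_participant(sim_i)
    pre <- preprocess_participant(part)
    trials <- prepare_trials(pre$eeg, pre$hbr, pre$hbo)
    pid <- sprintf("P%02d", i)
    res_i <- list()
    for (a in arr_by_count) {
      res <- cross_validate(trials, "hybrid", config$cv,
                            eeg_channels = config$eeg_channel_pair,
                            nirs_channels = a$channels[[1]])
      cfg_name <- sprintf("hybrid_%dpair", a$n_pairs)
      res_i[[cfg_name]] <- res
      rows[[length(rows) + 1]] <- tibble::tibble(
        participant = pid, configuration = cfg_name,
        accuracy = res$mean, sd = res$sd)
    }
    res <- cross_validate(trials, "eeg_only", config$cv,
                          eeg_channels = config$eeg_channel_pair)
    res_i[["eeg_only"]] <- res
    rows[[length(rows) + 1]] <- tibble::tibble(
      participant = pid, configuration = "eeg_only",
      accuracy = res$mean, sd = res$sd)
    if (config$run_selection) {
      selection[[pid]] <- list(
        sbs = sbs_channels(trials, cv = config$cv),
        sd = sd_pair_search(trials, arr, cv = config$cv))
    }
    cv_results[[pid]] <- res_i
  }
  accuracies <- dplyr::bind_rows(rows)
  comparison <- NULL
  if (config$n_participants >= 2 && length(unique(accuracies$configuration)) >= 2)
    comparison <- compare_configurations(
      accuracies[, c("configuration", "participant", "accuracy")])
  structure(list(accuracies = accuracies, cv_results = cv_results,
                 comparison = comparison,
                 selection = if (length(selection)) selection else NULL,
                 config = config), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d participants\n", x$config$n_participants))
  smry <- dplyr::summarise(dplyr::group_by(x$accuracies, .data$configuration),
                           mean = mean(.data$accuracy),
                           sd = stats::sd(.data$accuracy))
  print(smry)
  invisible(x)
}
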