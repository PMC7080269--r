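#' Write participants to the dataset container
#'
#' The container is a hierarchical directory: a top-level `manifest.json`
#' plus one subdirectory per participant holding the modality payloads
#' (`eeg.rds`, `od780.rds`, `od805.rds`, `od830.rds` — data matrix, sampling
#' rate, labels) and a shared `events.json` (onset in seconds and class per
#' trial). The round trip through [read_bci_dataset()] is lossless.
#'
#' @param x A `bci_participant` or a named list of them.
#' @param path Directory to create (must not already contain a manifest
#'   unless `overwrite = TRUE`).
#' @param overwrite Replace an existing container (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_bci_dataset <- function(x, path, overwrite = FALSE) {
  if (inherits(x, "bci_participant")) x <- list(participant_01 = x)
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1), "bci_participant")))
  if (is.null(names(x)) || any(names(x) == ""))
    names(x) <- sprintf("participant_%02d", seq_along(x))
  if (file.exists(file.path(path, "manifest.json")) && !overwrite)
    stop("container already exists at ", path, " (use overwrite = TRUE)")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(x)) {
    p <- x[[nm]]
    pdir <- file.path(path, nm)
    dir.create(pdir, showWarnings = FALSE)
    for (mod in c("eeg", "od780", "od805", "od830")) {
      rec <- p[[mod]]
      saveRDS(list(data = rec$data, fs = rec$fs,
                   channel_labels = rec$channel_labels,
                   modality = rec$modality),
              file.path(pdir, paste0(mod, ".rds")))
    }
    # RDS payload is authoritative (exact doubles); JSON copy for inspection
    saveRDS(p$events, file.path(pdir, "events.rds"))
    jsonlite::write_json(p$events, file.path(pdir, "events.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  jsonlite::write_json(list(format = "hybridbci-dataset", version = 1L,
                            participants = names(x)),
                       file.path(path, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a dataset container
#'
#' @param path Directory written by [write_bci_dataset()].
#' @return A named list of `bci_participant` objects (without simulation
#'   configs, which are not part of the container).
#' @export
read_bci_dataset <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no dataset manifest found at ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  out <- lapply(manifest$participants, function(nm) {
    pdir <- file.path(path, nm)
    ev_file <- file.path(pdir, "events.rds")
    if (!file.exists(ev_file))
      stop("malformed container: missing events for ", nm)
    events <- tibble::as_tibble(readRDS(ev_file))
    recs <- lapply(c("eeg", "od780", "od805", "od830"), function(mod) {
      f <- file.path(pdir, paste0(mod, ".rds"))
      if (!file.exists(f)) stop("malformed container: missing ", mod,
                                " for ", nm)
      r <- readRDS(f)
      raw_recording(r$data, r$fs, r$channel_labels, r$modality,
                    events[, c("onset_s", "class")])
    })
    structure(list(eeg = recs[[1]], od780 = recs[[2]], od805 = recs[[3]],
                   od830 = recs[[4]], events = events, config = NULL),
              class = "bci_participant")
  })
  names(out) <- manifest$participants
  out
}

#' EDF import adapter (not implemented)
#'
#' Placeholder for importing EEG recordings from European Data Format files.
#'
#' @param path Path to an EDF file.
#' @export
read_edf <- function(path) {
  stop("EDF import is not implemented; use the native dataset container ",
       "(read_bci_dataset) or construct raw_recording objects directly")
}

#' SNIRF import adapter (not implemented)
#'
#' Placeholder for importing fNIRS recordings from SNIRF files.
#'
#' @param path Path to a SNIRF file.
#' @export
read_snirf <- function(path) {
  stop("SNIRF import is not implemented; use the native dataset container ",
       "(read_bci_dataset) or construct raw_recording objects directly")
}
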