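sig6 <- function(x) signif(x, 6)

#' Write / read a cohort directory
#'
#' Plain-text layout: `subjects/<id>/continuous.csv` (wide, one column per
#' channel, microvolts, 6 significant digits), `subjects/<id>/events.csv`,
#' `montage.json`, `truth.json`, `outcomes.csv` and `config.yaml`
#' (informational summary of the generating configuration).
#'
#' @param cohort an `erp_cohort`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "erp_cohort"))
  dir.create(file.path(dir, "subjects"), recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$recordings)) {
    rec <- cohort$recordings[[id]]
    sd_ <- file.path(dir, "subjects", id)
    dir.create(sd_, showWarnings = FALSE)
    readr::write_csv(tibble::as_tibble(as.data.frame(sig6(rec$data))),
                     file.path(sd_, "continuous.csv"), progress = FALSE)
    readr::write_csv(rec$events, file.path(sd_, "events.csv"), progress = FALSE)
  }
  jsonlite::write_json(cohort$montage[c("quadrants", "excluded", "reference", "eog")],
                       file.path(dir, "montage.json"), pretty = TRUE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       digits = NA, pretty = TRUE)
  readr::write_csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
                   progress = FALSE)
  cfg <- cohort$config
  yaml::write_yaml(list(
    n_subjects = cfg$n_subjects, n_negative = cfg$n_negative,
    seed = cfg$seed,
    effects = lapply(cfg$effects, function(e)
      e[c("name", "phase", "applies_to", "mean_amplitude",
          "between_subject_sd", "onset", "offset", "ramp")]),
    noise = unclass(cfg$noise), artifact = unclass(cfg$artifact),
    timing = unclass(cfg$timing)),
    file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_cohort
#' @return `read_cohort()`: an `erp_cohort` (with `config = NULL`; the
#'   generating configuration is not reconstructed from disk).
#' @export
read_cohort <- function(dir) {
  mj <- jsonlite::read_json(file.path(dir, "montage.json"),
                            simplifyVector = TRUE)
  m <- montage(as.list(mj$quadrants), mj$excluded, mj$reference, mj$eog)
  ids <- sort(list.dirs(file.path(dir, "subjects"), recursive = FALSE,
                        full.names = FALSE))
  recordings <- lapply(ids, function(id) {
    sd_ <- file.path(dir, "subjects", id)
    dat <- as.matrix(readr::read_csv(file.path(sd_, "continuous.csv"),
                                     show_col_types = FALSE, progress = FALSE))
    ev <- readr::read_csv(file.path(sd_, "events.csv"),
                          show_col_types = FALSE, progress = FALSE)
    continuous_recording(id, dat, colnames(dat), ev)
  })
  names(recordings) <- ids
  truth <- tibble::as_tibble(jsonlite::read_json(file.path(dir, "truth.json"),
                                                 simplifyVector = TRUE))
  outcomes <- readr::read_csv(file.path(dir, "outcomes.csv"),
                              show_col_types = FALSE, progress = FALSE)
  structure(list(recordings = recordings, truth = truth,
                 outcomes = outcomes, montage = m, config = NULL),
            class = "erp_cohort")
}

#' Write / read an epoch collection
#'
#' `epochs.csv` holds the long-format samples (`trial`, `channel`,
#' `sample_index`, `uV`; 6 significant digits); `epochs_meta.json` holds
#' the trial table (conditions, kept flags, rejection log), channel order,
#' time axis and processing log. `write_epochs()` then `read_epochs()` is
#' the identity up to serialization precision, with metadata exact.
#'
#' @param epochs an `epoch_collection`.
#' @param path directory for the two files.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_collection"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(epochs$data)
  long <- tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(epochs$channels, each = d[1]), times = d[3]),
    sample_index = rep(seq_len(d[3]), each = d[1] * d[2]),
    uV = sig6(as.vector(epochs$data)))
  readr::write_csv(long, file.path(path, "epochs.csv"), progress = FALSE)
  jsonlite::write_json(list(
    subject_id = epochs$subject_id, channels = epochs$channels,
    time = epochs$time, fs = epochs$fs, baseline = epochs$baseline,
    trials = epochs$trials, log = epochs$log),
    file.path(path, "epochs_meta.json"), digits = NA, pretty = TRUE,
    auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "epochs_meta.json"),
                              simplifyVector = TRUE)
  long <- readr::read_csv(file.path(path, "epochs.csv"),
                          show_col_types = FALSE, progress = FALSE)
  nt <- max(long$trial); ns <- length(meta$time)
  channels <- meta$channels
  counts <- table(factor(long$trial, seq_len(nt)),
                  factor(long$channel, channels))
  if (any(counts != ns)) {
    bad <- which(counts != ns, arr.ind = TRUE)[1, ]
    abort(sprintf("epochs.csv schema violation: trial %s, channel %s has %d of %d samples",
                  rownames(counts)[bad[1]], colnames(counts)[bad[2]],
                  counts[bad[1], bad[2]], ns))
  }
  dat <- array(NA_real_, c(nt, length(channels), ns))
  dat[cbind(long$trial, match(long$channel, channels), long$sample_index)] <-
    long$uV
  dimnames(dat) <- list(NULL, channels, NULL)
  trials <- tibble::as_tibble(meta$trials)
  trials$reject_rule <- as.character(trials$reject_rule)
  structure(list(subject_id = meta$subject_id, data = dat, time = meta$time,
                 channels = channels, trials = trials, fs = meta$fs,
                 baseline = meta$baseline,
                 log = as.character(meta$log %||% character())),
            class = "epoch_collection")
}

# BrainVision (ASCII data format) ------------------------------------------

#' Export / import continuous recordings in BrainVision format
#'
#' Writes the standard `.vhdr` / `.vmrk` / `.dat` triplet using the ASCII,
#' multiplexed data layout (one sample per line, channels space-separated,
#' microvolts). Event markers are written as `Stimulus` markers whose
#' description encodes `phase/condition/block/item`. `read_brainvision()`
#' reads the same layout back by channel name; it supports only the ASCII
#' data format this writer produces.
#'
#' @param recording a `continuous_recording`.
#' @param basename path without extension; the three files are written as
#'   `<basename>.vhdr/.vmrk/.dat`.
#' @export
write_brainvision <- function(recording, basename) {
  stopifnot(inherits(recording, "continuous_recording"))
  stem <- basename(basename)
  ch <- recording$channels
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.dat", stem),
    sprintf("MarkerFile=%s.vmrk", stem),
    "DataFormat=ASCII",
    "DataOrientation=MULTIPLEXED",
    sprintf("NumberOfChannels=%d", length(ch)),
    sprintf("SamplingInterval=%d", as.integer(1e6 / recording$fs)),
    "[ASCII Infos]",
    "DecimalSymbol=.",
    "SkipLines=0",
    "SkipColumns=0",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(ch), ch))
  writeLines(hdr, paste0(basename, ".vhdr"), useBytes = TRUE)
  ev <- recording$events
  mk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "[Common Infos]",
    sprintf("DataFile=%s.dat", stem),
    "[Marker Infos]",
    "Mk1=New Segment,,1,1,0,0",
    if (nrow(ev)) sprintf("Mk%d=Stimulus,%s/%s/%d/%d,%d,1,0",
                          seq_len(nrow(ev)) + 1L, ev$phase, ev$condition,
                          ev$block, ev$item, ev$sample))
  writeLines(mk, paste0(basename, ".vmrk"), useBytes = TRUE)
  con <- file(paste0(basename, ".dat"), "w")
  on.exit(close(con))
  write.table(sig6(recording$data), con, row.names = FALSE,
              col.names = FALSE)
  invisible(basename)
}

bv_field <- function(lines, key) {
  hit <- grep(sprintf("^%s=", key), lines, value = TRUE)
  if (!length(hit)) abort(sprintf("BrainVision header: missing %s", key))
  sub(sprintf("^%s=", key), "", hit[1])
}

#' @rdname write_brainvision
#' @param vhdr path to the `.vhdr` header file.
#' @param subject_id subject id for the returned recording.
#' @export
read_brainvision <- function(vhdr, subject_id = basename(vhdr)) {
  lines <- readLines(vhdr, warn = FALSE)
  if (toupper(bv_field(lines, "DataFormat")) != "ASCII")
    abort("read_brainvision supports only the ASCII data format")
  nch <- as.integer(bv_field(lines, "NumberOfChannels"))
  fs <- 1e6 / as.numeric(bv_field(lines, "SamplingInterval"))
  ch <- vapply(seq_len(nch), function(i)
    strsplit(bv_field(lines, sprintf("Ch%d", i)), ",")[[1]][1], "")
  dir <- dirname(vhdr)
  dat <- as.matrix(utils::read.table(file.path(dir, bv_field(lines, "DataFile"))))
  if (ncol(dat) != nch) abort("BrainVision data/channel count mismatch")
  mk <- readLines(file.path(dir, bv_field(lines, "MarkerFile")), warn = FALSE)
  stim <- grep("^Mk\\d+=Stimulus,", mk, value = TRUE)
  ev <- if (length(stim)) {
    parts <- strsplit(sub("^Mk\\d+=", "", stim), ",")
    desc <- strsplit(vapply(parts, `[[`, "", 2), "/")
    tibble::tibble(
      sample = as.integer(vapply(parts, `[[`, "", 3)),
      phase = vapply(desc, `[[`, "", 1),
      condition = vapply(desc, `[[`, "", 2),
      block = as.integer(vapply(desc, function(d) d[3] %||% NA, "")),
      item = as.integer(vapply(desc, function(d) d[4] %||% NA, "")))
  } else tibble::tibble(sample = integer(), phase = character(),
                        condition = character(), block = integer(),
                        item = integer())
  continuous_recording(subject_id, dat, ch, ev, fs)
}
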