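#' Re-reference a recording to linked mastoids
#'
#' Subtracts the mean of the two mastoid channels from every scalp channel.
#' EOG channels (bipolar derivations) and the mastoids themselves are left
#' untouched.
#'
#' @param recording a `continuous_recording`.
#' @param montage a [montage] naming the mastoid and EOG channels.
#' @return The re-referenced `continuous_recording`.
#' @export
rereference <- function(recording, montage = default_montage()) {
  stopifnot(inherits(recording, "continuous_recording"))
  if (!all(montage$reference %in% recording$channels))
    abort(sprintf("missing mastoid channel(s): %s",
                  paste(setdiff(montage$reference, recording$channels),
                        collapse = ", ")))
  scalp <- setdiff(recording$channels, c(montage$reference, montage$eog))
  out <- subtract_ref(recording$data,
                      match(scalp, recording$channels),
                      match(montage$reference, recording$channels))
  colnames(out) <- recording$channels
  recording$data <- out
  recording$rereferenced <- TRUE
  recording
}

epoch_offsets <- function(fs = 200, window = c(-200, 800)) {
  seq(window[1] / 1000 * fs, window[2] / 1000 * fs - 1)
}

#' Cut a continuous recording into epochs
#'
#' One epoch per event, aligned 200 ms before word onset and extending to
#' 800 ms after it (half-open `[-200, 800)`: 200 samples at 200 Hz, sample
#' times `-200 + 5 i` ms). Events too close to the recording edges for a
#' full epoch are skipped with a logged warning rather than an error.
#' Baseline correction (subtraction of each epoch's `[-200, 0)` ms mean,
#' per channel) is applied by default.
#'
#' @param recording a `continuous_recording`.
#' @param window epoch span in ms, half-open (default `c(-200, 800)`).
#' @param baseline subtract the pre-stimulus mean (default TRUE).
#' @return An `epoch_collection`: trials x channels x samples array plus a
#'   trial table (`trial`, `sample`, `phase`, `condition`, `block`, `item`,
#'   `kept`, `reject_rule`).
#' @export
extract_epochs <- function(recording, window = c(-200, 800), baseline = TRUE) {
  stopifnot(inherits(recording, "continuous_recording"))
  fs <- recording$fs
  off <- epoch_offsets(fs, window)
  n <- nrow(recording$data)
  ev <- recording$events
  usable <- ev$sample + off[1] >= 1 & ev$sample + off[length(off)] <= n
  log <- character()
  if (any(!usable))
    log <- sprintf("skipped %d event(s) too close to the recording edge (samples: %s)",
                   sum(!usable), paste(ev$sample[!usable], collapse = ", "))
  ev <- ev[usable, , drop = FALSE]
  if (!nrow(ev)) abort("no usable events: every event is too close to an edge")
  nt <- nrow(ev)
  dat <- gather_epochs(recording$data,
                       as.integer(ev$sample + off[1]),
                       seq_along(recording$channels), length(off))
  dimnames(dat) <- list(NULL, recording$channels, NULL)
  time <- off / fs * 1000
  if (isTRUE(baseline)) {
    bl <- time < 0
    base <- rowMeans(dat[, , bl, drop = FALSE], dims = 2)
    dat <- dat - as.vector(base)               # recycles over samples
  }
  trials <- tibble::tibble(trial = seq_len(nt), sample = ev$sample,
                           phase = ev$phase, condition = ev$condition,
                           block = ev$block, item = ev$item,
                           kept = TRUE, reject_rule = NA_character_)
  structure(list(subject_id = recording$subject_id, data = dat,
                 time = time, channels = recording$channels,
                 trials = trials, fs = fs, baseline = isTRUE(baseline),
                 log = log),
            class = "epoch_collection")
}

#' @export
print.epoch_collection <- function(x, ...) {
  cat(sprintf("<epoch_collection> %s: %d trials (%d kept) x %d channels x %d samples [%g, %g) ms\n",
              x$subject_id, nrow(x$trials), sum(x$trials$kept),
              length(x$channels), length(x$time),
              min(x$time), max(x$time) + 1000 / x$fs))
  if (length(x$log)) cat("  log:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}

#' Screen epochs for artifacts
#'
#' Pure flagging: samples are never altered. A trial is rejected when
#' either rule fires on the analysis electrodes:
#'
#' * **amplitude** - any sample on any analysis electrode exceeds
#'   `amp_threshold` in absolute value (default +/-150 uV);
#' * **eog** - the absolute Pearson correlation between an analysis
#'   electrode and an EOG channel over the epoch reaches
#'   `eog_corr_threshold` (default 0.8) *and* that EOG channel's
#'   peak-to-peak amplitude is at least `eog_p2p_min` (default 50 uV).
#'   The peak-to-peak gate operationalizes "clear" ocular activity: quiet
#'   EOG channels cannot reject trials through chance correlations.
#'
#' @param epochs an `epoch_collection`.
#' @param montage a [montage].
#' @param amp_threshold rejection threshold in uV.
#' @param eog_corr_threshold absolute correlation threshold; `NULL` or
#'   values > 1 disable the EOG rule.
#' @param eog_p2p_min minimum EOG peak-to-peak (uV) for the EOG rule.
#' @return The `epoch_collection` with updated `kept` flags and a
#'   `reject_rule` entry (`"amplitude"` or `"eog"`) per rejected trial.
#' @export
reject_artifacts <- function(epochs, montage = default_montage(),
                             amp_threshold = 150, eog_corr_threshold = 0.8,
                             eog_p2p_min = 50) {
  stopifnot(inherits(epochs, "epoch_collection"))
  ach <- intersect(analysis_electrodes(montage), epochs$channels)
  if (!length(ach)) abort("no analysis electrodes present in the epochs")
  nt <- nrow(epochs$trials)
  rule <- rep(NA_character_, nt)

  amax <- apply(abs(epochs$data[, ach, , drop = FALSE]), 1, max)
  rule[amax > amp_threshold] <- "amplitude"

  eog <- intersect(montage$eog, epochs$channels)
  if (!is.null(eog_corr_threshold) && eog_corr_threshold <= 1 && length(eog)) {
    X <- epochs$data[, ach, , drop = FALSE]
    Xc <- X - as.vector(rowMeans(X, dims = 2))
    nX <- rowSums(Xc^2, dims = 2)                    # trials x electrodes
    na_ <- length(ach); ns <- dim(X)[3]
    for (ch in eog) {
      E <- epochs$data[, ch, , drop = TRUE]
      if (nt == 1) E <- matrix(E, 1)
      p2p <- apply(E, 1, function(v) diff(range(v)))
      Ec <- E - rowMeans(E)
      nE <- rowSums(Ec^2)
      E3 <- aperm(array(Ec, c(nt, ns, na_)), c(1, 3, 2))
      cross <- rowSums(Xc * E3, dims = 2)
      denom <- sqrt(outer(nE, rep(1, na_)) * nX)
      r <- abs(cross) / denom
      r[!is.finite(r)] <- 0
      hit <- p2p >= eog_p2p_min &
        apply(r, 1, max) >= eog_corr_threshold
      rule[is.na(rule) & hit] <- "eog"
    }
  }
  epochs$trials$kept <- is.na(rule)
  epochs$trials$reject_rule <- rule
  epochs
}
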