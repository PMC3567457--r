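#' Average kept trials of one condition into a subject ERP
#'
#' Pointwise mean over the *kept* trials matching `phase` and `condition`.
#' A subject with zero kept trials for the condition yields `NULL` with a
#' warning (the subject is excluded from that contrast downstream) rather
#' than an error.
#'
#' @param epochs an `epoch_collection` (after [reject_artifacts()]).
#' @param phase `"familiarization"` or `"test"`.
#' @param condition `"familiar"` or `"unfamiliar"`.
#' @return A `subject_erp` (channels x samples matrix with metadata), or
#'   `NULL` when no kept trials exist.
#' @export
average_condition <- function(epochs, phase, condition) {
  stopifnot(inherits(epochs, "epoch_collection"))
  sel <- which(epochs$trials$kept & epochs$trials$phase == phase &
                 epochs$trials$condition == condition)
  if (!length(sel)) {
    warn(sprintf("%s: no kept %s/%s trials; subject excluded from this contrast",
                 epochs$subject_id, phase, condition))
    return(NULL)
  }
  dat <- epochs$data[sel, , , drop = FALSE]
  avg <- colMeans(dat, dims = 1)
  rownames(avg) <- epochs$channels
  subject_erp(epochs$subject_id, phase, condition, avg, epochs$time,
              n_trials = length(sel))
}

subject_erp <- function(subject_id, phase, condition, data, time, n_trials) {
  rn <- rownames(data)
  structure(list(subject_id = subject_id, phase = phase,
                 condition = condition, data = data, time = time,
                 channels = rn, n_trials = n_trials),
            class = "subject_erp")
}

#' @export
print.subject_erp <- function(x, ...) {
  cat(sprintf("<subject_erp> %s %s/%s: %d channels x %d samples (%d trials)\n",
              x$subject_id, x$phase, x$condition, nrow(x$data),
              ncol(x$data), x$n_trials))
  invisible(x)
}

#' Familiar-minus-unfamiliar difference wave
#'
#' Pointwise subtraction with the package-wide sign convention
#' *familiarized minus unfamiliar*: a negative difference is the
#' "negative-going" familiarity response.
#'
#' @param familiar,unfamiliar `subject_erp`s of the same subject and phase.
#' @return A `subject_erp` with condition `"difference"`.
#' @export
difference_wave <- function(familiar, unfamiliar) {
  stopifnot(inherits(familiar, "subject_erp"),
            inherits(unfamiliar, "subject_erp"))
  if (!identical(dim(familiar$data), dim(unfamiliar$data)))
    abort("difference_wave: mismatched channel/sample dimensions")
  if (!identical(familiar$subject_id, unfamiliar$subject_id) ||
      !identical(familiar$phase, unfamiliar$phase))
    abort("difference_wave: ERPs must come from the same subject and phase")
  subject_erp(familiar$subject_id, familiar$phase, "difference",
              familiar$data - unfamiliar$data, familiar$time,
              n_trials = min(familiar$n_trials, unfamiliar$n_trials))
}

#' Grand average across subjects
#'
#' Unweighted mean of subject average waveforms (every subject counts
#' equally regardless of trial count).
#'
#' @param erps list of `subject_erp` (NULL entries, from subjects excluded
#'   for lack of trials, are dropped).
#' @return A `subject_erp` with subject id `"grand"`.
#' @export
grand_average <- function(erps) {
  erps <- purrr::compact(erps)
  if (!length(erps)) abort("grand_average: no subject ERPs supplied")
  acc <- Reduce(`+`, lapply(erps, `[[`, "data")) / length(erps)
  e1 <- erps[[1]]
  subject_erp("grand", e1$phase, e1$condition, acc, e1$time,
              n_trials = length(erps))
}

#' Window-mean amplitudes
#'
#' Mean amplitude per subject, condition and electrode over a half-open
#' latency window `[start, end)` ms. This is the quantity that enters the
#' repeated-measures ANOVAs and the responder classification.
#'
#' @param erps a `subject_erp` or a (possibly nested) list of them.
#' @param window `c(start, end)` in ms.
#' @param electrodes electrode subset (default: all analysis electrodes of
#'   `montage`).
#' @param montage a [montage] (adds quadrant / electrode-position columns).
#' @return A tibble of class `window_amplitudes` with columns `subject`,
#'   `phase`, `condition`, `electrode`, `quadrant`, `electrode_pos`,
#'   `n_trials`, `mean_uV`; the window is stored in `attr(, "window")`.
#' @export
window_means <- function(erps, window, electrodes = NULL,
                         montage = default_montage()) {
  if (inherits(erps, "subject_erp")) erps <- list(erps)
  erps <- purrr::compact(erps)
  flat <- list()
  for (e in erps) {
    if (inherits(e, "subject_erp")) flat <- c(flat, list(e))
    else flat <- c(flat, purrr::compact(e))
  }
  if (!length(flat)) abort("window_means: no ERPs supplied")
  electrodes <- electrodes %||% analysis_electrodes(montage)
  if (!length(electrodes)) abort("window_means: empty electrode set")
  et <- electrode_table(montage)
  out <- purrr::map_dfr(flat, function(e) {
    keep <- in_window(e$time, window)
    if (!any(keep)) abort("window lies outside the epoch span")
    el <- intersect(electrodes, e$channels)
    if (length(el) < length(electrodes))
      abort(sprintf("missing electrodes: %s",
                    paste(setdiff(electrodes, e$channels), collapse = ", ")))
    tibble::tibble(subject = e$subject_id, phase = e$phase,
                   condition = e$condition, electrode = el,
                   n_trials = e$n_trials,
                   mean_uV = unname(rowMeans(e$data[el, keep, drop = FALSE])))
  })
  out <- dplyr::left_join(out, et, by = "electrode")
  out <- out[c("subject", "phase", "condition", "electrode", "quadrant",
               "electrode_pos", "n_trials", "mean_uV")]
  structure(out, window = window,
            class = c("window_amplitudes", class(out)))
}

#' Per-subject mean amplitude over an electrode set
#'
#' Collapses a [window_means()] table to one value per subject (and
#' condition) by averaging the listed electrodes: the "electrode-set mean"
#' used for follow-up analyses such as the right-frontal four-electrode
#' subset or the left-frontal responder basis.
#'
#' @param amps a `window_amplitudes` tibble.
#' @param electrodes electrodes to average over.
#' @return Tibble `subject`, `phase`, `condition`, `mean_uV`.
#' @export
electrode_set_means <- function(amps, electrodes) {
  miss <- setdiff(electrodes, unique(amps$electrode))
  if (length(miss))
    abort(sprintf("missing electrodes: %s", paste(miss, collapse = ", ")))
  amps |>
    dplyr::filter(.data$electrode %in% electrodes) |>
    dplyr::group_by(.data$subject, .data$phase, .data$condition) |>
    dplyr::summarise(mean_uV = mean(.data$mean_uV), .groups = "drop")
}
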