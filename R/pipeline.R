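#' Analysis parameters of the ERP pipeline
#'
#' All stage parameters in one list, with the paradigm's values as
#' defaults: 1-30 Hz zero-phase band-pass, `[-200, 800)` ms epochs with
#' pre-stimulus baseline, +/-150 uV and EOG-correlation artifact screening,
#' the three analysis windows (familiarization 200-500 ms; test 350-450 and
#' 430-530 ms), the left-frontal 350-450 ms responder basis, and 50 ms /
#' 10 ms / run-of-5 onset scanning at alpha 0.05.
#'
#' @param ... overrides of the defaults listed above (unknown names error).
#' @return A named list of class `analyze_params`.
#' @export
analyze_params <- function(...) {
  def <- list(
    filter = TRUE, filter_low = 1, filter_high = 30,
    baseline = TRUE,
    amp_threshold = 150, eog_corr_threshold = 0.8, eog_p2p_min = 50,
    window_familiarization = c(200, 500),
    window_test_early = c(350, 450),
    window_test_late = c(430, 530),
    classification_window = c(350, 450),
    classification_electrodes = NULL,   # default: left-frontal quadrant
    rf_subset = c("F4", "F8", "FC4", "FT8"),
    lp_subset = c("LTP", "CP3", "P3"),
    onset_electrodes = c("FT8"),
    onset_search = c(0, 800), onset_bin = 50, onset_step = 10,
    onset_alpha = 0.05, onset_run = 5,
    run_anova = TRUE, run_onsets = TRUE)
  ov <- list(...)
  bad <- setdiff(names(ov), names(def))
  if (length(bad))
    abort(sprintf("unknown analysis parameter(s): %s",
                  paste(bad, collapse = ", ")))
  structure(modifyList(def, ov), class = "analyze_params")
}

#' Preprocess one subject: filter, re-reference, epoch, screen
#'
#' @param recording a `continuous_recording`.
#' @param montage a [montage].
#' @param params an [analyze_params()] list.
#' @return An `epoch_collection` with kept flags set.
#' @export
preprocess_subject <- function(recording, montage = default_montage(),
                               params = analyze_params()) {
  if (isTRUE(params$filter))
    recording <- bandpass_filter(recording, params$filter_low,
                                 params$filter_high)
  recording <- rereference(recording, montage)
  epochs <- extract_epochs(recording, baseline = params$baseline)
  reject_artifacts(epochs, montage,
                   amp_threshold = params$amp_threshold,
                   eog_corr_threshold = params$eog_corr_threshold,
                   eog_p2p_min = params$eog_p2p_min)
}

subject_condition_erps <- function(epochs) {
  out <- list(
    fam_familiar = average_condition(epochs, "familiarization", "familiar"),
    fam_unfamiliar = average_condition(epochs, "familiarization", "unfamiliar"),
    test_familiar = average_condition(epochs, "test", "familiar"),
    test_unfamiliar = average_condition(epochs, "test", "unfamiliar"))
  out$fam_difference <-
    if (!is.null(out$fam_familiar) && !is.null(out$fam_unfamiliar))
      difference_wave(out$fam_familiar, out$fam_unfamiliar)
  out$test_difference <-
    if (!is.null(out$test_familiar) && !is.null(out$test_unfamiliar))
      difference_wave(out$test_familiar, out$test_unfamiliar)
  out
}

#' Run the full analysis on a cohort
#'
#' Preprocesses every subject, forms condition averages and difference
#' waves, builds the window-amplitude tables, runs the
#' Familiarity x Quadrant x Electrode repeated-measures ANOVAs per window,
#' scans onsets on the test-phase difference wave, classifies responders by
#' left-frontal polarity and, when the cohort carries outcome scores,
#' computes the group comparisons and brain-behavior correlations.
#'
#' @param cohort an `erp_cohort` (or a list of `continuous_recording`s plus
#'   a montage via `montage =`).
#' @param params an [analyze_params()] list.
#' @param montage montage override when `cohort` is a bare recording list.
#' @param outcomes outcome tibble override.
#' @return A `segerp_report` list: `kept_trials`, `window_amplitudes`
#'   (named list of [window_means()] tables), `anovas`, `onsets`,
#'   `responders`, `group_comparisons`, `brain_behavior`, `two_effects`,
#'   `erps` (per-subject condition averages), `grand_averages`.
#' @export
analyze_cohort <- function(cohort, params = analyze_params(),
                           montage = NULL, outcomes = NULL) {
  if (inherits(cohort, "erp_cohort")) {
    recordings <- cohort$recordings
    montage <- montage %||% cohort$montage
    outcomes <- outcomes %||% cohort$outcomes
  } else {
    recordings <- cohort
    montage <- montage %||% default_montage()
  }
  erps <- lapply(recordings, function(rec)
    subject_condition_erps(preprocess_subject(rec, montage, params)))
  kept <- purrr::map_dfr(names(erps), function(id) {
    e <- erps[[id]]
    tibble::tibble(
      subject = id,
      fam_familiar = e$fam_familiar$n_trials %||% 0L,
      fam_unfamiliar = e$fam_unfamiliar$n_trials %||% 0L,
      test_familiar = e$test_familiar$n_trials %||% 0L,
      test_unfamiliar = e$test_unfamiliar$n_trials %||% 0L)
  })

  pick <- function(which) purrr::compact(lapply(erps, `[[`, which))
  conds <- function(prefix)
    c(pick(paste0(prefix, "_familiar")), pick(paste0(prefix, "_unfamiliar")),
      pick(paste0(prefix, "_difference")))

  complete_for <- function(prefix) {
    names(which(vapply(erps, function(e)
      !is.null(e[[paste0(prefix, "_familiar")]]) &&
        !is.null(e[[paste0(prefix, "_unfamiliar")]]), TRUE)))
  }
  fam_ok <- complete_for("fam"); test_ok <- complete_for("test")

  wa <- list(
    familiarization_200_500 = window_means(
      conds("fam"), params$window_familiarization, montage = montage),
    test_350_450 = window_means(
      conds("test"), params$window_test_early, montage = montage),
    test_430_530 = window_means(
      conds("test"), params$window_test_late, montage = montage))

  anovas <- NULL
  if (isTRUE(params$run_anova)) {
    anova_on <- function(tab, keep_subjects) {
      tab <- dplyr::filter(tab, .data$subject %in% keep_subjects,
                           .data$condition %in% c("familiar", "unfamiliar"))
      tryCatch(
        rm_anova(tab, dv = "mean_uV", subject = "subject",
                 within = c("condition", "quadrant", "electrode_pos")),
        error = function(e) NULL)
    }
    anovas <- list(
      familiarization_200_500 = anova_on(wa$familiarization_200_500, fam_ok),
      test_350_450 = anova_on(wa$test_350_450, test_ok),
      test_430_530 = anova_on(wa$test_430_530, test_ok))
  }

  onsets <- NULL
  if (isTRUE(params$run_onsets)) {
    tdiff <- pick("test_difference")
    onsets <- lapply(params$onset_electrodes, function(el) {
      if (length(tdiff) < 3) return(NULL)
      waves <- do.call(rbind, lapply(tdiff, function(e) e$data[el, ]))
      detect_onset(waves, tdiff[[1]]$time, search = params$onset_search,
                   bin = params$onset_bin, step = params$onset_step,
                   alpha = params$onset_alpha, run_length = params$onset_run)
    })
    names(onsets) <- params$onset_electrodes
  }

  cls_amps <- if (identical(params$classification_window,
                            params$window_test_early))
    wa$test_350_450
  else window_means(conds("test"), params$classification_window,
                    montage = montage)
  responders <- classify_responders(cls_amps, montage,
                                    electrodes = params$classification_electrodes)

  diff_set <- function(tab, electrodes)
    dplyr::filter(electrode_set_means(tab, electrodes),
                  .data$condition == "difference")[c("subject", "mean_uV")]
  two_effects <- tryCatch(
    correlate_two_effects(diff_set(wa$test_350_450, params$rf_subset),
                          diff_set(wa$test_430_530, params$lp_subset)),
    error = function(e) NULL)

  group_comparisons <- NULL; brain_behavior <- NULL
  if (!is.null(outcomes)) {
    group_comparisons <- tryCatch(compare_groups(responders, outcomes),
                                  error = function(e) NULL)
    brain_behavior <- tryCatch(
      correlate_effect_outcome(cls_amps, outcomes, montage,
                               electrodes = params$classification_electrodes),
      error = function(e) NULL)
  }

  grand <- list(
    fam_difference = tryCatch(grand_average(pick("fam_difference")),
                              error = function(e) NULL),
    test_difference = tryCatch(grand_average(pick("test_difference")),
                               error = function(e) NULL))

  structure(list(kept_trials = kept, window_amplitudes = wa,
                 anovas = anovas, onsets = onsets, responders = responders,
                 group_comparisons = group_comparisons,
                 brain_behavior = brain_behavior, two_effects = two_effects,
                 erps = erps, grand_averages = grand, params = params),
            class = "segerp_report")
}

#' @export
print.segerp_report <- function(x, ...) {
  cat("<segerp_report>\n")
  cat(sprintf("  subjects analysed: %d; mean kept trials (test, per condition): %.1f\n",
              nrow(x$kept_trials),
              mean((x$kept_trials$test_familiar +
                      x$kept_trials$test_unfamiliar) / 2)))
  if (!is.null(x$responders))
    cat(sprintf("  responders: %d negative / %d positive\n",
                sum(x$responders$label == "negative"),
                sum(x$responders$label == "positive")))
  if (!is.null(x$brain_behavior))
    cat(sprintf("  left-frontal effect vs word LQ: r = %.3f (p = %.3f), partial r = %.3f (p = %.3f)\n",
                x$brain_behavior$bivariate$r, x$brain_behavior$bivariate$p,
                x$brain_behavior$partial$r, x$brain_behavior$partial$p))
  for (nm in names(x$onsets))
    if (!is.null(x$onsets[[nm]]))
      cat(sprintf("  onset at %s: %s ms\n", nm,
                  format(x$onsets[[nm]]$onset)))
  invisible(x)
}
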