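#' Classify responders by left-frontal polarity
#'
#' Each subject's basis amplitude is the mean over the left-frontal
#' electrodes (F7, F3, FT7, FC3, C3) of the familiar-minus-unfamiliar
#' window mean in the test-phase 350-450 ms window. A strictly negative
#' basis gives a *negative responder* (the negative-going response that in
#' older infants marks speech segmentation); zero or positive gives a
#' *positive responder* (ties are a measure-zero event; assigning them to
#' the positive group keeps the rule deterministic).
#'
#' @param amps a [window_means()] table for the test phase containing both
#'   conditions (`familiar`, `unfamiliar`) on all left-frontal electrodes,
#'   or containing condition `"difference"`.
#' @param montage a [montage].
#' @param electrodes basis electrode set (default: the left-frontal
#'   quadrant; the all-five default is an assumption, override to probe a
#'   subset).
#' @return Tibble of class `responder_assignment`: `subject`, `label`
#'   (`"negative"`/`"positive"`), `basis_uV`.
#' @export
classify_responders <- function(amps, montage = default_montage(),
                                electrodes = NULL) {
  electrodes <- electrodes %||% montage$quadrants$left_frontal
  basis <- responder_basis(amps, electrodes)
  out <- basis |>
    dplyr::mutate(label = ifelse(.data$basis_uV < 0, "negative", "positive")) |>
    dplyr::select("subject", "label", "basis_uV")
  class(out) <- c("responder_assignment", class(out))
  out
}

responder_basis <- function(amps, electrodes) {
  sets <- electrode_set_means(amps, electrodes)
  if ("difference" %in% sets$condition) {
    sets |>
      dplyr::filter(.data$condition == "difference") |>
      dplyr::transmute(.data$subject, basis_uV = .data$mean_uV)
  } else {
    wide <- sets |>
      tidyr::pivot_wider(id_cols = "subject", names_from = "condition",
                         values_from = "mean_uV")
    if (!all(c("familiar", "unfamiliar") %in% names(wide)) ||
        anyNA(wide$familiar) || anyNA(wide$unfamiliar))
      abort("both test conditions are required for every subject")
    dplyr::transmute(wide, .data$subject,
                     basis_uV = .data$familiar - .data$unfamiliar)
  }
}

#' Compare responder groups on the language outcomes
#'
#' Pooled-variance Student t-tests (negative vs positive responders) for
#' each outcome measure: the three LQs, the SLAS composite and each SLAS
#' subscale.
#'
#' @param assignments a [classify_responders()] table.
#' @param outcomes an outcome tibble (see [generate_outcomes()]).
#' @param measures outcome columns to compare (default: all LQ/SLAS columns
#'   present).
#' @return Tibble: `measure`, `mean_negative`, `sd_negative`,
#'   `mean_positive`, `sd_positive`, `t`, `df`, `p`.
#' @export
compare_groups <- function(assignments, outcomes, measures = NULL) {
  d <- dplyr::inner_join(assignments, outcomes, by = "subject")
  if (nrow(d) < nrow(assignments))
    abort("every classified subject needs an outcome row")
  measures <- measures %||%
    intersect(c("LQ_comprehension", "LQ_sentence", "LQ_word",
                "SLAS_average", "SLAS_syntax", "SLAS_talkativeness",
                "SLAS_articulation"), names(outcomes))
  neg <- d[d$label == "negative", ]
  pos <- d[d$label == "positive", ]
  if (nrow(neg) < 2 || nrow(pos) < 2)
    abort("each responder group needs at least two members")
  purrr::map_dfr(measures, function(mcol) {
    tt <- two_sample_t(neg[[mcol]], pos[[mcol]])
    tibble::tibble(measure = mcol,
                   mean_negative = tt$mean_a, sd_negative = tt$sd_a,
                   mean_positive = tt$mean_b, sd_positive = tt$sd_b,
                   t = tt$t, df = tt$df, p = tt$p)
  })
}

#' Brain-behavior correlation of the familiarity effect
#'
#' Bivariate Pearson correlation between the left-frontal 350-450 ms
#' familiarity difference amplitude and word-production LQ, and the partial
#' correlation controlling comprehension and sentence-production LQs.
#' Negative correlations mean: the more negative (more mature) the
#' difference wave at 7 months, the higher the LQ at 3 years.
#'
#' @param amps test-phase [window_means()] table (350-450 ms window).
#' @param outcomes outcome tibble.
#' @param montage a [montage].
#' @param electrodes basis electrodes (default left-frontal quadrant).
#' @return List with elements `bivariate` and `partial`, each a
#'   `correlation_result` row.
#' @export
correlate_effect_outcome <- function(amps, outcomes,
                                     montage = default_montage(),
                                     electrodes = NULL) {
  electrodes <- electrodes %||% montage$quadrants$left_frontal
  basis <- responder_basis(amps, electrodes)
  d <- dplyr::inner_join(basis, outcomes, by = "subject")
  if (nrow(d) < 6) abort("need at least 6 subjects with basis and outcomes")
  list(
    bivariate = pearson_r(d$basis_uV, d$LQ_word),
    partial = partial_r(d$basis_uV, d$LQ_word,
                        d[c("LQ_comprehension", "LQ_sentence")]))
}

#' Correlation between the two test-phase familiarity effects
#'
#' Correlates, across subjects, the early right-frontal positive effect
#' (mean over F4, F8, FC4, FT8 in 350-450 ms) with the later left-posterior
#' negative effect (mean over LTP, CP3, P3 in 430-530 ms), both on the
#' familiar-minus-unfamiliar difference. A significant *positive*
#' correlation is the two-subpopulation signature: subjects with an early
#' positive effect keep a positive response, subjects with the later
#' negative effect never had the early positivity. A negative correlation
#' would instead mean both effects co-occur within subjects.
#'
#' @param early,late per-subject tibbles (`subject`, `mean_uV`) or plain
#'   numeric vectors over the same subjects in the same order.
#' @return A `correlation_result` row.
#' @export
correlate_two_effects <- function(early, late) {
  if (is.data.frame(early)) {
    d <- dplyr::inner_join(early, late, by = "subject",
                           suffix = c("_early", "_late"))
    x <- d$mean_uV_early; y <- d$mean_uV_late
  } else {
    x <- early; y <- late
  }
  pearson_r(x, y)
}
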