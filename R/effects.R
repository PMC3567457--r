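#' Specify a planted familiarity effect
#'
#' An effect spec describes one condition-difference component planted by the
#' synthetic-cohort generator: its phase (familiarization or test), which
#' responder subpopulation carries it, its amplitude distribution across
#' subjects, its time course (raised-cosine ramps around a plateau) and its
#' scalp topography (per-electrode weights).
#'
#' Amplitudes are expressed in *measured* microvolts: `mean_amplitude` is the
#' expected familiar-minus-unfamiliar mean that the full pipeline recovers in
#' `measure_window` over `reference_set`. Two conventions make this exact:
#' weights are normalized so their mean over `reference_set` is 1, and the
#' generator rescales the raw kernel so that the band-pass filter and
#' baseline correction of the measurement chain leave exactly
#' `mean_amplitude` in the window (see [filter_gain_for_effect()]).
#'
#' For test-phase effects carried by one subpopulation the per-subject
#' amplitude draw is sign-constrained (negative group strictly negative,
#' positive group non-negative) by truncated-normal sampling; the location
#' parameter is solved so that the *post-truncation* expectation equals
#' `mean_amplitude`, keeping parameter recovery centred on the configured
#' value.
#'
#' @param name identifier used in truth tables and reports.
#' @param phase `"familiarization"` or `"test"`.
#' @param applies_to `"all"`, `"negative_group"` or `"positive_group"`.
#' @param mean_amplitude expected measured amplitude, microvolts (signed).
#' @param between_subject_sd between-subject SD of the planted amplitude.
#' @param onset,offset kernel onset and plateau end, ms relative to word onset.
#' @param ramp raised-cosine ramp duration, ms.
#' @param electrode_weights named numeric vector, electrode -> unitless weight.
#' @param reference_set electrodes over which the measured window mean equals
#'   the planted amplitude; weights are renormalized to mean 1 over this set.
#' @param measure_window half-open window (ms) in which the effect is scored;
#'   defaults to `[onset + ramp, offset)`.
#' @param sign_constrained force per-subject draws to the sign of
#'   `mean_amplitude` (default `TRUE` for group-specific test effects).
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(name, phase = c("familiarization", "test"),
                        applies_to = c("all", "negative_group", "positive_group"),
                        mean_amplitude, between_subject_sd = 0,
                        onset, offset, ramp = 30,
                        electrode_weights, reference_set,
                        measure_window = NULL,
                        sign_constrained = NULL) {
  phase <- match.arg(phase)
  applies_to <- match.arg(applies_to)
  stopifnot(is.numeric(mean_amplitude), length(mean_amplitude) == 1,
            between_subject_sd >= 0, ramp >= 0)
  if (!(onset < offset)) abort("effect onset must precede offset")
  if (is.null(names(electrode_weights)))
    abort("electrode_weights must be a named vector")
  if (!all(reference_set %in% names(electrode_weights)))
    abort("reference_set electrodes must appear in electrode_weights")
  wbar <- mean(electrode_weights[reference_set])
  if (wbar <= 0) abort("mean weight over reference_set must be positive")
  electrode_weights <- electrode_weights / wbar
  measure_window <- measure_window %||% c(onset + ramp, offset)
  sign_constrained <- sign_constrained %||%
    (phase == "test" && applies_to != "all" && mean_amplitude != 0)
  structure(list(name = name, phase = phase, applies_to = applies_to,
                 mean_amplitude = mean_amplitude,
                 between_subject_sd = between_subject_sd,
                 onset = onset, offset = offset, ramp = ramp,
                 electrode_weights = electrode_weights,
                 reference_set = reference_set,
                 measure_window = measure_window,
                 sign_constrained = sign_constrained),
            class = "effect_spec")
}

#' Temporal kernel of an effect (unit amplitude)
#' @noRd
effect_kernel <- function(spec, time_ms) {
  k <- numeric(length(time_ms))
  on <- spec$onset; off <- spec$offset; r <- spec$ramp
  if (r > 0) {
    up <- time_ms >= on & time_ms < on + r
    k[up] <- 0.5 * (1 - cos(pi * (time_ms[up] - on) / r))
    dn <- time_ms > off & time_ms < off + r
    k[dn] <- 0.5 * (1 + cos(pi * (time_ms[dn] - off) / r))
  }
  k[time_ms >= on + r & time_ms <= off] <- 1
  k
}

#' Realize an effect as per-electrode waveforms
#'
#' Builds the deterministic waveform a subject with amplitude
#' `subject_amplitude` contributes in each electrode: zero before `onset`, a
#' raised-cosine ramp of `ramp` ms, a plateau at `subject_amplitude * weight`,
#' and a mirrored ramp down after `offset`. The mean over
#' `[onset + ramp, offset]` on the reference set equals `subject_amplitude`.
#'
#' @param spec an [effect_spec()].
#' @param subject_amplitude planted amplitude for this subject, microvolts.
#' @param time_ms numeric vector of sample times (ms relative to word onset).
#' @return Matrix electrodes x time (rownames = electrodes).
#' @examples
#' sp <- effect_spec("demo", "test", "all", 2, 0, onset = 300, offset = 460,
#'                   electrode_weights = c(F4 = 1, F8 = 1),
#'                   reference_set = c("F4", "F8"))
#' w <- synthesize_effect_waveform(sp, 2, seq(-200, 795, by = 5))
#' @export
synthesize_effect_waveform <- function(spec, subject_amplitude, time_ms) {
  k <- effect_kernel(spec, time_ms)
  out <- outer(spec$electrode_weights, subject_amplitude * k)
  rownames(out) <- names(spec$electrode_weights)
  out
}

#' Draw per-subject planted amplitudes
#'
#' Normal draws with optional sign truncation. Under truncation the location
#' is solved with [stats::uniroot()] so the truncated mean equals
#' `mean_amplitude`.
#' @noRd
draw_amplitudes <- function(spec, n) {
  mu <- spec$mean_amplitude; s <- spec$between_subject_sd
  if (n == 0) return(numeric(0))
  if (s == 0) return(rep(mu, n))
  if (!spec$sign_constrained) return(rnorm(n, mu, s))
  sgn <- sign(mu)
  etr <- function(m) m + s * dnorm(m / s) / pnorm(m / s) # E[X | X > 0]
  loc <- sgn * stats::uniroot(function(m) etr(m) - abs(mu),
                              interval = abs(mu) + c(-6, 2) * s,
                              extendInt = "upX", tol = 1e-10)$root
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), loc, s)
    ok <- if (sgn < 0) x < 0 else x >= 0
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

blank_weights <- function(m) {
  w <- rep(0, length(analysis_electrodes(m)))
  names(w) <- analysis_electrodes(m)
  w
}

quadrant_weights <- function(m, ...) {
  w <- blank_weights(m)
  vals <- list(...)
  for (q in names(vals)) w[m$quadrants[[q]]] <- vals[[q]]
  w
}

#' Default planted effects
#'
#' The three effects that give the synthetic cohort the structure of the
#' two-phase segmentation experiment:
#'
#' * `fam_repetition`: shared negative repetition effect for isolated words,
#'   mean -3.71 uV (SD 6.2) over the ten frontal electrodes in 200-500 ms,
#'   strongest left-frontally. Carried by every subject; the familiarized
#'   tokens (9-10) receive the full kernel and tokens 1-2 none, with a linear
#'   build-up in between.
#' * `test_positive`: positive test-phase effect of the positive-responder
#'   group, right-frontal topography, onset 300 ms, scored in 350-450 ms over
#'   the right-frontal quadrant. Its mean, 2.49 * 23/14 uV, is calibrated so
#'   the *cohort-pooled* right-frontal familiarity effect (negative
#'   responders contribute zero there) is +2.49 uV.
#' * `test_negative`: negative test-phase effect of the negative-responder
#'   group over the left-frontal and left-posterior quadrants, plateau
#'   spanning 350-530 ms so it is scored both in the 350-450 ms classification
#'   window and in the later 430-530 ms posterior window. Its mean (-3.8 uV)
#'   is a calibration choice that makes the pooled left-frontal effect of a
#'   9/14 cohort approximately cancel.
#'
#' @param m a [montage].
#' @return Named list of [effect_spec()] objects.
#' @export
default_effects <- function(m = default_montage()) {
  list(
    fam_repetition = effect_spec(
      "fam_repetition", "familiarization", "all",
      mean_amplitude = -3.71, between_subject_sd = 6.2,
      onset = 170, offset = 500, ramp = 30,
      electrode_weights = quadrant_weights(
        m, left_frontal = 1.15, right_frontal = 0.85,
        left_posterior = 0.30, right_posterior = 0.30),
      reference_set = c(m$quadrants$left_frontal, m$quadrants$right_frontal),
      measure_window = c(200, 500)),
    test_positive = effect_spec(
      "test_positive", "test", "positive_group",
      mean_amplitude = 2.49 * 23 / 14, between_subject_sd = 3.0,
      onset = 300, offset = 460, ramp = 30,
      electrode_weights = quadrant_weights(
        m, right_frontal = 1, left_frontal = 0.6,
        right_posterior = 0.5, left_posterior = 0.15),
      reference_set = m$quadrants$right_frontal,
      measure_window = c(350, 450)),
    test_negative = effect_spec(
      "test_negative", "test", "negative_group",
      mean_amplitude = -3.8, between_subject_sd = 3.0,
      onset = 320, offset = 540, ramp = 30,
      electrode_weights = quadrant_weights(
        m, left_frontal = 1, left_posterior = 0.8),
      reference_set = m$quadrants$left_frontal,
      measure_window = c(350, 450))
  )
}

#' Mean weight of an effect over an electrode set
#' @noRd
effect_set_weight <- function(spec, electrodes) {
  w <- spec$electrode_weights[electrodes]
  w[is.na(w)] <- 0
  mean(w)
}
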