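#' Background-noise model for synthetic EEG
#'
#' Channel-independent sum of 1/f ("pink") noise, a slow 0.3 Hz sinusoidal
#' drift with random phase (the component the 1 Hz offline high-pass exists
#' to remove), and white sensor noise. All amplitudes in microvolts.
#'
#' @param pink_rms RMS of the pink component (default 30).
#' @param drift_amplitude amplitude of the 0.3 Hz drift (default 20).
#' @param white_rms RMS of the white component (default 5).
#' @param scale convenience multiplier applied to all three components;
#'   `scale = 0` gives noise-free recordings, small values give the
#'   high-signal-to-noise regime used for classification checks.
#' @export
noise_config <- function(pink_rms = 30, drift_amplitude = 20, white_rms = 5,
                         scale = 1) {
  stopifnot(pink_rms >= 0, drift_amplitude >= 0, white_rms >= 0, scale >= 0)
  structure(list(pink_rms = pink_rms * scale,
                 drift_amplitude = drift_amplitude * scale,
                 white_rms = white_rms * scale),
            class = "noise_config")
}

#' Artifact process for synthetic EEG
#'
#' Two epoch-locked artifact types: eye blinks (a 400 ms half-sine on the
#' vertical EOG channel, propagated to scalp channels with frontally
#' decaying gains, detected downstream by the EOG-correlation rule) and
#' large-amplitude excursions on a random scalp channel (detected by the
#' +/-150 uV rule). Default probabilities are calibrated so the screened
#' trial-rejection rate falls in the mid-50s-to-60s percent range reported
#' for infant recordings of this kind.
#'
#' @param blink_prob_per_epoch probability an event epoch carries a blink.
#' @param blink_amplitude length-2 range of blink peak amplitudes (uV) on VEOG.
#' @param excursion_prob_per_epoch probability of a large excursion.
#' @param excursion_amplitude peak amplitude of the excursion (uV, > 150).
#' @param scale multiplier on both probabilities (`scale = 0`: artifact-free).
#' @export
artifact_config <- function(blink_prob_per_epoch = 0.42,
                            blink_amplitude = c(300, 500),
                            excursion_prob_per_epoch = 0.33,
                            excursion_amplitude = 400,
                            scale = 1) {
  p1 <- blink_prob_per_epoch * scale
  p2 <- excursion_prob_per_epoch * scale
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1,
            length(blink_amplitude) == 2, excursion_amplitude > 150)
  structure(list(blink_prob_per_epoch = p1,
                 blink_amplitude = sort(blink_amplitude),
                 excursion_prob_per_epoch = p2,
                 excursion_amplitude = excursion_amplitude),
            class = "artifact_config")
}

#' Outcome model linking the planted ERP effect to 3-year language scores
#'
#' Language quotients (LQs) are age-normed scores with population mean 100
#' and SD 15. The cohort is a typically developing, somewhat above-average
#' sample: its word-production LQ is generated with cohort mean
#' `lq_means["word"]` and SD `lq_sds["word"]`, a standardized link of
#' strength `erp_lq_link` to the planted left-frontal test-phase amplitude
#' (negative direction: more negative effect, higher LQ), and a
#' group-placement term that puts the negative responders' mean at
#' `100 + 15 * negative_group_offset` points. The placement term is built
#' from the component of group membership orthogonal (in-sample) to the
#' standardized amplitude, so it does not alter the amplitude-LQ
#' correlation. `negative_group_offset = 0` disables placement entirely.
#'
#' Comprehension and sentence-production LQs and the parent-rated SLAS
#' subscales load on the same latent ability (the systematic part of the
#' word-LQ model) with loading `inter_test_loading`; SLAS ratings are
#' clipped to the 1-7 scale.
#'
#' @param lq_population_mean,lq_population_sd the LQ norm scale (100, 15).
#' @param erp_lq_link standardized amplitude-to-word-LQ link in `[-1, 1]`
#'   (default 0.47; applied with negative sign).
#' @param lq_means,lq_sds named per-test cohort means and SDs
#'   (comprehension, sentence, word).
#' @param negative_group_offset negative responders' mean word LQ elevation
#'   above the norm mean, in norm-SD units (default 1.5; 0 disables).
#' @param slas_mean,slas_sd SLAS rating location and spread on the 1-7 scale.
#' @param inter_test_loading loading of the secondary outcomes on the shared
#'   ability factor.
#' @export
outcome_config <- function(lq_population_mean = 100, lq_population_sd = 15,
                           erp_lq_link = 0.47,
                           lq_means = c(comprehension = 115.4,
                                        sentence = 113.9, word = 118.9),
                           lq_sds = c(comprehension = 11.8,
                                      sentence = 14.7, word = 11.2),
                           negative_group_offset = 1.5,
                           slas_mean = 4.7, slas_sd = 0.9,
                           inter_test_loading = 0.65) {
  if (abs(erp_lq_link) > 1) abort("erp_lq_link must lie in [-1, 1]")
  stopifnot(all(lq_sds > 0), lq_population_sd > 0, slas_sd > 0,
            abs(inter_test_loading) <= 1,
            all(c("comprehension", "sentence", "word") %in% names(lq_means)),
            all(c("comprehension", "sentence", "word") %in% names(lq_sds)))
  structure(list(lq_population_mean = lq_population_mean,
                 lq_population_sd = lq_population_sd,
                 erp_lq_link = erp_lq_link,
                 lq_means = lq_means, lq_sds = lq_sds,
                 negative_group_offset = negative_group_offset,
                 slas_mean = slas_mean, slas_sd = slas_sd,
                 inter_test_loading = inter_test_loading),
            class = "outcome_config")
}

#' Normative outcome configuration
#'
#' The outcome model evaluated on the norm population itself: LQ mean 100,
#' SD 15 for every test, no group placement. Used to check that generated
#' scores respect the LQ scale definition.
#' @export
norm_outcome_config <- function() {
  outcome_config(lq_means = c(comprehension = 100, sentence = 100, word = 100),
                 lq_sds = c(comprehension = 15, sentence = 15, word = 15),
                 negative_group_offset = 0)
}

#' Stimulus timing of the simulated experiment
#'
#' Onset-to-onset intervals of the simulated word onsets. The `"paper"`
#' profile reproduces the published presentation rate (isolated tokens
#' roughly every 3.2 s: 0.71 s word + 2.5 s silence; sentence-embedded
#' targets every 8.3 s). The `"compact"` profile keeps every statistical
#' property of the cohort (trial counts, effects, noise, artifact rates;
#' epochs never overlap and filter-transient leakage between neighbouring
#' epochs is below 0.02 uV) while shrinking the dead time between events,
#' and is used for simulation studies with many replicate cohorts.
#'
#' @param profile `"paper"` or `"compact"`.
#' @param token_soa_s,sentence_soa_s,lead_in_s,inter_block_gap_s overrides (s).
#' @export
timing_config <- function(profile = c("paper", "compact"),
                          token_soa_s = NULL, sentence_soa_s = NULL,
                          lead_in_s = NULL, inter_block_gap_s = NULL) {
  profile <- match.arg(profile)
  def <- switch(profile,
    paper   = list(token_soa_s = 3.21, sentence_soa_s = 8.28),
    compact = list(token_soa_s = 2.50, sentence_soa_s = 2.50))
  out <- list(token_soa_s = token_soa_s %||% def$token_soa_s,
              sentence_soa_s = sentence_soa_s %||% def$sentence_soa_s,
              lead_in_s = lead_in_s %||% 3,
              inter_block_gap_s = inter_block_gap_s %||% 2)
  stopifnot(out$token_soa_s >= 1.2, out$sentence_soa_s >= 1.2,
            out$lead_in_s >= 1.5)
  structure(out, class = "timing_config")
}

#' Measurement-chain parameters assumed by the generator
#'
#' The preprocessing settings under which planted amplitudes are expressed
#' (band-pass edges, baseline correction, sampling rate). Planted kernels
#' are rescaled so that *this* measurement chain recovers the configured
#' amplitude exactly; analysing a cohort with different settings recovers a
#' correspondingly scaled amplitude.
#' @param filter_low,filter_high band edges in Hz; `NULL` filter_low disables.
#' @param baseline logical, subtract the pre-stimulus `[-200, 0)` ms mean.
#' @param fs sampling rate in Hz (fixed at 200 for this paradigm).
#' @export
measurement_config <- function(filter_low = 1, filter_high = 30,
                               baseline = TRUE, fs = 200) {
  structure(list(filter_low = filter_low, filter_high = filter_high,
                 baseline = baseline, fs = fs),
            class = "measurement_config")
}

#' Configuration of a synthetic cohort
#'
#' Bundles everything [generate_cohort()] needs: cohort size and responder
#' split, per-subject block-count distribution (mean 13, range 8-20,
#' realized as 8 + Binomial(12, 5/12)), trial structure (10 familiarization
#' tokens, then 8 test sentences per block: 4 with the familiarized target,
#' 4 with the unfamiliar control), the planted effects, noise, artifact and
#' outcome models, stimulus timing, and the master seed.
#'
#' @param n_subjects cohort size (default 23, the outcome-linked subsample;
#'   use 28 for ERP-phase-only runs).
#' @param n_negative number of negative responders (default 9).
#' @param blocks_per_subject `NULL` for the default distribution, or a fixed
#'   count, or a length-2 range to sample uniformly.
#' @param tokens_per_familiarization isolated tokens per block (10).
#' @param sentences_per_test sentence-embedded targets per block (8).
#' @param effects list of [effect_spec()]; default [default_effects()].
#' @param noise a [noise_config()].
#' @param artifact an [artifact_config()].
#' @param outcome an [outcome_config()].
#' @param timing a [timing_config()].
#' @param measurement a [measurement_config()].
#' @param compensate_filter plant kernels in measured units (default TRUE).
#' @param simulate_excluded also simulate the seven excluded electrodes
#'   (default TRUE; they carry noise only and are never analysed, so
#'   large simulation studies can drop them).
#' @param montage a [montage].
#' @param seed master integer seed.
#' @export
cohort_config <- function(n_subjects = 23, n_negative = 9,
                          blocks_per_subject = NULL,
                          tokens_per_familiarization = 10,
                          sentences_per_test = 8,
                          effects = NULL,
                          noise = noise_config(),
                          artifact = artifact_config(),
                          outcome = outcome_config(),
                          timing = timing_config("paper"),
                          measurement = measurement_config(),
                          compensate_filter = TRUE,
                          simulate_excluded = TRUE,
                          montage = default_montage(),
                          seed = 1L) {
  if (!is_count(n_subjects)) abort("n_subjects must be a positive count")
  if (!(is.numeric(n_negative) && n_negative >= 0 &&
        n_negative == round(n_negative)))
    abort("n_negative must be a non-negative count")
  if (n_negative > n_subjects)
    abort("n_negative cannot exceed n_subjects")
  stopifnot(is_count(tokens_per_familiarization), is_count(sentences_per_test),
            sentences_per_test %% 2 == 0)
  effects <- effects %||% default_effects(montage)
  if (is.null(names(effects)))
    names(effects) <- vapply(effects, `[[`, "", "name")
  epoch_span <- c(-200, 800)
  for (ef in effects) {
    if (ef$onset < epoch_span[1] || ef$offset + ef$ramp > epoch_span[2])
      abort(sprintf("effect '%s' window lies outside the epoch span [-200, 800)",
                    ef$name))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_negative = as.integer(n_negative),
                 blocks_per_subject = blocks_per_subject,
                 tokens_per_familiarization = as.integer(tokens_per_familiarization),
                 sentences_per_test = as.integer(sentences_per_test),
                 effects = effects, noise = noise, artifact = artifact,
                 outcome = outcome, timing = timing,
                 measurement = measurement,
                 compensate_filter = isTRUE(compensate_filter),
                 simulate_excluded = isTRUE(simulate_excluded),
                 montage = montage, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Noise-free, artifact-free variant of a config (used by exactness tests)
#' @param config a [cohort_config()].
#' @export
noise_free <- function(config) {
  config$noise <- noise_config(scale = 0)
  config$artifact <- artifact_config(scale = 0)
  config
}

draw_block_count <- function(spec) {
  if (is.null(spec)) return(8L + stats::rbinom(1, 12, 5 / 12))
  if (length(spec) == 1) return(as.integer(spec))
  as.integer(sample(seq(spec[1], spec[2]), 1))
}
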