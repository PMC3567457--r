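test_that("identical config and seed give byte-identical cohorts", {
  c1 <- generate_cohort(quick_config(seed = 33))
  c2 <- generate_cohort(quick_config(seed = 33))
  expect_identical(serialize(c1, NULL), serialize(c2, NULL))
  c3 <- generate_cohort(quick_config(seed = 34))
  expect_false(identical(c1$recordings[[1]]$data, c3$recordings[[1]]$data))
})

test_that("group assignment honours the configured responder split", {
  coh <- generate_cohort(cohort_config(n_subjects = 23, n_negative = 9,
                                       blocks_per_subject = 1,
                                       noise = noise_config(scale = 0),
                                       artifact = artifact_config(scale = 0),
                                       timing = timing_config("compact"),
                                       seed = 2))
  expect_equal(sum(coh$truth$group == "negative"), 9)
  expect_equal(sum(coh$truth$group == "positive"), 14)
  # negative responders carry the negative effect, positives the positive one
  expect_true(all(coh$truth$amp_test_negative[coh$truth$group == "negative"] < 0))
  expect_true(all(coh$truth$amp_test_negative[coh$truth$group == "positive"] == 0))
  expect_true(all(coh$truth$amp_test_positive[coh$truth$group == "positive"] >= 0))
  expect_error(cohort_config(n_subjects = 5, n_negative = 9),
               "cannot exceed")
})

test_that("a noise-free single-effect cohort reproduces the kernel in every epoch", {
  m <- default_montage()
  eff <- effect_spec("step", "test", "all", mean_amplitude = 2,
                     between_subject_sd = 0, onset = 300, offset = 460,
                     ramp = 30,
                     electrode_weights = segerp:::quadrant_weights(
                       m, right_frontal = 1),
                     reference_set = m$quadrants$right_frontal)
  cfg <- cohort_config(n_subjects = 2, n_negative = 0,
                       blocks_per_subject = 2, effects = list(step = eff),
                       noise = noise_config(scale = 0),
                       artifact = artifact_config(scale = 0),
                       timing = timing_config("compact"),
                       compensate_filter = FALSE, seed = 8)
  coh <- generate_cohort(cfg)
  # analysed without filtering, the epoch difference equals the kernel exactly
  ep <- preprocess_subject(coh$recordings[[1]], m,
                           analyze_params(filter = FALSE))
  expect_true(all(ep$trials$kept))
  erps <- segerp:::subject_condition_erps(ep)
  d <- difference_wave(erps$test_familiar, erps$test_unfamiliar)
  kern <- synthesize_effect_waveform(eff, 2, d$time)
  expect_equal(d$data[rownames(kern), ], kern, tolerance = 1e-10,
               ignore_attr = TRUE)
  # and the familiar epochs themselves hold the planted kernel
  fam_trials <- which(ep$trials$phase == "test" &
                        ep$trials$condition == "familiar")
  expect_equal(ep$data[fam_trials[1], "F4", ], kern["F4", ],
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("cohort-mean measured amplitudes converge to the planted means", {
  # moderate-size replication with default noise and artifacts; tolerance is
  # three Monte-Carlo standard errors of the measured cohort mean
  res <- purrr::map_dfr(1:10, function(s) {
    coh <- generate_cohort(cohort_config(
      n_subjects = 16, n_negative = 6, timing = timing_config("compact"),
      simulate_excluded = FALSE, seed = 400 + s))
    rep <- analyze_cohort(coh, analyze_params(run_anova = FALSE,
                                              run_onsets = FALSE))
    wa <- rep$window_amplitudes$familiarization_200_500
    fam <- dplyr::filter(wa, .data$condition == "difference",
                         .data$quadrant %in% c("left_frontal", "right_frontal"))
    fam <- dplyr::summarise(dplyr::group_by(fam, .data$subject),
                            m = mean(.data$mean_uV))
    fam <- dplyr::left_join(fam, coh$truth, by = "subject")
    tibble::tibble(meas = fam$m, planted = fam$amp_fam_repetition)
  })
  err <- res$meas - res$planted
  se <- sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), 3 * se + 0.15)
  # oracle: direct average of planted truth amplitudes
  expect_equal(mean(res$meas), mean(res$planted), tolerance = 3 * se + 0.15)
})

test_that("block counts follow the configured distribution", {
  coh <- generate_cohort(cohort_config(n_subjects = 40, n_negative = 10,
                                       blocks_per_subject = NULL,
                                       noise = noise_config(scale = 0),
                                       artifact = artifact_config(scale = 0),
                                       timing = timing_config("compact"),
                                       seed = 3))
  expect_true(all(coh$truth$n_blocks >= 8 & coh$truth$n_blocks <= 20))
  expect_equal(mean(coh$truth$n_blocks), 13, tolerance = 1.2)
  # 10 familiarization tokens then 8 test events per block
  ev <- coh$recordings[[1]]$events
  b1 <- ev[ev$block == 1, ]
  expect_equal(sum(b1$phase == "familiarization"), 10)
  expect_equal(sum(b1$phase == "test"), 8)
  expect_equal(sum(b1$phase == "test" & b1$condition == "familiar"), 4)
})

test_that("outcome generation realizes the configured link and calibration", {
  mk_truth <- function(n, p = 9 / 23, seed = 1) {
    withr::with_seed(seed, {
      g <- ifelse(runif(n) < p, "negative", "positive")
      a <- ifelse(g == "negative", -abs(rnorm(n, -3.8, 3)),
                  0.6 * abs(rnorm(n, 4.09, 3)))
    })
    tibble::tibble(subject = sprintf("S%05d", 1:n), group = g, lf_basis = a)
  }

  # beta = 0: no amplitude-LQ correlation
  tr <- mk_truth(10000, seed = 2)
  o0 <- generate_outcomes(tr, outcome_config(erp_lq_link = 0), seed = 5)
  expect_lt(abs(cor(tr$lf_basis, o0$LQ_word)), 0.03)

  # beta = 1, no group placement: deterministic link, |r| = 1
  o1 <- generate_outcomes(tr, outcome_config(erp_lq_link = 1,
                                             negative_group_offset = 0),
                          seed = 5)
  expect_equal(cor(tr$lf_basis, o1$LQ_word), -1, tolerance = 1e-10)

  # beta = 0.47 at large n: r close to -0.47, calibrated mean/SD
  tr2 <- mk_truth(40000, seed = 3)
  oc <- outcome_config()
  o <- generate_outcomes(tr2, oc, seed = 7)
  expect_equal(cor(tr2$lf_basis, o$LQ_word), -0.47, tolerance = 0.01)
  expect_equal(mean(o$LQ_word), 118.9, tolerance = 1)
  expect_equal(sd(o$LQ_word), 11.2, tolerance = 1)
  # negative responders' mean word LQ sits ~1.5 norm SDs above 100
  elev <- (mean(o$LQ_word[tr2$group == "negative"]) - 100) / 15
  expect_equal(elev, 1.5, tolerance = 0.05)
  # SLAS ratings respect the 1-7 scale
  expect_true(all(o$SLAS_average >= 1 & o$SLAS_average <= 7))
  expect_equal(mean(o$SLAS_average), 4.7, tolerance = 0.15)
  expect_error(generate_outcomes(tr, outcome_config(erp_lq_link = 1.2)),
               "\\[-1, 1\\]")
})

test_that("planted artifacts are logged with their type and channel", {
  cfg <- quick_config(seed = 9)
  cfg$noise <- noise_config(scale = 0)
  coh <- generate_cohort(cfg)
  art <- coh$recordings[[1]]$artifacts
  expect_true(all(art$type %in% c("blink", "excursion")))
  expect_true(all(art$channel[art$type == "blink"] == "VEOG"))
  expect_true(all(art$channel[art$type == "excursion"] %in%
                    analysis_electrodes(coh$montage)))
})
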