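lf_amps <- function(basis, subjects = sprintf("S%02d", seq_along(basis))) {
  # minimal window-amplitude table: left-frontal electrodes carry the basis
  # value on the difference; other electrodes zero
  m <- default_montage()
  et <- electrode_table(m)
  purrr::map_dfr(seq_along(basis), function(i)
    dplyr::mutate(et,
                  subject = subjects[i], phase = "test",
                  condition = "difference", n_trials = 10L,
                  mean_uV = ifelse(.data$quadrant == "left_frontal",
                                   basis[i], 0)))
}

lf_amps_from_truth <- function(truth) lf_amps(truth$lf_basis, truth$subject)

test_that("classification follows the sign of the left-frontal basis", {
  cls <- classify_responders(lf_amps(c(-0.5, 0.5, 0)))
  expect_equal(cls$label, c("negative", "positive", "positive"))  # tie -> positive
  expect_equal(cls$basis_uV, c(-0.5, 0.5, 0))
})

test_that("classification accepts familiar/unfamiliar condition pairs", {
  m <- default_montage()
  et <- electrode_table(m)
  amps <- purrr::map_dfr(c(familiar = 1, unfamiliar = 3), function(v)
    dplyr::mutate(et, subject = "S01", phase = "test",
                  n_trials = 5L, mean_uV = v),
    .id = "condition")
  cls <- classify_responders(amps)
  expect_equal(cls$basis_uV, -2)
  expect_equal(cls$label, "negative")
  expect_error(classify_responders(dplyr::filter(amps, condition == "familiar")),
               "both test conditions")
})

test_that("the default seeded cohort recovers the 9/14 split at high SNR", {
  cfg <- cohort_config(n_subjects = 23, n_negative = 9,
                       noise = noise_config(scale = 0.02),
                       artifact = artifact_config(scale = 0),
                       timing = timing_config("compact"),
                       simulate_excluded = FALSE, seed = 1)
  coh <- generate_cohort(cfg)
  rep <- analyze_cohort(coh, analyze_params(run_anova = FALSE,
                                            run_onsets = FALSE))
  cls <- dplyr::inner_join(rep$responders, coh$truth, by = "subject")
  expect_equal(sum(cls$label == "negative"), 9)
  expect_equal(sum(cls$label == "positive"), 14)
  expect_true(all(cls$label == cls$group))   # 100% agreement with truth
})

test_that("group comparisons use the pooled t and recover planted offsets", {
  # toy 3 vs 3 with hand-computed pooled t
  assign <- tibble::tibble(subject = sprintf("S%d", 1:6),
                           label = rep(c("negative", "positive"), each = 3),
                           basis_uV = c(-1, -2, -3, 1, 2, 3))
  out <- tibble::tibble(subject = assign$subject,
                        LQ_word = c(0, 1, 2, 3, 4, 5))
  cmp <- compare_groups(assign, out, measures = "LQ_word")
  expect_equal(cmp$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(cmp$df, 4)

  # identical outcome distributions -> t = 0
  out2 <- out; out2$LQ_word <- rep(c(2, 4, 6), 2)
  expect_equal(compare_groups(assign, out2, measures = "LQ_word")$t, 0)

  expect_error(compare_groups(assign[c(1, 4:6), ], out[c(1, 4:6), ]),
               "at least two members")

  # planted 1.5-SD group placement recovered on a large simulated cohort
  withr::with_seed(31, {
    n <- 4000
    g <- ifelse(runif(n) < 9 / 23, "negative", "positive")
    a <- ifelse(g == "negative", -abs(rnorm(n, -3.8, 3)),
                0.6 * abs(rnorm(n, 4.09, 3)))
  })
  truth <- tibble::tibble(subject = sprintf("S%04d", 1:n), group = g,
                          lf_basis = a)
  oc <- generate_outcomes(truth, outcome_config(), seed = 8)
  assign2 <- tibble::tibble(subject = truth$subject,
                            label = truth$group, basis_uV = truth$lf_basis)
  cmp2 <- compare_groups(assign2, oc, measures = "LQ_word")
  expect_equal((cmp2$mean_negative - 100) / 15, 1.5, tolerance = 0.08)
})

test_that("group comparison on permuted labels rejects at ~alpha", {
  withr::with_seed(12, {
    outcomes <- tibble::tibble(subject = sprintf("S%02d", 1:23),
                               LQ_word = rnorm(23, 118.9, 11.2))
    p <- vapply(1:600, function(i) {
      lab <- sample(rep(c("negative", "positive"), c(9, 14)))
      a <- tibble::tibble(subject = outcomes$subject, label = lab,
                          basis_uV = 0)
      compare_groups(a, outcomes, measures = "LQ_word")$p
    }, numeric(1))
  })
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("brain-behavior correlations match their oracles", {
  # beta = 0 generator: r near zero
  withr::with_seed(41, {
    n <- 2000
    g <- ifelse(runif(n) < 0.4, "negative", "positive")
    a <- ifelse(g == "negative", -abs(rnorm(n, -3.8, 3)),
                0.6 * abs(rnorm(n, 4.09, 3)))
  })
  truth <- tibble::tibble(subject = sprintf("S%04d", 1:n), group = g,
                          lf_basis = a)
  o0 <- generate_outcomes(truth, outcome_config(erp_lq_link = 0), seed = 3)
  cor0 <- correlate_effect_outcome(lf_amps_from_truth(truth), o0)
  expect_lt(abs(cor0$bivariate$r), 0.06)

  # toy 8-subject table: partial r against the residual-regression oracle
  withr::with_seed(55, {
    d <- tibble::tibble(subject = sprintf("S%02d", 1:8),
                        basis = rnorm(8), comp = rnorm(8), sent = rnorm(8))
    d$word <- -0.5 * d$basis + 0.4 * d$comp + rnorm(8)
  })
  amps <- lf_amps(d$basis, d$subject)
  outcomes <- tibble::tibble(subject = d$subject,
                             LQ_comprehension = d$comp, LQ_sentence = d$sent,
                             LQ_word = d$word)
  got <- correlate_effect_outcome(amps, outcomes)
  rx <- resid(lm(basis ~ comp + sent, d))
  ry <- resid(lm(word ~ comp + sent, d))
  expect_equal(got$partial$r, cor(rx, ry), tolerance = 1e-10)
  expect_equal(got$partial$df, 8 - 2 - 2)
  expect_equal(got$bivariate$r, cor(d$basis, d$word), tolerance = 1e-10)
})

test_that("the two test-phase effects correlate positively across subpopulations", {
  # one subpopulation: positive early right-frontal effect, no late effect;
  # the other: no early effect, negative late left-posterior effect
  withr::with_seed(66, {
    n <- 200
    g <- rep(c("pos", "neg"), each = n / 2)
    early <- ifelse(g == "pos", abs(rnorm(n, 4, 1)), rnorm(n, 0, 0.3))
    late <- ifelse(g == "neg", -abs(rnorm(n, -3, 1)), rnorm(n, 0, 0.3))
  })
  r <- correlate_two_effects(early, late)
  expect_gt(r$r, 0.3)   # positive correlation = two-subpopulation signature
  expect_equal(correlate_two_effects(early, early)$r, 1)
})

test_that("the pipeline's two-effect correlation is positive on a planted two-group cohort", {
  cfg <- cohort_config(n_subjects = 46, n_negative = 18,
                       blocks_per_subject = 2,
                       noise = noise_config(scale = 0),
                       artifact = artifact_config(scale = 0),
                       timing = timing_config("compact"),
                       simulate_excluded = FALSE, compensate_filter = FALSE,
                       seed = 71)
  rep <- analyze_cohort(generate_cohort(cfg),
                        analyze_params(filter = FALSE, run_anova = FALSE,
                                       run_onsets = FALSE))
  # early positive right-frontal carriers are not the late left-posterior
  # negativity carriers, so the cross-effect correlation is positive
  expect_gt(rep$two_effects$r, 0.15)
  expect_lt(rep$two_effects$p, 0.05)
})

test_that("classification accuracy does not degrade with more trials", {
  acc_at <- function(blocks, seeds) {
    mean(purrr::map_dbl(seeds, function(s) {
      coh <- generate_cohort(cohort_config(
        n_subjects = 8, n_negative = 3, blocks_per_subject = blocks,
        timing = timing_config("compact"), simulate_excluded = FALSE,
        seed = s))
      rep <- analyze_cohort(coh, analyze_params(run_anova = FALSE,
                                                run_onsets = FALSE))
      cls <- dplyr::inner_join(rep$responders, coh$truth, by = "subject")
      mean(cls$label == cls$group)
    }))
  }
  seeds <- 300 + 1:6
  a2 <- acc_at(2, seeds); a13 <- acc_at(13, seeds)
  expect_gte(a13, a2)
  expect_gt(a13, 0.7)
})

test_that("making planted effects more negative never loses negative labels", {
  m <- default_montage()
  base_effects <- default_effects(m)
  # turn off sign truncation so the same RNG stream yields shifted copies
  for (nm in c("test_positive", "test_negative"))
    base_effects[[nm]]$sign_constrained <- FALSE
  shifted <- base_effects
  shifted$test_positive$mean_amplitude <-
    shifted$test_positive$mean_amplitude - 3
  shifted$test_negative$mean_amplitude <-
    shifted$test_negative$mean_amplitude - 3
  count_neg <- function(effects) {
    coh <- generate_cohort(cohort_config(
      n_subjects = 10, n_negative = 4, blocks_per_subject = 3,
      effects = effects, timing = timing_config("compact"),
      simulate_excluded = FALSE, seed = 90))
    rep <- analyze_cohort(coh, analyze_params(run_anova = FALSE,
                                              run_onsets = FALSE))
    sum(rep$responders$label == "negative")
  }
  expect_gte(count_neg(shifted), count_neg(base_effects))
})
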