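pkg_env <- new.env(parent = emptyenv())

# Classic 3rd-order "pinking" IIR that shapes white noise to ~1/f power.
pink_b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
pink_a <- c(1, -2.494956002, 2.017265875, -0.522189400)

pink_gain <- function() {
  if (is.null(pkg_env$pink_gain)) {
    h <- iir_cols(matrix(c(1, numeric(16383)), ncol = 1), pink_b, pink_a)
    pkg_env$pink_gain <- sqrt(sum(h^2))
  }
  pkg_env$pink_gain
}

#' Construct a continuous recording object
#'
#' @param subject_id subject identifier.
#' @param data samples x channels numeric matrix (microvolts, 200 Hz).
#' @param channels channel names (column order of `data`).
#' @param events tibble with columns `sample` (1-based index of word onset),
#'   `phase`, `condition`, `block`, `item`.
#' @param fs sampling rate, Hz.
#' @return A `continuous_recording`.
#' @export
continuous_recording <- function(subject_id, data, channels, events, fs = 200) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == length(channels))
  colnames(data) <- channels
  if (nrow(events) && (min(events$sample) < 1 || max(events$sample) > nrow(data)))
    abort("event sample indices must lie within the recording")
  structure(list(subject_id = subject_id, data = data, channels = channels,
                 events = tibble::as_tibble(events), fs = fs),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %s: %d channels x %d samples (%.1f s at %g Hz), %d events\n",
              x$subject_id, ncol(x$data), nrow(x$data),
              nrow(x$data) / x$fs, x$fs, nrow(x$events)))
  invisible(x)
}

# Event schedule for one subject -------------------------------------------

schedule_events <- function(n_blocks, config) {
  tm <- config$timing
  fs <- config$measurement$fs
  n_tok <- config$tokens_per_familiarization
  n_sen <- config$sentences_per_test
  block_dur <- n_tok * tm$token_soa_s + 0.5 + n_sen * tm$sentence_soa_s +
    tm$inter_block_gap_s
  ev <- purrr::map_dfr(seq_len(n_blocks), function(b) {
    t0 <- tm$lead_in_s + (b - 1) * block_dur
    tok_on <- t0 + (seq_len(n_tok) - 1) * tm$token_soa_s
    sen_on <- t0 + n_tok * tm$token_soa_s + 0.5 +
      (seq_len(n_sen) - 1) * tm$sentence_soa_s
    fam_cond <- rep("intermediate", n_tok)
    fam_cond[1:2] <- "unfamiliar"
    fam_cond[(n_tok - 1):n_tok] <- "familiar"
    test_cond <- sample(rep(c("familiar", "unfamiliar"), n_sen / 2))
    dplyr::bind_rows(
      tibble::tibble(onset_s = tok_on, phase = "familiarization",
                     condition = fam_cond, block = b, item = seq_len(n_tok)),
      tibble::tibble(onset_s = sen_on, phase = "test",
                     condition = test_cond, block = b, item = seq_len(n_sen)))
  })
  ev$sample <- as.integer(round(ev$onset_s * fs)) + 1L
  dur_s <- tm$lead_in_s + n_blocks * block_dur + 3
  list(events = ev[c("sample", "phase", "condition", "block", "item")],
       n_samples = as.integer(ceiling(dur_s * fs)))
}

# Repetition build-up: how much of the familiarization kernel each token
# carries (tokens 1-2 none, 9-10 full, linear in between).
fam_token_scale <- function(item, n_tok) {
  clip((item - 2) / (n_tok - 3), 0, 1)
}

# Frontally decaying blink propagation gains (fraction of the VEOG blink
# reaching each scalp channel).
blink_gains <- function(channels) {
  # Capped below ~0.45 so that even the largest blink stays under the
  # +/-150 uV screening threshold at the scalp: blinks are meant to be
  # caught by the EOG-correlation rule, not the amplitude rule.
  g <- c(F7 = 0.45, F3 = 0.45, F4 = 0.45, F8 = 0.45, Fz = 0.45,
         FT7 = 0.35, FC3 = 0.35, FC4 = 0.35, FT8 = 0.35, FCz = 0.35,
         C3 = 0.2, C4 = 0.2, LT = 0.2, RT = 0.2, Cz = 0.2,
         CP3 = 0.12, CP4 = 0.12, LTP = 0.12, RTP = 0.12,
         P3 = 0.06, P4 = 0.06, LP = 0.06, RP = 0.06,
         Pz = 0.06, PO7 = 0.04, PO8 = 0.04, Oz = 0.04)
  out <- g[channels]
  out[is.na(out)] <- 0
  names(out) <- channels
  out
}

# Simulate one subject's continuous recording ------------------------------

simulate_recording <- function(subject_id, group, amplitudes, n_blocks,
                               config, effect_gains) {
  m <- config$montage
  fs <- config$measurement$fs
  channels <- c(analysis_electrodes(m),
                if (config$simulate_excluded) m$excluded,
                m$reference, m$eog)
  sched <- schedule_events(n_blocks, config)
  ev <- sched$events
  n <- sched$n_samples
  nch <- length(channels)
  x <- matrix(0, n, nch)
  colnames(x) <- channels

  # background noise: pink + 0.3 Hz drift + white; channels independent;
  # the online-reference left mastoid is identically zero.
  noisy <- setdiff(channels, m$reference[1])
  nc <- config$noise
  nn <- length(noisy)
  if (nc$pink_rms > 0 || nc$white_rms > 0 || nc$drift_amplitude > 0) {
    phases <- runif(nn, 0, 2 * pi)
    x[, noisy] <- noise_cols(n, nn, pink_b, pink_a,
                             nc$pink_rms / pink_gain(), nc$white_rms,
                             nc$drift_amplitude, 0.3, fs, phases)
  }

  # planted effects on the condition-defining events
  epoch_off <- 0:(0.8 * fs - 1)            # kernel support [0, 800) ms
  tms <- epoch_off / fs * 1000
  for (nm in names(config$effects)) {
    spec <- config$effects[[nm]]
    a <- amplitudes[[nm]]
    if (is.na(a) || a == 0) next
    kern <- effect_kernel(spec, tms) * (a / effect_gains[[nm]])
    wmat <- outer(kern, spec$electrode_weights)   # samples x electrodes
    cols <- match(names(spec$electrode_weights), channels)
    if (spec$phase == "familiarization") {
      idx <- which(ev$phase == "familiarization")
      scale <- fam_token_scale(ev$item[idx], config$tokens_per_familiarization)
    } else {
      idx <- which(ev$phase == "test" & ev$condition == "familiar")
      scale <- rep(1, length(idx))
    }
    for (j in seq_along(idx)) {
      if (scale[j] == 0) next
      rows <- ev$sample[idx[j]] + epoch_off
      x[rows, cols] <- x[rows, cols] + wmat * scale[j]
    }
  }

  # artifacts (planted events are logged for parameter-recovery tests)
  ac <- config$artifact
  veog <- m$eog[1]
  gains <- blink_gains(channels)
  scalp <- setdiff(channels, c(m$reference, m$eog))
  art <- list()
  if (ac$blink_prob_per_epoch > 0) {
    hit <- which(runif(nrow(ev)) < ac$blink_prob_per_epoch)
    blink <- sin(pi * seq(0, 1, length.out = round(0.4 * fs)))
    for (i in hit) {
      amp <- runif(1, ac$blink_amplitude[1], ac$blink_amplitude[2])
      start <- ev$sample[i] + round(runif(1, -0.05, 0.4) * fs)
      rows <- start + seq_along(blink) - 1
      rows <- rows[rows >= 1 & rows <= n]
      bl <- amp * blink[seq_along(rows)]
      x[rows, veog] <- x[rows, veog] + bl
      x[rows, scalp] <- x[rows, scalp] + outer(bl, gains[scalp])
      art <- c(art, list(tibble::tibble(type = "blink", event = i,
                                        sample = start, channel = veog,
                                        amplitude = amp)))
    }
  }
  if (ac$excursion_prob_per_epoch > 0) {
    hit <- which(runif(nrow(ev)) < ac$excursion_prob_per_epoch)
    puls <- sin(2 * pi * seq(0, 1, length.out = round(0.1 * fs)))
    achans <- analysis_electrodes(m)
    for (i in hit) {
      ch <- sample(achans, 1)
      start <- ev$sample[i] + round(runif(1, -0.15, 0.65) * fs)
      rows <- start + seq_along(puls) - 1
      rows <- rows[rows >= 1 & rows <= n]
      x[rows, ch] <- x[rows, ch] + ac$excursion_amplitude * puls[seq_along(rows)]
      art <- c(art, list(tibble::tibble(type = "excursion", event = i,
                                        sample = start, channel = ch,
                                        amplitude = ac$excursion_amplitude)))
    }
  }

  rec <- continuous_recording(subject_id, x, channels, ev, fs)
  rec$artifacts <- if (length(art)) dplyr::bind_rows(art) else
    tibble::tibble(type = character(), event = integer(), sample = integer(),
                   channel = character(), amplitude = numeric())
  rec
}

#' Generate a synthetic infant ERP cohort
#'
#' Draws the cohort design (responder groups, block counts, per-subject
#' planted amplitudes), simulates one continuous 200 Hz recording per
#' subject with event markers for the familiarization tokens and the
#' sentence-embedded test words, and generates the linked 3-year language
#' outcomes. All randomness derives from `config$seed` through named
#' substreams (design, one per subject, outcomes), so a fixed config is
#' reproduced identically and downstream analysis choices can never
#' perturb the simulated data.
#'
#' @param config a [cohort_config()].
#' @return An object of class `erp_cohort`: list with `recordings` (one
#'   `continuous_recording` per subject), `truth` (tibble of planted
#'   per-subject ground truth: group, per-effect amplitudes, left-frontal
#'   basis amplitude, latent ability; read only by tests, never by the
#'   analysis stages), `outcomes` (tibble, see [generate_outcomes()]),
#'   `montage` and `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_subjects = 4, n_negative = 2,
#'                                         blocks_per_subject = 2, seed = 7))
#' cohort$truth
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  m <- config$montage
  n <- config$n_subjects
  ids <- sprintf("S%02d", seq_len(n))

  design <- with_substream(config$seed, "design", code = {
    group <- rep("positive", n)
    group[sample.int(n, config$n_negative)] <- "negative"
    blocks <- vapply(seq_len(n), function(i)
      draw_block_count(config$blocks_per_subject), integer(1))
    amps <- matrix(NA_real_, n, length(config$effects),
                   dimnames = list(NULL, names(config$effects)))
    for (nm in names(config$effects)) {
      spec <- config$effects[[nm]]
      takers <- switch(spec$applies_to,
                       all = seq_len(n),
                       negative_group = which(group == "negative"),
                       positive_group = which(group == "positive"))
      amps[, nm] <- 0
      amps[takers, nm] <- draw_amplitudes(spec, length(takers))
    }
    list(group = group, blocks = blocks, amps = amps)
  })

  effect_gains <- lapply(config$effects, function(spec) {
    if (config$compensate_filter)
      filter_gain_for_effect(spec, config$measurement)
    else 1
  })

  # planted left-frontal test-phase basis amplitude (what the responder
  # classification and the outcome link are built on)
  lf <- m$quadrants$left_frontal
  lf_basis <- rep(0, n)
  for (nm in names(config$effects)) {
    spec <- config$effects[[nm]]
    if (spec$phase != "test") next
    lf_basis <- lf_basis + design$amps[, nm] * effect_set_weight(spec, lf)
  }

  truth <- tibble::tibble(subject = ids, group = design$group,
                          n_blocks = design$blocks)
  for (nm in colnames(design$amps))
    truth[[paste0("amp_", nm)]] <- design$amps[, nm]
  truth$lf_basis <- lf_basis

  recordings <- lapply(seq_len(n), function(i) {
    with_substream(config$seed, "subject", i, code =
      simulate_recording(ids[i], design$group[i],
                         as.list(design$amps[i, ]), design$blocks[i],
                         config, effect_gains))
  })
  names(recordings) <- ids

  out <- generate_outcomes(truth, config$outcome,
                           seed = substream_seed(config$seed, "outcomes"))
  truth$latent_ability <- attr(out, "latent_ability")

  structure(list(recordings = recordings, truth = truth, outcomes = out,
                 montage = m, config = config),
            class = "erp_cohort")
}

#' @export
print.erp_cohort <- function(x, ...) {
  cat(sprintf("<erp_cohort> %d subjects (%d negative / %d positive responders planted), seed %d\n",
              nrow(x$truth), sum(x$truth$group == "negative"),
              sum(x$truth$group == "positive"), x$config$seed))
  invisible(x)
}
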