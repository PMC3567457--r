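# Shared fixtures, all generated in code at test time.

quick_config <- function(..., seed = 1) {
  cohort_config(n_subjects = 4, n_negative = 2, blocks_per_subject = 2,
                timing = timing_config("compact"), seed = seed, ...)
}

# A tiny deterministic epoch collection built by hand: nt trials of a
# constant value per trial, 4 channels (2 analysis-ish + VEOG/HEOG).
toy_epochs <- function(values, channels = c("F7", "C3", "VEOG", "HEOG"),
                       phase = "test",
                       condition = rep("familiar", length(values)),
                       ns = 200, fs = 200) {
  nt <- length(values)
  dat <- array(0, c(nt, length(channels), ns),
               dimnames = list(NULL, channels, NULL))
  for (i in seq_len(nt)) dat[i, , ] <- values[i]
  structure(list(subject_id = "toy", data = dat,
                 time = seq(-200, by = 1000 / fs, length.out = ns),
                 channels = channels,
                 trials = tibble::tibble(
                   trial = seq_len(nt), sample = 1000 + seq_len(nt),
                   phase = phase, condition = condition,
                   block = 1L, item = seq_len(nt),
                   kept = TRUE, reject_rule = NA_character_),
                 fs = fs, baseline = FALSE, log = character()),
            class = "epoch_collection")
}

toy_recording <- function(data, channels, events = NULL, fs = 200) {
  events <- events %||% tibble::tibble(
    sample = integer(), phase = character(), condition = character(),
    block = integer(), item = integer())
  continuous_recording("toy", data, channels, events, fs)
}

# Independent brute-force repeated-measures sums of squares for a fully
# crossed within design, computed from marginal means (the textbook route,
# no contrast matrices).
brute_rm_F <- function(data, dv, subject, within) {
  data[[subject]] <- factor(data[[subject]])
  for (w in within) data[[w]] <- factor(data[[w]])
  n <- nlevels(data[[subject]])
  grand <- mean(data[[dv]])
  ss <- function(fac) {
    mt <- tapply(data[[dv]], data[fac], mean)
    cnt <- nrow(data) / length(mt)
    sum(cnt * (mt - grand)^2)
  }
  # all main/interaction terms involving subject and factors
  terms <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)
  sseff <- function(eff) {
    tot <- ss(eff)
    if (length(eff) > 1)
      for (k in seq_len(length(eff) - 1))
        for (sub in utils::combn(eff, k, simplify = FALSE))
          tot <- tot - sseff(sub)
    tot
  }
  out <- list()
  for (eff in terms) {
    ss_e <- sseff(eff)
    full <- sseff(c(eff, subject))   # error term: effect x subject
    df1 <- prod(vapply(eff, function(w) nlevels(data[[w]]) - 1L, 1L))
    df2 <- df1 * (n - 1)
    out[[paste(eff, collapse = ":")]] <-
      list(F = (ss_e / df1) / (full / df2), df1 = df1, df2 = df2)
  }
  out
}
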