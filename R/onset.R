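#' Sliding-bin onset detection for a familiarity effect
#'
#' Scans the difference waveforms in 50 ms bins stepped by 10 ms (40 ms
#' overlap: 0-50, 10-60, ...). In each bin the per-subject mean amplitude
#' is tested against zero with [one_sample_t()]; the effect onset is the
#' start of the first run of at least `run_length` consecutive bins that
#' are significant at `alpha` *and* share the sign of their mean (the sign
#' requirement, configurable off, keeps alternating-sign noise runs from
#' qualifying). Absence of such a run is a valid result (`onset = NA`).
#'
#' @param waves subjects x samples matrix of difference waveforms for one
#'   electrode (or an electrode-set mean), >= 3 subjects.
#' @param time sample times in ms (length `ncol(waves)`).
#' @param search `c(start, end)` ms; bins are laid from `start` in steps of
#'   `step` while they fit inside `end`.
#' @param bin bin width in ms (default 50).
#' @param step bin step in ms (default 10).
#' @param alpha per-bin significance level (default 0.05).
#' @param run_length consecutive significant bins required (default 5).
#' @param require_sign require a common sign across the run (default TRUE).
#' @return Object of class `onset_result`: `onset` (ms, or `NA`), `bins`
#'   tibble (`start`, `end`, `mean`, `t`, `p`, `significant`, `sign`).
#' @export
detect_onset <- function(waves, time, search = c(0, 800), bin = 50, step = 10,
                         alpha = 0.05, run_length = 5, require_sign = TRUE) {
  waves <- as.matrix(waves)
  stopifnot(nrow(waves) >= 3, ncol(waves) == length(time))
  starts <- seq(search[1], search[2] - bin, by = step)
  if (!length(starts)) abort("search range narrower than one bin")
  n <- nrow(waves)
  sel <- vapply(starts, function(s) in_window(time, c(s, s + bin)),
                logical(length(time)))          # samples x bins
  counts <- colSums(sel)
  if (any(counts == 0)) abort("a bin contains no samples")
  bm <- waves %*% sel / rep(counts, each = n)   # subject x bin means
  m <- colMeans(bm)
  sdv <- sqrt(colSums((bm - rep(m, each = n))^2) / (n - 1))
  tv <- ifelse(sdv > 0, m / (sdv / sqrt(n)), 0)
  pv <- ifelse(sdv > 0, 2 * pt(abs(tv), n - 1, lower.tail = FALSE), 1)
  stat <- tibble::tibble(start = starts, end = starts + bin, mean = m,
                         t = tv, p = pv)
  stat$significant <- stat$p < alpha
  stat$sign <- sign(stat$mean)

  onset <- NA_real_
  ok <- stat$significant
  if (require_sign) {
    run <- 0L
    for (i in seq_len(nrow(stat))) {
      if (!ok[i]) { run <- 0L; next }
      if (run > 0L && stat$sign[i] != stat$sign[i - 1L]) run <- 0L
      run <- run + 1L
      if (run >= run_length) { onset <- stat$start[i - run_length + 1L]; break }
    }
  } else {
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    hit <- which(r$values & r$lengths >= run_length)
    if (length(hit))
      onset <- stat$start[ends[hit[1]] - r$lengths[hit[1]] + 1L]
  }
  structure(list(onset = onset, bins = stat, alpha = alpha,
                 run_length = run_length, bin = bin, step = step,
                 n_subjects = n),
            class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  cat(sprintf("<onset_result> %s (n = %d; %g ms bins, %g ms step, alpha %g, run %d)\n",
              if (is.na(x$onset)) "no onset detected"
              else sprintf("onset at %g ms", x$onset),
              x$n_subjects, x$bin, x$step, x$alpha, x$run_length))
  invisible(x)
}

#' @export
tidy.onset_result <- function(x, ...) x$bins

#' @export
glance.onset_result <- function(x, ...) {
  tibble::tibble(onset = x$onset, n_subjects = x$n_subjects,
                 n_bins = nrow(x$bins), n_significant = sum(x$bins$significant))
}
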