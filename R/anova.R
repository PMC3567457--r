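#' Greenhouse-Geisser and Huynh-Feldt sphericity corrections
#'
#' Given the covariance matrix `C` of a within-subject effect's orthonormal
#' contrast scores (d x d, estimated across `n` subjects), returns
#' \deqn{\hat\epsilon_{GG} = \mathrm{tr}(C)^2 / (d\,\mathrm{tr}(C^2))}
#' and the single-group Huynh-Feldt correction
#' \deqn{\hat\epsilon_{HF} = \min\{1, (n d \hat\epsilon_{GG} - 2) /
#'       (d (n - 1 - d \hat\epsilon_{GG}))\}.}
#' Several HF variants circulate; fixing this one makes results
#' bit-reproducible. Bounds: `1/d <= eps_gg <= 1` and `eps_hf >= eps_gg`.
#'
#' @param contrast_covariance symmetric positive semidefinite d x d matrix.
#' @param n number of subjects.
#' @return Named list `epsilon_gg`, `epsilon_hf`.
#' @examples
#' gg_hf_epsilon(diag(c(3, 1, 1)), n = 10)
#' @export
gg_hf_epsilon <- function(contrast_covariance, n) {
  C <- as.matrix(contrast_covariance)
  d <- nrow(C)
  stopifnot(d == ncol(C), n > d + 1)
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    abort("contrast covariance must be symmetric")
  trC <- sum(diag(C))
  if (trC <= 0) abort("contrast covariance has zero trace (no variance)")
  gg <- trC^2 / (d * sum(C * C))
  hf <- min(1, (n * d * gg - 2) / (d * (n - 1 - d * gg)))
  list(epsilon_gg = gg, epsilon_hf = hf)
}

orthonormal_contrasts <- function(l) {
  if (l == 1) return(matrix(numeric(0), 1, 0))
  H <- stats::contr.helmert(l)
  sweep(H, 2, sqrt(colSums(H^2)), "/")
}

#' Repeated-measures ANOVA with sphericity correction
#'
#' Univariate sums-of-squares decomposition for fully crossed
#' within-subject designs (e.g. Familiarity x Quadrant x Electrode on
#' window-mean amplitudes). For each effect the subject x cell table is
#' projected onto orthonormal contrasts; with scores `S` (subjects x d),
#' `F = n * sum(colMeans(S)^2) / tr(cov(S))` on `(d, d (n - 1))` degrees of
#' freedom, and the effect's Greenhouse-Geisser / Huynh-Feldt epsilons come
#' from `cov(S)` via [gg_hf_epsilon()]. Reported p-values use the original
#' degrees of freedom scaled by the Huynh-Feldt epsilon (the convention of
#' reporting original dfs alongside adjusted p-values).
#'
#' @param data a data frame / `window_amplitudes` tibble in long format:
#'   one row per subject x cell.
#' @param dv name of the response column (default `"mean_uV"`).
#' @param subject name of the subject id column (default `"subject"`).
#' @param within character vector of within-subject factor columns, in
#'   reporting order.
#' @return Object of class `rm_anova`; `tidy()` gives the effect table
#'   (`effect`, `df1`, `df2`, `F`, `epsilon_gg`, `epsilon_hf`, `p`,
#'   `p_hf`), `glance()` a one-row design summary.
#' @examples
#' d <- tidyr::expand_grid(subject = sprintf("s%d", 1:8),
#'                         familiarity = c("familiar", "unfamiliar"))
#' d$mean_uV <- rnorm(nrow(d))
#' tidy(rm_anova(d, dv = "mean_uV", within = "familiarity"))
#' @export
rm_anova <- function(data, dv = "mean_uV", subject = "subject", within) {
  data <- as.data.frame(data)
  stopifnot(all(c(dv, subject, within) %in% names(data)), length(within) >= 1)
  for (w in within) data[[w]] <- factor(data[[w]])
  levs <- lapply(data[within], levels)
  nlev <- vapply(levs, length, 0L)
  subjects <- unique(data[[subject]])
  n <- length(subjects)
  ncell <- prod(nlev)

  cells <- do.call(tidyr::expand_grid, stats::setNames(levs, within))
  key <- do.call(paste, c(cells, sep = "\r"))
  data$.cell <- do.call(paste, c(data[within], sep = "\r"))
  tab <- table(data[[subject]], data$.cell)
  if (any(tab != 1) || ncol(tab) != ncell)
    abort("design must be complete and balanced: exactly one observation per subject x cell")

  Y <- matrix(NA_real_, n, ncell,
              dimnames = list(as.character(subjects), key))
  Y[cbind(as.character(data[[subject]]), data$.cell)] <- data[[dv]]

  effects <- unlist(lapply(seq_along(within), function(k)
    utils::combn(within, k, simplify = FALSE)), recursive = FALSE)

  rows <- purrr::map_dfr(effects, function(eff) {
    M <- Reduce(kronecker, lapply(within, function(w) {
      l <- nlev[[w]]
      if (w %in% eff) orthonormal_contrasts(l)
      else matrix(1 / sqrt(l), l, 1)
    }))
    d <- ncol(M)
    S <- Y %*% M
    mbar <- colMeans(S)
    C <- stats::cov(S)
    trC <- sum(diag(C))
    if (trC <= 1e-12 * max(1, sum(mbar^2)))
      abort(sprintf("no error variance for effect %s",
                    paste(eff, collapse = ":")))
    if (n <= d + 1)
      abort(sprintf("too few subjects (%d) to estimate sphericity for effect %s (df1 = %d)",
                    n, paste(eff, collapse = ":"), d))
    Fval <- n * sum(mbar^2) / trC
    eps <- gg_hf_epsilon(C, n)
    df1 <- d; df2 <- d * (n - 1)
    tibble::tibble(
      effect = paste(eff, collapse = ":"),
      df1 = df1, df2 = df2, F = Fval,
      epsilon_gg = eps$epsilon_gg, epsilon_hf = eps$epsilon_hf,
      p = pf(Fval, df1, df2, lower.tail = FALSE),
      p_hf = pf(Fval, df1 * eps$epsilon_hf, df2 * eps$epsilon_hf,
                lower.tail = FALSE))
  })
  structure(list(table = rows, n = n, within = within, nlev = nlev,
                 dv = dv),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA (%s; n = %d; within: %s)\n",
              x$dv, x$n, paste(sprintf("%s[%d]", x$within, x$nlev),
                               collapse = " x ")))
  cat("Huynh-Feldt adjusted p-values reported with original dfs.\n")
  print(as.data.frame(x$table), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @export
glance.rm_anova <- function(x, ...) {
  tibble::tibble(n_subjects = x$n, n_effects = nrow(x$table),
                 n_cells = prod(x$nlev))
}
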