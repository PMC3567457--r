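#' One-sample t-test with a zero-variance rule
#'
#' Student t of `values` against `mu0`. Onset scanning feeds this thousands
#' of constant-zero bins, so zero variance is not an error: it returns
#' `t = 0, p = 1` with a warning (a constant signal carries no evidence
#' against its own mean; a constant different from `mu0` is degenerate and
#' also reported non-significant).
#'
#' @param values numeric vector, length >= 2.
#' @param mu0 null mean (default 0).
#' @return One-row tibble `estimate`, `t`, `df`, `p`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  n <- length(values)
  stopifnot(n >= 2)
  if (sd(values) == 0) {
    warn("one_sample_t: zero variance; reported non-significant")
    return(tibble::tibble(estimate = mean(values), t = 0, df = n - 1, p = 1))
  }
  ht <- stats::t.test(values, mu = mu0)
  tibble::tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value)
}

#' Pooled-variance two-sample t-test
#'
#' Student (equal-variance) t with `df = n_a + n_b - 2`, the classical
#' form behind reported `t_21` group comparisons of 9 vs 14 children.
#'
#' @param group_a,group_b numeric vectors, each length >= 2.
#' @return One-row tibble with group means/SDs, `t`, `df`, `p`.
#' @export
two_sample_t <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    return(tibble::tibble(
      mean_a = mean(group_a), sd_a = 0, mean_b = mean(group_b), sd_b = 0,
      t = if (mean(group_a) == mean(group_b)) 0 else Inf,
      df = length(group_a) + length(group_b) - 2,
      p = if (mean(group_a) == mean(group_b)) 1 else 0))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  tibble::tibble(mean_a = mean(group_a), sd_a = sd(group_a),
                 mean_b = mean(group_b), sd_b = sd(group_b),
                 t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value)
}

#' Pearson correlation
#'
#' Product-moment correlation with the usual t-based two-tailed p on
#' `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return One-row tibble of class `correlation_result`:
#'   `r`, `n`, `df`, `p`, `covariates` (0).
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0)
    abort("pearson_r: zero variance in x or y")
  ht <- stats::cor.test(x, y)
  out <- tibble::tibble(r = unname(ht$estimate), n = length(x),
                        df = unname(ht$parameter), p = ht$p.value,
                        covariates = 0L)
  class(out) <- c("correlation_result", class(out))
  out
}

#' Partial correlation by residual regression
#'
#' Correlation between the residuals of `x` and `y` after least-squares
#' projection on an intercept plus the covariates, with
#' `df = n - 2 - n_covariates` and the t-based two-tailed p.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric vector, matrix or data frame of 1-2 covariates.
#' @return One-row tibble of class `correlation_result`.
#' @export
partial_r <- function(x, y, covariates) {
  Z <- as.matrix(as.data.frame(covariates))
  n <- length(x)
  k <- ncol(Z)
  stopifnot(length(y) == n, nrow(Z) == n, k >= 1)
  if (n < 4 + k) abort("partial_r: too few observations")
  if (qr(cbind(1, Z))$rank < k + 1) abort("partial_r: collinear covariates")
  rx <- resid(lm(x ~ Z))
  ry <- resid(lm(y ~ Z))
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12)
    abort("partial_r: a variable is fully explained by the covariates")
  r <- cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  out <- tibble::tibble(r = r, n = n, df = df,
                        p = 2 * pt(abs(tval), df, lower.tail = FALSE),
                        covariates = as.integer(k))
  class(out) <- c("correlation_result", class(out))
  out
}
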