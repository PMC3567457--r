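#' Generate linked 3-year language outcomes
#'
#' Produces per-child language quotients (comprehension, sentence
#' production, word production), SLAS parent-rating subscales and their
#' composite, linked to the planted left-frontal test-phase amplitude.
#'
#' The word-production LQ follows
#' \deqn{LQ_w = m_w + s_w\,(-\beta z(a) + c\,\tilde g + \sqrt{1-\beta^2-c^2}\,\epsilon)}
#' where \eqn{z(a)} standardizes the planted amplitude across the cohort,
#' \eqn{\beta} is `erp_lq_link` (so the amplitude-LQ correlation is
#' \eqn{-\beta}: the more negative the effect, the higher the LQ),
#' \eqn{\tilde g} is the in-sample standardized component of
#' negative-group membership orthogonal to \eqn{z(a)}, and \eqn{c} is
#' solved so that the negative responders' expected mean lands at
#' `100 + 15 * negative_group_offset`. Because \eqn{\tilde g} is orthogonal
#' to the amplitude, the placement term leaves the amplitude-LQ correlation
#' untouched; because the three components have unit total variance, the
#' generated LQ keeps the configured cohort SD.
#'
#' Comprehension and sentence LQs and the SLAS ratings load on the shared
#' systematic ability \eqn{-\beta z + c \tilde g} with loading
#' `inter_test_loading`; SLAS values are clipped to the 1-7 rating scale.
#'
#' @param truth tibble with columns `subject`, `group`, `lf_basis`
#'   (as produced by [generate_cohort()]).
#' @param config an [outcome_config()].
#' @param seed integer seed for the outcome noise draws.
#' @return Tibble with one row per child: `subject`, `LQ_comprehension`,
#'   `LQ_sentence`, `LQ_word`, `lq_risk` (any LQ below 85), `SLAS_syntax`,
#'   `SLAS_talkativeness`, `SLAS_articulation`, `SLAS_average`. The
#'   standardized latent ability is attached as attribute
#'   `"latent_ability"`.
#' @export
generate_outcomes <- function(truth, config = outcome_config(), seed = 1L) {
  stopifnot(all(c("subject", "group", "lf_basis") %in% names(truth)))
  if (abs(config$erp_lq_link) > 1) abort("erp_lq_link must lie in [-1, 1]")
  n <- nrow(truth)
  beta <- config$erp_lq_link
  a <- truth$lf_basis
  z <- if (n >= 2 && sd(a) > 0) as.numeric(scale(a)) else rep(0, n)

  g <- as.numeric(truth$group == "negative")
  o <- config$negative_group_offset
  cc <- 0
  gres <- rep(0, n)
  if (o != 0 && any(g == 1) && any(g == 0)) {
    gr <- resid(lm(g ~ z))
    if (sd(gr) > 1e-12) {
      gres <- as.numeric(gr / sd(gr))
      target <- (config$lq_population_mean +
                   config$lq_population_sd * o - config$lq_means[["word"]]) /
        config$lq_sds[["word"]]
      cc <- (target + beta * mean(z[g == 1])) / mean(gres[g == 1])
      cmax <- sqrt(max(0, 1 - beta^2))
      if (abs(cc) > cmax) {
        warn("group placement capped: offset not fully reachable at this link strength")
        cc <- sign(cc) * cmax
      }
    }
  }
  k <- sqrt(max(0, 1 - beta^2 - cc^2))
  ability <- -beta * z + cc * gres
  u <- if (n >= 2 && sd(ability) > 0) as.numeric(scale(ability)) else rep(0, n)

  lam <- config$inter_test_loading
  res <- sqrt(1 - lam^2)
  withr::with_seed(seed, {
    word <- config$lq_means[["word"]] +
      config$lq_sds[["word"]] * (ability + k * rnorm(n))
    comp <- config$lq_means[["comprehension"]] +
      config$lq_sds[["comprehension"]] * (lam * u + res * rnorm(n))
    sent <- config$lq_means[["sentence"]] +
      config$lq_sds[["sentence"]] * (lam * u + res * rnorm(n))
    slas <- function() clip(config$slas_mean +
                              config$slas_sd * (0.5 * u + sqrt(0.75) * rnorm(n)),
                            1, 7)
    syn <- slas(); talk <- slas(); art <- slas()
  })
  out <- tibble::tibble(
    subject = truth$subject,
    LQ_comprehension = comp, LQ_sentence = sent, LQ_word = word,
    lq_risk = comp < 85 | sent < 85 | word < 85,
    SLAS_syntax = syn, SLAS_talkativeness = talk, SLAS_articulation = art,
    SLAS_average = (syn + talk + art) / 3)
  attr(out, "latent_ability") <- u
  out
}
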