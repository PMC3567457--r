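test_that("one-sample t matches the closed form and handles zero variance", {
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(r$df, 2)

  expect_equal(one_sample_t(c(-2, -1, 1, 2))$t, 0)

  expect_warning(rz <- one_sample_t(rep(5, 6), mu0 = 5), "zero variance")
  expect_equal(rz$p, 1)
  expect_warning(rz2 <- one_sample_t(rep(5, 6), mu0 = 0), "zero variance")
  expect_equal(rz2$p, 1)
})

test_that("two-sample t is pooled-variance Student with df n1 + n2 - 2", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$t, 0)

  r <- two_sample_t(c(0, 1, 2), c(3, 4, 5))
  # pooled var = 1, se = sqrt(2/3)
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(r$df, 4)

  # the 9-vs-14 responder split yields df = 21
  expect_equal(two_sample_t(rnorm(9), rnorm(14))$df, 21)
})

test_that("pearson_r reproduces hand-computed and degenerate correlations", {
  x <- 1:6
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)

  x5 <- c(1, 2, 3, 4, 5); y5 <- c(2, 1, 4, 3, 5)
  r <- pearson_r(x5, y5)
  expect_equal(r$r, 0.8, tolerance = 1e-12)  # cross-products 8 / sqrt(10*10)
  expect_equal(r$df, 3)

  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
})

test_that("partial_r agrees with the inverse-correlation-matrix formula", {
  withr::with_seed(7, {
    x <- rnorm(8); z <- rnorm(8); y <- 0.5 * x + 0.7 * z + rnorm(8)
  })
  got <- partial_r(x, y, z)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  expect_equal(got$r, oracle, tolerance = 1e-12)
  expect_equal(got$df, 8 - 2 - 1)

  # covariate orthogonal to both -> partial equals bivariate
  xo <- c(1, -1, 2, -2, 3, -3, 4, -4)
  yo <- c(2, -2, 3, -3, 5, -5, 7, -7)
  zo <- rep(c(1, 1, -1, -1), 2)  # orthogonal to xo and yo
  expect_lt(abs(cor(xo, zo)), 1e-12)
  expect_equal(partial_r(xo, yo, zo)$r, pearson_r(xo, yo)$r, tolerance = 1e-6)

  # covariate identical to y -> residual variance 0 -> error path
  z2 <- rnorm(10)
  expect_error(partial_r(rnorm(10), z2, z2), "fully explained")
})

test_that("gg_hf_epsilon matches direct evaluation and respects bounds", {
  e <- gg_hf_epsilon(diag(c(3, 1, 1)), n = 10)
  expect_equal(e$epsilon_gg, 25 / 33, tolerance = 1e-12)
  # HF formula gives 20.7273/20.1818 = 1.027 -> capped at 1
  expect_equal(e$epsilon_hf, 1)

  expect_equal(gg_hf_epsilon(diag(2) * 4, n = 8)$epsilon_gg, 1)
  expect_equal(gg_hf_epsilon(matrix(2), n = 5)$epsilon_gg, 1)

  expect_error(gg_hf_epsilon(matrix(0, 2, 2), n = 10), "zero trace")

  # bounds on random PSD matrices, eigenvalue oracle
  withr::with_seed(42, {
    for (i in 1:300) {
      d <- sample(2:5, 1)
      A <- matrix(rnorm(d * d), d)
      C <- crossprod(A) + diag(d) * 1e-8
      e <- gg_hf_epsilon(C, n = d + 2 + sample(1:20, 1))
      lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
      expect_equal(e$epsilon_gg, sum(lam)^2 / (d * sum(lam^2)),
                   tolerance = 1e-8)
      expect_gte(e$epsilon_gg, 1 / d - 1e-12)
      expect_lte(e$epsilon_gg, 1 + 1e-12)
      expect_gte(e$epsilon_hf, e$epsilon_gg - 1e-12)
      expect_lte(e$epsilon_hf, 1)
    }
  })
})

test_that("rm_anova on a 2-level factor reproduces the paired t-test", {
  withr::with_seed(11, {
    for (rep in 1:40) {
      n <- sample(5:15, 1)
      d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:n),
                              familiarity = c("fam", "unfam"))
      d$mean_uV <- rnorm(nrow(d))
      a <- tidy(rm_anova(d, within = "familiarity"))
      wide <- tidyr::pivot_wider(d, names_from = "familiarity",
                                 values_from = "mean_uV")
      tt <- t.test(wide$fam, wide$unfam, paired = TRUE)
      expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
      expect_equal(a$p_hf, tt$p.value, tolerance = 1e-9)
      expect_equal(a$epsilon_gg, 1)
      expect_equal(a$df1, 1)
      expect_equal(a$df2, n - 1)
    }
  })
})

test_that("rm_anova matches an independent brute-force decomposition", {
  withr::with_seed(3, {
    d <- tidyr::expand_grid(subject = sprintf("s%d", 1:6),
                            A = c("a1", "a2"), B = c("b1", "b2"))
    d$mean_uV <- rnorm(nrow(d), mean = ifelse(d$A == "a1", 1, 0))
  })
  got <- tidy(rm_anova(d, within = c("A", "B")))
  oracle <- brute_rm_F(d, "mean_uV", "subject", c("A", "B"))
  for (eff in names(oracle)) {
    row <- got[got$effect == eff, ]
    expect_equal(row$F, oracle[[eff]]$F, tolerance = 1e-8)
    expect_equal(row$df1, oracle[[eff]]$df1)
    expect_equal(row$df2, oracle[[eff]]$df2)
  }
})

test_that("rm_anova agrees with car's multivariate route on a 2x4x5 design", {
  skip_if_not_installed("car")
  n <- 28
  withr::with_seed(99, {
    d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:n),
                            familiarity = c("fam", "unfam"),
                            quadrant = c("LF", "RF", "LP", "RP"),
                            electrode_pos = factor(1:5))
    d$mean_uV <- rnorm(nrow(d)) + ifelse(d$familiarity == "fam", 0.3, 0) *
      ifelse(d$quadrant %in% c("LF", "RF"), 1, 0)
  })
  got <- tidy(rm_anova(d, within = c("familiarity", "quadrant",
                                     "electrode_pos")))
  # reported dfs match the 2x4x5 design with n = 28
  expect_equal(got$df1[got$effect == "familiarity"], 1)
  expect_equal(got$df2[got$effect == "familiarity"], 27)
  expect_equal(got$df1[got$effect == "familiarity:quadrant"], 3)
  expect_equal(got$df2[got$effect == "familiarity:quadrant"], 81)

  wide <- tidyr::pivot_wider(
    dplyr::arrange(d, subject, familiarity, quadrant, electrode_pos),
    id_cols = "subject",
    names_from = c("familiarity", "quadrant", "electrode_pos"),
    values_from = "mean_uV")
  Y <- as.matrix(wide[-1])
  idata <- tidyr::expand_grid(familiarity = factor(c("fam", "unfam")),
                              quadrant = factor(c("LF", "RF", "LP", "RP"),
                                                levels = c("LF", "RF", "LP", "RP")),
                              electrode_pos = factor(1:5))
  fit <- car::Anova(lm(Y ~ 1), idata = as.data.frame(idata),
                    idesign = ~ familiarity * quadrant * electrode_pos,
                    type = 3)
  su <- summary(fit, multivariate = FALSE)
  s <- su$univariate.tests
  pa <- su$pval.adjustments
  for (eff in c("familiarity", "familiarity:quadrant",
                "familiarity:quadrant:electrode_pos")) {
    row <- got[got$effect == eff, ]
    expect_equal(row$F, s[eff, "F value"], tolerance = 1e-6)
    expect_equal(row$p, s[eff, "Pr(>F)"], tolerance = 1e-6)
    if (eff %in% rownames(pa)) {
      expect_equal(row$epsilon_gg, pa[eff, "GG eps"], tolerance = 1e-6)
      expect_equal(row$epsilon_hf, min(1, pa[eff, "HF eps"]),
                   tolerance = 1e-6)
      expect_equal(row$p_hf, pa[eff, "Pr(>F[HF])"], tolerance = 1e-6)
    }
  }
})

test_that("rm_anova rejects incomplete or unbalanced tables", {
  d <- tidyr::expand_grid(subject = sprintf("s%d", 1:5),
                          familiarity = c("f", "u"))
  d$mean_uV <- rnorm(10)
  expect_error(rm_anova(d[-1, ], within = "familiarity"),
               "complete and balanced")
  expect_error(rm_anova(rbind(d, d[1, ]), within = "familiarity"),
               "complete and balanced")
})

test_that("corrected p-values are calibrated under a true null", {
  n <- 14
  withr::with_seed(2024, {
    pvals <- replicate(900, {
      d <- tidyr::expand_grid(subject = sprintf("s%02d", 1:n),
                              A = c("a1", "a2"), B = c("b1", "b2", "b3"))
      d$mean_uV <- rnorm(nrow(d))
      tidy(rm_anova(d, within = c("A", "B")))$p_hf
    })
  })
  rates <- rowMeans(pvals < 0.05)   # one row per effect (A, B, A:B)
  for (r in rates) {
    expect_gte(r, 0.03)
    expect_lte(r, 0.07)
  }
})
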