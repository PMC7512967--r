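test_that("normality gate routes by Shapiro-Wilk and flags degenerate input", {
  set.seed(61)
  g1 <- normality_gate(rnorm(200))
  expect_equal(g1$branch, "parametric")
  g2 <- normality_gate(rlnorm(200, sdlog = 1.5))
  expect_equal(g2$branch, "nonparametric")
  expect_warning(g3 <- normality_gate(rep(5, 20)), "constant")
  expect_true(g3$degenerate)
  expect_equal(g3$branch, "nonparametric")
  expect_error(normality_gate(c(1, 2)), "at least 3")
})

test_that("paired comparison: shifts give T = 0; equality is degenerate", {
  set.seed(62)
  b <- rnorm(20)
  res <- compare_paired(b + 2, b, method = "wilcoxon")
  expect_equal(res$statistic, 0)
  expect_equal(res$direction, 1)
  expect_lt(res$p_value, 0.001)

  dg <- compare_paired(b, b)
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 1)
})

test_that("comparisons delegate to the standard routines", {
  set.seed(63)
  a <- rnorm(25); b <- rnorm(25, 0.3)
  res_w <- compare_paired(a, b, method = "wilcoxon")
  expect_equal(res_w$p_value, wilcox.test(a, b, paired = TRUE)$p.value)
  res_t <- compare_paired(a, b, method = "ttest")
  expect_equal(res_t$p_value, t.test(a, b, paired = TRUE)$p.value)
  expect_equal(res_t$statistic, unname(t.test(a, b, paired = TRUE)$statistic))

  x <- rnorm(30); y <- rnorm(35, 0.5)
  res_u <- compare_independent(x, y, method = "mannwhitney")
  expect_equal(res_u$p_value, wilcox.test(x, y)$p.value)
  W <- unname(wilcox.test(x, y)$statistic)
  expect_equal(res_u$statistic, min(W, 30 * 35 - W))

  m <- matrix(rnorm(60), nrow = 10)
  res_f <- repeated_trend(m)
  expect_equal(res_f$statistic, unname(friedman.test(m)$statistic))
  expect_equal(res_f$p_value, friedman.test(m)$p.value)

  y2 <- x[1:30]^3 + rnorm(30, 0, 0.5)
  res_s <- correlate_spearman(x[1:30], y2)
  ct <- suppressWarnings(cor.test(x[1:30], y2, method = "spearman"))
  expect_equal(res_s$statistic, unname(ct$estimate))
  expect_equal(res_s$p_value, ct$p.value)
})

test_that("signed-rank reporting statistics are internally consistent", {
  # hand-checked small case: d = c(1, -2, 3, 4) -> ranks 1,2,3,4
  tz <- compare_paired(c(2, 1, 5, 7), c(1, 3, 2, 3), method = "wilcoxon")
  # T+ = 1 + 3 + 4 = 8, T- = 2, T = 2
  expect_equal(tz$statistic, 2)
})

test_that("Friedman on identical columns is exactly null", {
  m <- matrix(rep(rnorm(8), 4), nrow = 8)
  res <- repeated_trend(m)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(repeated_trend(matrix(c(1, NA, 2, 3, 4, 5, 6, 7, 8), 3)),
               "complete")
})

test_that("Spearman correlation hits the rank-agreement extremes", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(correlate_spearman(x, exp(x))$statistic, 1)
  expect_equal(correlate_spearman(x, -x^3)$statistic, -1)
  dg <- correlate_spearman(x, rep(2, 6))
  expect_true(dg$degenerate)
})

test_that("identical independent samples give a null result", {
  set.seed(64)
  x <- rnorm(50)
  res <- compare_independent(x, x, method = "mannwhitney")
  expect_gt(res$p_value, 0.9)
})

test_that("paired experiment reports have the published table shape", {
  cfg <- experiment_presets("language_paired")
  s <- summarize_experiment(gen_experiment(cfg, seed = 65))
  rep <- experiment_report(s, "paired")
  expect_equal(nrow(rep$descriptives), 6L)  # 3 indexes x 2 conditions
  expect_true(all(c("index", "condition", "n") %in%
                  names(rep$descriptives)))
  expect_equal(nrow(rep$tests), 3L)
  expect_true(all(rep$tests$n == 29))
  # nonparametric branch carries Med/Q1/Q3 honoring Q1 <= Med <= Q3
  npar <- rep$descriptives[!is.na(rep$descriptives$median), ]
  expect_true(all(npar$q1 <= npar$median & npar$median <= npar$q3))
})

test_that("timecourse reports carry Friedman per arm plus pairwise columns", {
  cfg <- experiment_presets("alcohol_timecourse")
  cfg$n_subjects <- 8L  # shape check only
  s <- summarize_experiment(gen_experiment(cfg, seed = 66))
  rep <- experiment_report(s, "timecourse", indexes = "sampen")
  expect_equal(nrow(rep$descriptives), 12L)  # 2 arms x 6 segments
  fr <- rep$tests[grepl("dynamics", rep$tests$comparison), ]
  expect_equal(nrow(fr), 2L)
  pw <- rep$tests[grepl("@", rep$tests$comparison), ]
  expect_equal(nrow(pw), 6L)
  # optional Holm correction never lowers a p-value
  rep_h <- experiment_report(s, "timecourse", indexes = "sampen",
                             p_adjust = "holm")
  pw_h <- rep_h$tests[grepl("@", rep_h$tests$comparison), ]
  expect_true(all(pw_h$p_value >= pw$p_value - 1e-12))
})
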