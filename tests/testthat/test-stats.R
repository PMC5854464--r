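plan <- bundled_plan("canonical")

test_that("percent rounding is half away from zero at one decimal", {
  expect_equal(round_half_away(100 * 46 / 96), 47.9)
  expect_equal(round_half_away(100 * 28 / 113), 24.8)
  expect_equal(round_half_away(0.25, 1), 0.3)
  expect_equal(round_half_away(-0.25, 1), -0.3)
  expect_equal(round_half_away(100 * 50 / 96), 52.1)
})

test_that("per-subline percentages reproduce the printed cells", {
  pct <- score_percentages(table1_scores())
  cell <- function(step, sub, class) {
    pct$pct[pct$step == step & pct$subline == sub & pct$class == class]
  }
  expect_equal(cell("F3", "S1", "mCe+mO+mC"), 52.1)
  expect_equal(cell("F3", "S6", "mCe"), 48.2)
  expect_equal(cell("F4", "S4", "mO+mC"), 3.0)
  expect_equal(cell("F5", "S5", "mO+mC"), 30.0)
  expect_equal(cell("F6-S", "S1", "mC"), 53.6)
  expect_equal(cell("F7-O", "S1", "mO"), 100.0)
})

test_that("summarize reproduces the printed across-subline mean and SD cells", {
  s <- summarize_scores(table1_scores(), theoretical = plan)
  cell <- function(step, class) {
    r <- s[s$step == step & s$class == class, ]
    c(r$mean_pct, r$sd_pct)
  }
  expect_equal(cell("F3", "mCe"), c(49.2, 3.9))
  expect_equal(cell("F3", "mCe+mO+mC"), c(50.8, 3.9))
  expect_equal(cell("F4", ""), c(23.9, 7.2))
  expect_equal(cell("F4", "mCe"), c(30.8, 8.5))
  expect_equal(cell("F4", "mO"), c(12.9, 5.6))
  expect_equal(cell("F4", "mC"), c(9.5, 2.1))
  expect_equal(cell("F4", "mCe+mO"), c(9.9, 6.3))
  expect_equal(cell("F4", "mCe+mC"), c(11.8, 4.2))
  expect_equal(cell("F4", "mO+mC")[1], 0.5)
  expect_equal(cell("F4", "mCe+mO+mC")[1], 0.7)
  expect_equal(cell("F5", ""), c(25.8, 3.5))
  expect_equal(cell("F5", "mO"), c(28.1, 3.5))
  expect_equal(cell("F5", "mC"), c(22.2, 8.8))
  expect_equal(cell("F5", "mO+mC"), c(23.9, 4.0))
  expect_equal(cell("F6-S", "mO"), c(52.1, 3.7))
  expect_equal(cell("F6-S", "mC"), c(47.9, 3.7))
  expect_equal(cell("F6", "mO"), c(20.7, 1.9))
  expect_equal(cell("F6", "mC"), c(26.9, 5.2))
  expect_equal(cell("F7-O", "mO"), c(100, 0))
  expect_equal(cell("F7-C", "mC"), c(100, 0))
})

test_that("a single subline gives a mean but no SD or test", {
  t1 <- table1_scores()
  s <- summarize_scores(t1[t1$subline == "S1", ], theoretical = plan)
  r <- s[s$step == "F3" & s$class == "mCe", ]
  expect_equal(r$n_sublines, 1L)
  expect_equal(r$mean_pct, 47.9)
  expect_true(is.na(r$sd_pct))
  expect_true(is.na(r$p_value))
})

test_that("the one-sample t-test reproduces hand-computed reference values", {
  # the six both-marker percentages of the first scored cross vs 50%
  x <- c(52.1, 47.6, 44.9, 55.9, 52.4, 51.8)
  tt <- one_sample_ttest(x, 50)
  expect_equal(tt$statistic, 0.4912, tolerance = 1e-3)
  expect_equal(tt$p_value, 0.6441, tolerance = 1e-3)
  expect_equal(tt$df, 5)
  # degenerate samples
  expect_equal(one_sample_ttest(c(100, 100, 100), 100)$p_value, 1)
  expect_equal(one_sample_ttest(c(100, 100, 100), 100)$statistic, 0)
  expect_equal(one_sample_ttest(c(90, 90), 100)$p_value, 0)
  expect_error(one_sample_ttest(50, 50), "n >= 2")
})

test_that("the t-test agrees with the textbook formula on random inputs", {
  set.seed(23)
  for (i in 1:50) {
    x <- rnorm(sample(3:12, 1), mean = 50, sd = 5)
    mu <- runif(1, 40, 60)
    got <- one_sample_ttest(x, mu)
    want <- oracle_ttest(x, mu)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
})

test_that("the heterozygote-cross both-marker percentages are not significant", {
  x <- c(54.9, 43.0, 54.2, 55.3, 51.4, 55.9)
  expect_gt(one_sample_ttest(x, 50)$p_value, 0.05)
})

test_that("multinomial goodness of fit: exact, asymptotic and violations", {
  # counts exactly proportional to the distribution
  g0 <- multinomial_gof(setNames(c(25L, 25L, 50L), c("mO", "mC", "mO+mC")),
                        setNames(c(0.25, 0.25, 0.5), c("mO", "mC", "mO+mC")))
  expect_equal(g0$statistic, 0)
  expect_equal(g0$p_value, 1)
  expect_equal(g0$method, "exact multinomial")

  # a published equal-ratio brood (31/30/27/26 of 114) vs uniform quarters
  cnt <- setNames(c(31L, 30L, 27L, 26L), c("", "mO", "mC", "mO+mC"))
  g1 <- multinomial_gof(cnt, setNames(rep(0.25, 4), names(cnt)))
  expect_equal(g1$method, "exact multinomial")
  expect_gt(g1$p_value, 0.05)
  expect_false(g1$violation)

  # exact p agrees with the binomial tail in the two-class case
  g2 <- multinomial_gof(setNames(c(9L, 21L), c("mO", "mC")),
                        setNames(c(0.5, 0.5), c("mO", "mC")))
  want <- sum(dbinom(0:30, 30, 0.5)[dbinom(0:30, 30, 0.5) <=
                                      dbinom(9, 30, 0.5) + 1e-12])
  expect_equal(g2$p_value, want, tolerance = 1e-9)

  # large brood falls back to the chi-square approximation
  g3 <- multinomial_gof(setNames(c(260L, 240L), c("mO", "mC")),
                        setNames(c(0.5, 0.5), c("mO", "mC")))
  expect_equal(g3$method, "chi-square")
  expect_equal(g3$p_value, chisq.test(c(260, 240), p = c(0.5, 0.5))$p.value,
               tolerance = 1e-12)

  # zero-probability class observed: a model violation, not a p-value
  g4 <- multinomial_gof(setNames(c(95L, 5L), c("mO", "mO+mC")),
                        setNames(c(1, 0), c("mO", "mO+mC")))
  expect_true(g4$violation)
  expect_equal(g4$classes, "mO+mC")
  expect_error(multinomial_gof(setNames(0L, "mO"), setNames(1, "mO")),
               "positive")
})

test_that("insertion-number and viability thresholds are inclusive", {
  expect_equal(classify_insertions(0.521), "single")
  expect_equal(classify_insertions(0.60), "single")
  expect_equal(classify_insertions(0.75), "multiple")
  expect_equal(classify_viability(0.75), "homozygous-viable")
  expect_equal(classify_viability(0.70), "homozygous-viable")
  expect_equal(classify_viability(2 / 3), "suspect")
})

test_that("recombination efficiency is estimated from residual both-marker carriers", {
  t1 <- table1_scores()
  est <- estimate_recombination_efficiency(t1[t1$subline == "S4", ], "F4")
  expect_equal(est$p_hat, 1 - 7 / 71, tolerance = 1e-12)
  expect_equal(est$both, 7L)
  expect_equal(est$carriers, 71L)
  expect_equal(est$residual_both_fraction, 0.07, tolerance = 1e-12)
  expect_true(est$ci[1] < est$p_hat && est$p_hat < est$ci[2])
  # the interval is the reversed Clopper-Pearson interval of the residual
  bt <- binom.test(7, 71)
  expect_equal(est$ci, rev(1 - bt$conf.int), tolerance = 1e-12)

  # boundary cases
  clean <- data.frame(step = "F4", subline = "S1",
                      class = c("mO", "mC"), count = c(40L, 40L))
  expect_equal(estimate_recombination_efficiency(clean, "F4")$p_hat, 1)
  stuck <- data.frame(step = "F4", subline = "S1",
                      class = "mO+mC", count = 50L)
  expect_equal(estimate_recombination_efficiency(stuck, "F4")$p_hat, 0)
  wt <- data.frame(step = "F4", subline = "S1", class = "", count = 10L)
  expect_error(estimate_recombination_efficiency(wt, "F4"), "no transgene")
})

test_that("the pooled-deviation reading of the test is non-significant throughout", {
  pd <- pooled_deviation_test(table1_scores(), plan)
  expect_true(all(pd$p_value > 0.05))
})
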