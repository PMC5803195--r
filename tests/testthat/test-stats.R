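test_that("within-subject CV matches hand-computed values and bins", {
  # identical pairs
  res <- cv_test_retest(c(5, 7, 9), c(5, 7, 9))
  expect_equal(res$cv_percent, 0)
  expect_equal(res$bin, "good")
  # single-pair formula: 100 * sqrt(0.5) / 10.5 (padded with an identical
  # pair to satisfy n >= 2)
  res1 <- cv_test_retest(c(10, 10), c(11, 11))
  expect_equal(res1$cv_percent, 100 * sqrt(0.5) / 10.5, tolerance = 1e-12)
  expect_equal(res1$bin, "good")
  # |difference| = 5 with mean 10 throughout: 100 * (5 / sqrt(2)) / 10
  res2 <- cv_test_retest(c(12.5, 7.5), c(7.5, 12.5))
  expect_equal(res2$cv_percent, 100 * 5 / sqrt(2) / 10, tolerance = 1e-12)
  expect_equal(res2$bin, "poor")
  # boundary conventions
  expect_equal(cv_bin_of(10), "good")
  expect_equal(cv_bin_of(10.01), "moderate")
  expect_equal(cv_bin_of(25), "poor")
  expect_error(cv_test_retest(c(1, 0), c(1, 1)), "positive")
  expect_error(cv_test_retest(1, 1), "pairs")
})

test_that("the two CV estimators agree on homogeneous pairs and differ on heterogeneous ones", {
  x1 <- c(10, 10); x2 <- c(11, 11)
  expect_equal(cv_test_retest(x1, x2, "rms")$cv_percent,
               cv_test_retest(x1, x2, "per_subject")$cv_percent,
               tolerance = 1e-12)
  y1 <- c(10, 100); y2 <- c(12, 101)
  expect_false(isTRUE(all.equal(
    cv_test_retest(y1, y2, "rms")$cv_percent,
    cv_test_retest(y1, y2, "per_subject")$cv_percent)))
})

test_that("percentage Bland-Altman bias and limits are exact on toy input", {
  res0 <- bland_altman_percent(c(5, 7, 9), c(5, 7, 9))
  expect_equal(c(res0$bias_percent, res0$lower, res0$upper), c(0, 0, 0))
  # differences +2% and -2%: bias 0, SD = 2 * sqrt(2)
  res <- bland_altman_percent(c(101, 99), c(99, 101))
  expect_equal(res$bias_percent, 0)
  expect_equal(res$sd_percent, 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(res$upper, 1.96 * 2 * sqrt(2), tolerance = 1e-12)
  # swapping exams negates the bias and mirrors the limits
  a <- c(10, 12, 9.5); b <- c(11, 11.5, 9.8)
  r1 <- bland_altman_percent(a, b); r2 <- bland_altman_percent(b, a)
  expect_equal(r1$bias_percent, -r2$bias_percent)
  expect_equal(r1$lower, -r2$upper)
  expect_error(bland_altman_percent(c(1, -1), c(1, 1)), "zero")
})

test_that("CV and Bland-Altman are scale and relabeling invariant as expected", {
  set.seed(42)
  x1 <- runif(8, 5, 15); x2 <- x1 * (1 + rnorm(8, 0, 0.05))
  cv <- cv_test_retest(x1, x2)$cv_percent
  ba <- bland_altman_percent(x1, x2)
  # multiplying all values by c > 0 changes nothing
  expect_equal(cv_test_retest(3 * x1, 3 * x2)$cv_percent, cv)
  expect_equal(bland_altman_percent(3 * x1, 3 * x2)$bias_percent,
               ba$bias_percent)
  # subject relabeling changes nothing; exam swap leaves CV alone
  p <- sample(8)
  expect_equal(cv_test_retest(x1[p], x2[p])$cv_percent, cv)
  expect_equal(cv_test_retest(x2, x1)$cv_percent, cv)
})

test_that("Spearman TE trend handles monotone, null and degenerate input", {
  te <- rep(c(60, 70, 80, 90, 100, 120), each = 3)
  inc <- seq_along(te)
  res <- spearman_te_trend(inc, te)
  expect_lt(abs(res$rho - cor(inc, te, method = "spearman")), 1e-12)
  expect_gt(res$rho, 0.9)
  expect_equal(spearman_te_trend(te + 0, te)$rho, 1)  # perfect, with ties
  expect_equal(spearman_te_trend(te + 0, te)$bin, "strong")
  # rho is invariant under strictly monotone transforms of TE
  set.seed(7)
  v <- rnorm(length(te), mean = te / 50)
  expect_equal(spearman_te_trend(v, te)$rho,
               spearman_te_trend(v, log(te))$rho)
  # TE-independent values: small rho, non-significant
  set.seed(8)
  nul <- spearman_te_trend(rnorm(600),
                           rep(c(60, 70, 80, 90, 100, 120), each = 100))
  expect_lt(abs(nul$rho), 0.1)
  expect_gt(nul$p_value, 0.05)
  # constant input is flagged, not an error
  flat <- spearman_te_trend(rep(2, 18), te)
  expect_false(flat$defined)
  expect_equal(flat$bin, "undefined")
})

test_that("one-way ANOVA matches the hand-computed F and flags degeneracy", {
  res <- anova_across_te(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$f_statistic, 13.5, tolerance = 1e-12)
  expect_equal(res$df, c(1, 4))
  expect_equal(res$p_value,
               stats::pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  # equal groups with zero variance: undefined F, flagged
  deg <- anova_across_te(list(c(2, 2), c(2, 2)))
  expect_false(deg$defined)
  expect_true(is.na(deg$f_statistic))
  # distinct constant groups: infinite separation
  inf <- anova_across_te(list(c(1, 1), c(2, 2)))
  expect_equal(inf$f_statistic, Inf)
  expect_error(anova_across_te(list(1:3)), "groups")
})

test_that("SNR estimator is the ROI mean over the muscle SD and is scale invariant", {
  muscle <- c(9, 10, 11, 10.5, 9.5)
  expect_equal(snr_estimate(20, c(0, 2)), 20 / sd(c(0, 2)))
  expect_equal(snr_estimate(c(19, 21), muscle), 20 / sd(muscle))
  expect_equal(snr_estimate(2 * c(19, 21), 2 * muscle),
               snr_estimate(c(19, 21), muscle))
  expect_error(snr_estimate(20, c(1, 1)), "zero")
  expect_error(snr_estimate(20, 1), "muscle")
})
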