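test_that("welch_ttest handles raw, summary and degenerate inputs", {
  x <- c(1, 2, 3, 4, 5)
  r0 <- welch_ttest(x, x)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)

  # summary path agrees with stats::t.test on the same data
  set.seed(11)
  a <- stats::rnorm(40, 5, 2); b <- stats::rnorm(55, 6, 3)
  raw <- welch_ttest(a, b)
  summ <- welch_ttest(list(mean = mean(a), sd = stats::sd(a), n = 40),
                      list(mean = mean(b), sd = stats::sd(b), n = 55))
  expect_equal(summ$t, raw$t, tolerance = 1e-12)
  expect_equal(summ$df, raw$df, tolerance = 1e-12)
  expect_equal(summ$p_value, raw$p_value, tolerance = 1e-12)

  # strongly separated groups
  set.seed(12)
  g1 <- stats::rnorm(50, 0, 1); g2 <- stats::rnorm(50, 3, 1)
  expect_lt(welch_ttest(g1, g2)$p_value, 1e-10)

  expect_error(welch_ttest(1, x), "n >= 2")
  expect_error(welch_ttest(list(mean = 1, sd = 0, n = 5),
                           list(mean = 2, sd = 1, n = 5)), "degenerate")
})

test_that("published age summaries separate the clinical groups", {
  r <- welch_ttest(list(mean = 71.9, sd = 10.4, n = 135),
                   list(mean = 77.1, sd = 6.9, n = 83))
  expect_lt(r$p_value, 0.001)
})

test_that("icc matches the explicit ANOVA oracle on random matrices", {
  set.seed(13)
  for (k in c(2, 3)) {
    x <- matrix(stats::rnorm(10 * k, 10, 2), 10, k)
    orc <- icc_oracle(x)
    for (form in c("absolute", "consistency")) {
      r <- icc(x, form)
      expect_equal(r$icc, orc[[form]], tolerance = 1e-10)
      expect_true(r$lower <= r$icc && r$icc <= r$upper)
      expect_true(r$icc >= -1 && r$icc <= 1)
    }
  }
})

test_that("icc reacts to offsets and degenerate data as theory says", {
  x <- matrix(stats::rnorm(12, 5, 2), 12, 1)[, c(1, 1)]
  expect_equal(icc(x, "absolute")$icc, 1, tolerance = 1e-12)
  expect_equal(icc(x, "consistency")$icc, 1, tolerance = 1e-12)

  y <- cbind(x[, 1], x[, 1] + 2)
  expect_equal(icc(y, "consistency")$icc, 1, tolerance = 1e-12)
  expect_lt(icc(y, "absolute")$icc, 1)

  # consistency >= absolute whenever the data carry real subject variance
  # (MSR >= MSE) and systematic rater offsets (MSC >= MSE); the standard
  # untruncated estimators can invert the ordering outside that regime
  set.seed(14)
  for (i in 1:10) {
    m <- outer(stats::rnorm(10, 0, 2), rep(1, 3)) +
      matrix(stats::rnorm(30, 0, 0.5), 10, 3) + outer(rep(1, 10), c(0, 1, 2))
    r <- icc(m, "consistency")
    expect_gte(r$msc, r$mse)
    expect_gte(r$msr, r$mse)
    expect_gte(r$icc, icc(m, "absolute")$icc - 1e-12)
  }

  expect_warning(r0 <- icc(matrix(5, 6, 2), "consistency"),
                 "zero between-subject")
  expect_equal(r0$icc, 0)
  expect_error(icc(matrix(1, 2, 2)), ">= 3 subjects")
})

test_that("bland_altman reproduces constant offsets and the LOA width", {
  x <- c(0.5, 0.6, 0.7, 0.8)
  b0 <- bland_altman(x, x)
  expect_equal(b0$mean_diff, 0)
  expect_equal(c(b0$loa_lower, b0$loa_upper), c(0, 0))

  b1 <- bland_altman(x, x - 0.04)
  expect_equal(b1$mean_diff, 0.04, tolerance = 1e-12)
  expect_equal(b1$sd_diff, 0)
  expect_equal(c(b1$loa_lower, b1$loa_upper), c(0.04, 0.04),
               tolerance = 1e-12)

  set.seed(15)
  sig <- 0.3
  d <- stats::rnorm(10000, 0, sig)
  b2 <- bland_altman(d, numeric(10000))
  half <- (b2$loa_upper - b2$loa_lower) / 2
  expect_lt(abs(half - 1.96 * sig) / (1.96 * sig), 0.05)

  # antisymmetry
  set.seed(16)
  u <- stats::rnorm(50); v <- stats::rnorm(50)
  expect_equal(bland_altman(u, v)$mean_diff, -bland_altman(v, u)$mean_diff,
               tolerance = 1e-12)
  expect_error(bland_altman(u, v[-1]), "equal length")
})

test_that("classification metrics follow their definitions", {
  cm <- classification_metrics(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_true(all(c(cm$acc, cm$sen, cm$spec, cm$auc) == 1))

  cm2 <- classification_metrics(c(1, 1, 0, 0), c(0, 0, 0, 0))
  expect_equal(cm2$sen, 0)
  expect_equal(cm2$spec, 1)
  expect_equal(cm2$auc, 0.5)

  set.seed(17)
  tr <- sample(0:1, 60, TRUE); pr <- sample(0:1, 60, TRUE)
  perm <- sample(60)
  expect_identical(classification_metrics(tr, pr),
                   classification_metrics(tr[perm], pr[perm]))
  cm3 <- classification_metrics(tr, pr)
  expect_equal(cm3$auc, (cm3$sen + cm3$spec) / 2, tolerance = 1e-12)
  expect_equal(cm3$acc, (cm3$tp + cm3$tn) / 60, tolerance = 1e-12)

  expect_error(classification_metrics(rep(1, 5), sample(0:1, 5, TRUE)),
               "single class")
})

test_that("printed metrics invert to a unique confusion matrix", {
  hits <- reconstruct_confusion(acc = 0.9633, sen = 0.9412, spec = 0.9774,
                                n = 218)
  expect_identical(nrow(hits), 1L)
  expect_identical(as.integer(hits[1, ]), c(80L, 5L, 130L, 3L))
  truth <- rep(c(1, 0), c(85, 133))
  pred <- c(rep(1, 80), rep(0, 5), rep(0, 130), rep(1, 3))
  cm <- classification_metrics(truth, pred)
  expect_equal(round(cm$acc, 4), 0.9633)
  expect_equal(round(cm$sen, 4), 0.9412)
  expect_equal(round(cm$spec, 4), 0.9774)
  expect_equal(round(cm$auc, 4), 0.9593)
})

test_that("statistics results tidy and plot cleanly", {
  set.seed(18)
  m <- matrix(stats::rnorm(20), 10, 2)
  td <- tidy(icc(m, "absolute"))
  expect_s3_class(td, "tbl_df")
  expect_identical(td$form, "absolute")
  ba <- bland_altman(m[, 1], m[, 2])
  expect_s3_class(glance(ba), "tbl_df")
  expect_s3_class(autoplot(ba), "ggplot")
})
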