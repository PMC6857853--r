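test_that("diagnostic metrics reproduce count-ratio arithmetic", {
  m <- metrics_from_counts(confusion_counts(tp = 14, fn = 1, tn = 13, fp = 2))
  expect_equal(m$percent_rounded[m$metric == "sensitivity"], 93)
  m2 <- metrics_from_counts(confusion_counts(tp = 8, fn = 3, tn = 3, fp = 0))
  expect_equal(m2$percent_rounded[m2$metric == "sensitivity"], 73)
  expect_equal(m2$percent_rounded[m2$metric == "specificity"], 100)
  perfect <- metrics_from_counts(confusion_counts(tp = 7, fn = 0, tn = 9, fp = 0))
  expect_true(all(perfect$percent_rounded == 100))
})

test_that("zero denominators are undefined, never zero", {
  m <- metrics_from_counts(confusion_counts(tp = 0, fn = 0, tn = 5, fp = 2))
  expect_true(is.na(m$fraction[m$metric == "sensitivity"]))
  expect_true(is.na(m$percent_rounded[m$metric == "sensitivity"]))
  expect_false(is.na(m$fraction[m$metric == "specificity"]))
})

test_that("percent rounding is half-up with the raw fraction retained", {
  expect_equal(round_half_up(c(86.5, 87.5, 92.5)), c(87, 88, 93))
  m <- metrics_from_counts(confusion_counts(tp = 13, fn = 2, tn = 1, fp = 1))
  sens <- m[m$metric == "sensitivity", ]
  expect_equal(sens$fraction, 13 / 15)
  expect_equal(sens$percent_rounded, 87)   # 86.67 rounds to 87, not 88
  m1 <- metrics_from_counts(confusion_counts(tp = 13, fn = 2, tn = 1, fp = 1),
                            rounding = "one_decimal")
  expect_equal(m1$percent_rounded[m1$metric == "sensitivity"], 86.7)
})

test_that("metrics agree with a brute-force recount from prediction vectors", {
  withr::with_seed(6, {
    truth <- runif(200) < 0.4
    pred <- ifelse(runif(200) < 0.8, truth, !truth)
  })
  cc <- count_confusion(truth, pred)
  m <- metrics_from_counts(cc)
  expect_equal(m$fraction[m$metric == "sensitivity"],
               mean(pred[truth]))
  expect_equal(m$fraction[m$metric == "specificity"],
               mean(!pred[!truth]))
  expect_equal(m$fraction[m$metric == "accuracy"], mean(pred == truth))
})

test_that("Cohen's kappa matches hand-computed marginals and its oracle", {
  k <- cohen_kappa(matrix(c(40, 10, 5, 45), 2))
  expect_equal(k$po, 0.85)
  expect_equal(k$pe, 0.50)
  expect_equal(k$kappa, 0.70)
  expect_equal(cohen_kappa(c(1, 0, 1, 1), c(1, 0, 1, 1))$kappa, 1)
  # independent raters: kappa near 0
  withr::with_seed(10, {
    a <- runif(10000) < 0.5; b <- runif(10000) < 0.5
  })
  expect_lt(abs(cohen_kappa(a, b)$kappa), 0.05)
  # symmetry and relabelling invariance
  withr::with_seed(2, {
    x <- sample(c("p", "n"), 100, replace = TRUE)
    y <- sample(c("p", "n"), 100, replace = TRUE)
  })
  expect_equal(cohen_kappa(x, y)$kappa, cohen_kappa(y, x)$kappa)
  relab <- function(v) ifelse(v == "p", "z1", "z0")
  expect_equal(cohen_kappa(x, y)$kappa, cohen_kappa(relab(x), relab(y))$kappa)
  # independent oracle: e1071's classAgreement on the same table
  tab <- table(x, y)
  expect_equal(cohen_kappa(tab)$kappa,
               e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
  # both raters constant and identical: undefined
  und <- cohen_kappa(c("a", "a"), c("a", "a"))
  expect_true(und$undefined)
  expect_true(is.na(und$kappa))
})

test_that("McNemar handles exact, corrected and degenerate regimes", {
  expect_equal(mcnemar_test(7, 7)$p_value, 1)
  ex <- mcnemar_test(10, 0)
  expect_equal(ex$p_value, 2 * 0.5^10, tolerance = 1e-15)
  expect_identical(ex$method, "exact_binomial")
  deg <- mcnemar_test(0, 0)
  expect_equal(deg$p_value, 1)
  expect_true(deg$degenerate)
  # corrected chi-square agrees with the stats oracle for b + c >= 25
  big <- mcnemar_test(20, 12)
  oracle <- stats::mcnemar.test(matrix(c(5, 12, 20, 5), 2), correct = TRUE)
  expect_equal(big$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(big$p_value, oracle$p.value, tolerance = 1e-12)
  expect_error(mcnemar_test(-1, 2), "non-negative")
})

test_that("ROC analysis: AUC, Youden cutoff and invariances", {
  r <- roc_analysis(c(0.8, 0.9, 0.1, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$youden_cutoff, 0.5)     # midpoint of (0.2, 0.8)
  expect_equal(r$youden_j, 1)
  # AUC invariant under strictly increasing transforms
  s <- c(0.1, 0.3, 0.35, 0.6, 0.7, 0.9)
  lab <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  expect_equal(roc_analysis(s, lab)$auc, roc_analysis(qlogis(s), lab)$auc)
  # null scores: AUC near 1/2
  withr::with_seed(3, {
    s2 <- runif(4000); lab2 <- runif(4000) < 0.5
  })
  expect_lt(abs(roc_analysis(s2, lab2)$auc - 0.5), 0.05)
  expect_error(roc_analysis(c(1, 2), c(TRUE, TRUE)), "both positive and negative")
  expect_error(roc_analysis(c(1, 1), c(TRUE, FALSE)), "identical")
  # independent oracle on random data
  if (requireNamespace("pROC", quietly = TRUE)) {
    withr::with_seed(8, {
      sc <- c(rnorm(40, 1), rnorm(40))
      lb <- rep(c(TRUE, FALSE), each = 40)
    })
    expect_equal(roc_analysis(sc, lb)$auc,
                 as.numeric(suppressMessages(pROC::auc(lb, sc))),
                 tolerance = 1e-12)
  }
})

test_that("group tests report Kruskal-Wallis, normality and correlation", {
  withr::with_seed(5, {
    df <- data.frame(
      class = rep(c("A", "B", "C"), each = 30),
      value = c(rnorm(30, 0), rnorm(30, 2), rnorm(30, 4))
    )
  })
  gt <- group_tests(df, "value", "class")
  expect_lt(gt$kruskal$p_value, 1e-6)
  expect_equal(gt$kruskal$df, 2)
  expect_equal(nrow(gt$normality), 3)
  expect_identical(unique(gt$normality$method), "ks_estimated_params")
  # degenerate group flagged, not fatal
  df2 <- rbind(df, data.frame(class = "D", value = 1))
  gt2 <- group_tests(df2, "value", "class")
  expect_identical(gt2$normality$method[gt2$normality$group == "D"],
                   "undefined")
  # exact linear relation gives r = 1
  xy <- data.frame(x = 1:20, y = 2 * (1:20) + 1)
  expect_equal(feature_correlation(xy, "x", "y")$r, 1)
})

test_that("Wilson intervals cover the estimate and match binom.test bounds' order", {
  ci <- wilson_ci(14, 15)
  expect_equal(ci$estimate, 14 / 15)
  expect_true(ci$lower < ci$estimate && ci$estimate < ci$upper)
  expect_true(ci$lower >= 0 && ci$upper <= 1)
  # degenerate extremes stay inside [0, 1] with non-empty intervals
  lo <- wilson_ci(0, 10); hi <- wilson_ci(10, 10)
  expect_gt(lo$upper, 0)
  expect_lt(hi$lower, 1)
  expect_error(wilson_ci(5, 0), "n")
  expect_error(wilson_ci(11, 10), "x")
})

test_that("manual cytology score sums features with a strict >3 rule", {
  rec <- tibble::as_tibble(setNames(as.list(rep(0, 7)), manual_features()))
  expect_equal(manual_cytology_score(rec)$score, 0L)
  expect_false(manual_cytology_score(rec)$positive)
  rec4 <- rec; rec4[1, 1:4] <- 1
  out4 <- manual_cytology_score(rec4)
  expect_equal(out4$score, 4L)
  expect_true(out4$positive)
  rec3 <- rec; rec3[1, 1:3] <- 1
  expect_false(manual_cytology_score(rec3)$positive)   # exactly 3: negative
  expect_error(manual_cytology_score(rec[, -1]), "multi_nucleation")
  rec_na <- rec; rec_na[1, 2] <- NA
  expect_error(manual_cytology_score(rec_na), "missing")
  # six-feature variant
  six <- manual_features(include_abnormal_shape = FALSE)
  expect_length(six, 6)
  expect_equal(manual_cytology_score(rec4, features = six)$score, 4L)
})
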