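test_that("a 60-patient cohort splits exactly 30/30, stratified", {
  coh <- separable_cohort(n_per_class = 15)
  sp <- split_cohort(coh, fraction = 0.5, seed = 4)
  expect_equal(nrow(sp$train), 30)
  expect_equal(nrow(sp$test), 30)
  expect_equal(sort(c(sp$train$patient_id, sp$test$patient_id)),
               sort(coh$patient_id))                      # disjoint, exhaustive
  for (cl in unique(coh$class)) {
    n_cl <- sum(coh$class == cl)
    expect_lte(abs(sum(sp$train$class == cl) - ceiling(0.5 * n_cl)), 1)
  }
  again <- split_cohort(coh, fraction = 0.5, seed = 4)
  expect_identical(sp$train$patient_id, again$train$patient_id)
  tiny <- coh[c(1, 16, 31, 46, 2), ]                      # one class with 1
  expect_error(split_cohort(tiny[c(1:4), ], fraction = 0.5), "fewer than 2")
  expect_error(split_cohort(coh, fraction = 0), "fraction")
})

test_that("Test-1 SVM separates a linearly separable cohort perfectly", {
  coh <- separable_cohort()
  sp <- split_cohort(coh, fraction = 0.5, seed = 1)
  m <- train_test1(sp$train)
  pred_tr <- predict_test1(m, sp$train)
  expect_true(all(pred_tr$positive == (sp$train$class == "OSCC")))
  pred_te <- predict_test1(m, sp$test)
  expect_true(all(pred_te$positive == (sp$test$class == "OSCC")))
  only <- sp$train[sp$train$class != "OSCC", ]
  expect_error(train_test1(only), "both OSCC and non-OSCC")
  broken <- sp$train
  broken$mean_all[1] <- NA
  expect_error(train_test1(broken), "undefined")
})

test_that("label permutation destroys Test-1 skill (null control)", {
  coh <- generate_score_cohort(cohort_spec(seed = 8))
  feats <- aggregate_cohort(coh)
  withr::with_seed(21, {
    feats$class <- sample(feats$class)
  })
  sp <- split_cohort(feats, fraction = 0.5, seed = 3)
  m <- train_test1(sp$train)
  acc <- mean(predict_test1(m, sp$test)$positive ==
                (sp$test$class == "OSCC"))
  expect_gt(acc, 0.25)   # within binomial noise of chance for a 1:3 prior
  expect_lt(acc, 0.95)
})

test_that("Test-2 cutoff maximises Youden's J on the training scores", {
  train <- tibble::tibble(
    patient_id = sprintf("p%d", 1:4),
    class = c("OSCC", "OSCC", "LGD", "LGD"),
    mean_atypical = c(0.8, 0.9, 0.55, 0.6)
  )
  t2 <- derive_test2_cutoff(train)
  expect_gt(t2$cutoff, 0.6)
  expect_lt(t2$cutoff, 0.8)
  expect_equal(t2$j, 1)
  expect_false(t2$noninformative)
  # perfectly interleaved scores carry no information
  inter <- tibble::tibble(class = rep(c("OSCC", "LGD"), 4),
                          mean_atypical = c(0.6, 0.6, 0.7, 0.7,
                                            0.8, 0.8, 0.9, 0.9))
  expect_true(derive_test2_cutoff(inter)$noninformative)
  flat <- tibble::tibble(class = c("OSCC", "LGD"),
                         mean_atypical = c(0.7, 0.7))
  expect_error(derive_test2_cutoff(flat), "no discriminative cutoff")
  expect_error(derive_test2_cutoff(train[train$class == "LGD", ]), "defined")
})

test_that("the cascade routes patients per the two-test logic", {
  coh <- separable_cohort()
  sp <- split_cohort(coh, fraction = 0.5, seed = 2)
  model <- fit_cascade(sp$train, seed = 2)
  pred <- cascade_predict(sp$test, model)
  # strata partition the cohort
  expect_equal(sum(table(pred$stratum)), nrow(sp$test))
  # Test-1 positives are OSCC_risk regardless of the Test-2 feature
  expect_true(all(pred$stratum[pred$test1_positive] == "OSCC_risk"))
  # Test 2 is never evaluated on Test-1 positives
  expect_true(all(pred$test2_evaluated == !pred$test1_positive))
  # undefined mean atypical score -> automatic negative
  rec <- sp$test[1:2, ]
  rec$mean_atypical <- NA_real_
  rec$mean_all <- c(0.1, 0.12); rec$pct_atypical <- c(5, 6)
  p2 <- cascade_predict(rec, model)
  expect_true(all(p2$stratum == "LGD_or_benign"))
  # Test-1 negative above the cutoff -> HGD_risk
  rec3 <- sp$test[1, ]
  rec3$mean_all <- 0.1; rec3$pct_atypical <- 5
  rec3$mean_atypical <- model$test2$cutoff + 0.01
  expect_equal(as.character(cascade_predict(rec3, model)$stratum), "HGD_risk")
})

test_that("all five learners ace a separable cohort with a fixed seed", {
  coh <- separable_cohort()
  sp <- split_cohort(coh, fraction = 0.5, seed = 5)
  tab <- compare_learners(sp$train, sp$test, seed = 5)
  expect_equal(nrow(tab), 5)
  expect_setequal(tab$learner,
                  c("svm_linear", "random_forest", "logistic_regression",
                    "lda", "knn"))
  expect_true(all(tab$accuracy == 1))
  expect_true(all(is.na(tab$error)))
  again <- compare_learners(sp$train, sp$test, seed = 5)
  expect_identical(tab, again)
})

test_that("mean all-cell score and atypical percentage are strongly correlated", {
  feats <- aggregate_cohort(generate_score_cohort(cohort_spec(seed = 14)))
  r <- feature_correlation(feats, "mean_all", "pct_atypical")$r
  expect_gt(r, 0.9)
})

test_that("tidy and glance expose the fitted cascade", {
  sp <- split_cohort(separable_cohort(), fraction = 0.5, seed = 6)
  model <- fit_cascade(sp$train, seed = 6)
  td <- tidy(model)
  expect_setequal(td$term, c("mean_all_weight", "pct_atypical_weight",
                             "test1_intercept", "test2_cutoff"))
  gl <- glance(model)
  expect_equal(gl$n_train, nrow(sp$train))
  expect_equal(gl$test2_cutoff, model$test2$cutoff)
})
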