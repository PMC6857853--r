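#' Split a patient cohort into training and hold-out sets
#'
#' Seeded random split, stratified by class by default so every histology
#' grade is represented on both sides (switchable). Per-class training
#' counts use largest-remainder rounding (ties broken by class order), so a
#' 60-patient cohort at fraction 0.5 splits exactly 30/30 while every class
#' stays within one patient of `ceiling(fraction * n_class)`.
#'
#' @param records Per-patient feature tibble (needs `patient_id`; `class`
#'   required when `stratify = TRUE`).
#' @param fraction Training fraction in (0, 1); default 0.5.
#' @param seed Integer seed.
#' @param stratify Stratify by `class` (default `TRUE`).
#' @return List with `train` and `test` tibbles (disjoint, exhaustive).
#' @export
split_cohort <- function(records, fraction = 0.5, seed = 1L, stratify = TRUE) {
  check_that(is_scalar_number(fraction) && fraction > 0 && fraction < 1,
             "fraction", "must lie in (0, 1)")
  n <- nrow(records)
  check_that(n >= 2, "records", "need at least 2 patients")
  if (!stratify) {
    idx <- withr::with_seed(seed, sample(n, round(fraction * n)))
    return(list(train = records[sort(idx), , drop = FALSE],
                test = records[setdiff(seq_len(n), idx), , drop = FALSE]))
  }
  check_that("class" %in% names(records), "records",
             "stratified split needs a `class` column")
  cls <- unique(records$class)
  sizes <- vapply(cls, function(cl) sum(records$class == cl), integer(1))
  if (any(sizes < 2)) {
    abort(sprintf("class '%s' has fewer than 2 patients; cannot stratify",
                  cls[which(sizes < 2)[1]]))
  }
  total_train <- round(fraction * n)
  quota <- fraction * sizes
  alloc <- floor(quota)
  extras <- total_train - sum(alloc)
  if (extras > 0) {
    ord <- order(-(quota - alloc), seq_along(cls))
    bump <- rep_len(ord, extras)
    for (i in bump) alloc[i] <- alloc[i] + 1
  } else if (extras < 0) {
    ord <- order(quota - alloc, seq_along(cls))
    cut_ <- rep_len(ord, -extras)
    for (i in cut_) alloc[i] <- alloc[i] - 1
  }
  alloc <- pmin(pmax(alloc, 1), sizes - 1)  # both sides keep every class
  train_idx <- withr::with_seed(seed, {
    unlist(lapply(seq_along(cls), function(i) {
      rows <- which(records$class == cls[i])
      sample(rows, alloc[i])
    }))
  })
  list(train = records[sort(train_idx), , drop = FALSE],
       test = records[setdiff(seq_len(n), sort(train_idx)), , drop = FALSE])
}

test1_feature_matrix <- function(records) {
  check_that(all(c("mean_all", "pct_atypical") %in% names(records)),
             "records", "need `mean_all` and `pct_atypical` features")
  x <- cbind(mean_all = records$mean_all, pct_atypical = records$pct_atypical)
  if (any(!is.finite(x))) abort("undefined Test-1 features (NA/Inf) in records")
  x
}

#' Train the Test-1 linear SVM (carcinoma vs the rest)
#'
#' Test 1 of the risk cascade flags patients at high risk of carcinoma
#' (OSCC) using a linear-kernel maximum-margin classifier on two strongly
#' correlated per-patient features: the mean score of all cells and the
#' percentage of atypical cells. Features are standardised to zero mean and
#' unit variance on the training set; the decision rule is kept as explicit
#' weights so the model serialises to JSON and predictions are exactly
#' reproducible.
#'
#' @param train Per-patient feature tibble with a `class` column; the
#'   positive class is `"OSCC"`.
#' @param cost SVM regularisation constant C (default 1).
#' @return An object of class `cyto_test1`: standardisation constants,
#'   weights, intercept, training ids.
#' @export
train_test1 <- function(train, cost = 1) {
  check_that("class" %in% names(train), "train", "needs a `class` column")
  y <- factor(ifelse(train$class == "OSCC", "OSCC", "other"),
              levels = c("OSCC", "other"))
  if (length(unique(y)) < 2) {
    abort("Test-1 training needs both OSCC and non-OSCC patients")
  }
  x <- test1_feature_matrix(train)
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, `/`)
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  # e1071 orients decision values toward the first factor level, but verify
  # against its own predictions and flip if needed
  margin <- drop(xs %*% w) + b
  pred <- predict(fit, xs)
  agree <- mean((margin > 0) == (pred == "OSCC"))
  if (agree < 0.5) {
    w <- -w; b <- -b
  }
  structure(
    list(weights = setNames(w, colnames(x)), intercept = b,
         center = center, scale = scale_, cost = cost,
         positive_class = "OSCC",
         train_ids = train$patient_id %||% seq_len(nrow(train)),
         n_train = nrow(train)),
    class = "cyto_test1"
  )
}

#' Predict Test-1 margins and calls
#'
#' @param model A `cyto_test1`.
#' @param records Per-patient feature tibble.
#' @return Tibble `margin`, `positive` (margin > 0 means OSCC risk).
#' @export
predict_test1 <- function(model, records) {
  x <- test1_feature_matrix(records)
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, `/`)
  margin <- drop(xs %*% model$weights) + model$intercept
  tibble(margin = margin, positive = margin > 0)
}

#' Derive the Test-2 cutoff on the mean atypical-cell score
#'
#' Test 2 separates high-grade dysplasia from low-grade/benign among Test-1
#' negatives using a single scalar: the patient's mean atypical-cell score.
#' The cutoff is derived by ROC analysis of carcinoma versus low-grade
#' training patients on that feature alone, taking the candidate threshold
#' (midpoints between adjacent sorted unique training scores) that maximises
#' Youden's J, ties resolved toward the lower cutoff (higher sensitivity).
#'
#' @param train Per-patient feature tibble with `class` and `mean_atypical`.
#' @param positive_class,negative_class Classes contrasted in the ROC
#'   (defaults `"OSCC"` vs `"LGD"`).
#' @return An object of class `cyto_test2`: `cutoff`, `j`, `noninformative`
#'   flag and the full `roc` record.
#' @export
derive_test2_cutoff <- function(train, positive_class = "OSCC",
                                negative_class = "LGD") {
  check_that(all(c("class", "mean_atypical") %in% names(train)),
             "train", "needs `class` and `mean_atypical`")
  sub <- train[train$class %in% c(positive_class, negative_class) &
                 !is.na(train$mean_atypical), , drop = FALSE]
  if (sum(sub$class == positive_class) < 1 || sum(sub$class == negative_class) < 1) {
    abort(sprintf("need %s and %s patients with defined mean atypical scores",
                  positive_class, negative_class))
  }
  roc <- roc_analysis(sub$mean_atypical, sub$class == positive_class)
  structure(
    list(cutoff = roc$youden_cutoff, j = roc$youden_j,
         noninformative = roc$youden_j <= 1e-12,
         n_pos = sum(sub$class == positive_class),
         n_neg = sum(sub$class == negative_class),
         positive_class = positive_class, negative_class = negative_class,
         roc = roc),
    class = "cyto_test2"
  )
}

#' Fit the two-test risk-stratification cascade
#'
#' Trains Test 1 (linear SVM, carcinoma vs rest) and derives the Test-2
#' cutoff (ROC on the mean atypical-cell score, carcinoma vs low-grade) on
#' the same training records. At prediction time Test 2 is applied only to
#' Test-1 negatives.
#'
#' @param train Per-patient feature tibble (`class`, `mean_all`,
#'   `pct_atypical`, `mean_atypical`).
#' @param seed Seed recorded in the model metadata.
#' @param cost Test-1 SVM cost.
#' @return An object of class `cyto_cascade`.
#' @export
fit_cascade <- function(train, seed = 1L, cost = 1) {
  structure(
    list(test1 = train_test1(train, cost = cost),
         test2 = derive_test2_cutoff(train),
         label_map = c(positive1 = "OSCC_risk", positive2 = "HGD_risk",
                       negative = "LGD_or_benign"),
         seed = as.integer(seed), n_train = nrow(train)),
    class = "cyto_cascade"
  )
}

#' @method print cyto_cascade
#' @export
print.cyto_cascade <- function(x, ...) {
  cat(sprintf(
    "<cyto_cascade: Test-1 linear SVM on (mean_all, pct_atypical), n=%d; Test-2 cutoff %.3f (J=%.2f)>\n",
    x$n_train, x$test2$cutoff, x$test2$j))
  invisible(x)
}

#' Predict risk strata with a fitted cascade
#'
#' Test-1 positives are labelled `OSCC_risk` regardless of their Test-2
#' feature. Test-1 negatives with a defined mean atypical score at or above
#' the cutoff are `HGD_risk`; all others (including patients with no
#' atypical cells, whose mean atypical score is undefined) are
#' `LGD_or_benign`. The three strata partition any cohort.
#'
#' @param records Per-patient feature tibble.
#' @param model A [fit_cascade()] object.
#' @return Tibble `patient_id` (if present), `stratum` (factor),
#'   `test1_margin`, `test1_positive`, `mean_atypical`, `test2_evaluated`.
#' @export
cascade_predict <- function(records, model) {
  stopifnot(inherits(model, "cyto_cascade"))
  t1 <- predict_test1(model$test1, records)
  ma <- records$mean_atypical %||% rep(NA_real_, nrow(records))
  test2_eval <- !t1$positive
  test2_pos <- test2_eval & !is.na(ma) & ma >= model$test2$cutoff
  stratum <- ifelse(t1$positive, "OSCC_risk",
                    ifelse(test2_pos, "HGD_risk", "LGD_or_benign"))
  out <- tibble(
    stratum = factor(stratum,
                     levels = c("OSCC_risk", "HGD_risk", "LGD_or_benign")),
    test1_margin = t1$margin,
    test1_positive = t1$positive,
    mean_atypical = ma,
    test2_evaluated = test2_eval
  )
  if (!is.null(records$patient_id)) {
    out <- bind_cols(tibble(patient_id = records$patient_id), out)
  }
  out
}

#' Compare five linear-feature learners on the Test-1 task
#'
#' Fits a linear SVM, random forest, logistic regression, linear
#' discriminant analysis and k-nearest neighbours on the standardised Test-1
#' features (carcinoma vs rest), all with the same split and seed, and
#' reports held-out sensitivity, specificity and accuracy per learner.
#' A learner that fails to fit is recorded with its error message rather
#' than aborting the comparison.
#'
#' @param train,test Per-patient feature tibbles with `class`.
#' @param seed Integer seed (controls the random-forest bootstrap).
#' @param knn_k Neighbours for k-NN (default 5).
#' @return Tibble: `learner`, `sensitivity`, `specificity`, `accuracy`,
#'   `error`.
#' @export
compare_learners <- function(train, test, seed = 1L, knn_k = 5) {
  y_tr <- factor(ifelse(train$class == "OSCC", "OSCC", "other"),
                 levels = c("OSCC", "other"))
  y_te <- factor(ifelse(test$class == "OSCC", "OSCC", "other"),
                 levels = c("OSCC", "other"))
  x_tr <- test1_feature_matrix(train)
  center <- colMeans(x_tr); scale_ <- apply(x_tr, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  std <- function(x) sweep(sweep(x, 2, center), 2, scale_, `/`)
  xs_tr <- std(x_tr); xs_te <- std(test1_feature_matrix(test))

  learners <- list(
    svm_linear = function() {
      fit <- e1071::svm(xs_tr, y_tr, kernel = "linear", cost = 1, scale = FALSE)
      predict(fit, xs_te)
    },
    random_forest = function() {
      withr::with_seed(derive_seed(seed, 2L), {
        fit <- randomForest::randomForest(xs_tr, y_tr, ntree = 500)
        predict(fit, xs_te)
      })
    },
    logistic_regression = function() {
      df_tr <- data.frame(xs_tr, y = y_tr == "OSCC")
      # separable cohorts legitimately drive fitted probabilities to 0/1
      fit <- suppressWarnings(
        glm(y ~ mean_all + pct_atypical, data = df_tr, family = binomial()))
      p <- predict(fit, newdata = data.frame(xs_te), type = "response")
      factor(ifelse(p > 0.5, "OSCC", "other"), levels = levels(y_tr))
    },
    lda = function() {
      fit <- MASS::lda(xs_tr, grouping = y_tr)
      predict(fit, xs_te)$class
    },
    knn = function() {
      withr::with_seed(derive_seed(seed, 5L),
                       class::knn(xs_tr, xs_te, y_tr, k = knn_k))
    }
  )

  rows <- imap(learners, function(f, nm) {
    pred <- tryCatch(f(), error = function(e) e)
    if (inherits(pred, "error")) {
      return(tibble(learner = nm, sensitivity = NA_real_,
                    specificity = NA_real_, accuracy = NA_real_,
                    error = conditionMessage(pred)))
    }
    cc <- count_confusion(y_te == "OSCC", pred == "OSCC")
    tibble(
      learner = nm,
      sensitivity = cc$tp / (cc$tp + cc$fn),
      specificity = cc$tn / (cc$tn + cc$fp),
      accuracy = (cc$tp + cc$tn) / cc$n,
      error = NA_character_
    )
  })
  bind_rows(rows)
}

#' @rdname fit_cascade
#' @param x A `cyto_cascade`.
#' @param ... Unused.
#' @export
tidy.cyto_cascade <- function(x, ...) {
  tibble(
    term = c("mean_all_weight", "pct_atypical_weight", "test1_intercept",
             "test2_cutoff"),
    estimate = c(unname(x$test1$weights["mean_all"]),
                 unname(x$test1$weights["pct_atypical"]),
                 x$test1$intercept, x$test2$cutoff)
  )
}

#' @rdname fit_cascade
#' @export
glance.cyto_cascade <- function(x, ...) {
  tibble(
    n_train = x$n_train,
    test2_cutoff = x$test2$cutoff,
    test2_j = x$test2$j,
    test2_noninformative = x$test2$noninformative,
    seed = x$seed
  )
}
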