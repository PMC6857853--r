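#' Confusion counts for a binary diagnostic test
#'
#' @param tp,fn,tn,fp Non-negative integer counts.
#' @param positive Label describing the positive-class definition.
#' @return An object of class `confusion_counts`.
#' @seealso [count_confusion()] to tally counts from vectors,
#'   [metrics_from_counts()] for the derived metrics.
#' @export
confusion_counts <- function(tp, fn, tn, fp, positive = "positive") {
  for (nm in c("tp", "fn", "tn", "fp")) {
    v <- get(nm)
    check_that(is_scalar_number(v) && v >= 0 && v == round(v),
               nm, "must be a non-negative integer")
  }
  n <- tp + fn + tn + fp
  check_that(n >= 1, "counts", "must total at least 1")
  structure(list(tp = tp, fn = fn, tn = tn, fp = fp, n = n,
                 positive = positive),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param truth,pred Logical vectors (or coercible) of the same length.
#' @export
count_confusion <- function(truth, pred, positive = "positive") {
  truth <- as.logical(truth); pred <- as.logical(pred)
  stopifnot(length(truth) == length(pred), !anyNA(truth), !anyNA(pred))
  confusion_counts(tp = sum(truth & pred), fn = sum(truth & !pred),
                   tn = sum(!truth & !pred), fp = sum(!truth & pred),
                   positive = positive)
}

#' @method print confusion_counts
#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts [%s]: TP=%d FN=%d TN=%d FP=%d (n=%d)>\n",
              x$positive, x$tp, x$fn, x$tn, x$fp, x$n))
  invisible(x)
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity, specificity, accuracy, positive and negative predictive
#' values, each retained as a raw fraction and reported as a percent rounded
#' half-up — integer percents by default, matching the usual diagnostic
#' table style, or one decimal. A metric with a zero denominator is
#' undefined (`NA`), never reported as 0.
#'
#' @param counts A [confusion_counts()].
#' @param rounding `"integer"` (default) or `"one_decimal"`.
#' @return Tibble: `metric`, `numerator`, `denominator`, `fraction`,
#'   `percent`, `percent_rounded`.
#' @export
#' @examples
#' metrics_from_counts(confusion_counts(tp = 14, fn = 1, tn = 13, fp = 2))
metrics_from_counts <- function(counts, rounding = c("integer", "one_decimal")) {
  stopifnot(inherits(counts, "confusion_counts"))
  rounding <- match.arg(rounding)
  digits <- if (rounding == "integer") 0 else 1
  defs <- list(
    sensitivity = c(counts$tp, counts$tp + counts$fn),
    specificity = c(counts$tn, counts$tn + counts$fp),
    accuracy = c(counts$tp + counts$tn, counts$n),
    ppv = c(counts$tp, counts$tp + counts$fp),
    npv = c(counts$tn, counts$tn + counts$fn)
  )
  rows <- imap(defs, function(v, nm) {
    num <- v[1]; den <- v[2]
    frac <- if (den >= 1) num / den else NA_real_
    tibble(metric = nm, numerator = num, denominator = den,
           fraction = frac, percent = 100 * frac,
           percent_rounded = round_half_up(100 * frac, digits))
  })
  out <- bind_rows(rows)
  attr(out, "rounding") <- rounding
  attr(out, "positive") <- counts$positive
  out
}

#' Cohen's kappa for agreement between two raters or tests
#'
#' Unweighted chance-corrected agreement: `kappa = (po - pe) / (1 - pe)`
#' where `po` is the observed and `pe` the chance agreement from the
#' marginals. Accepts either two rating vectors or a pre-tabulated square
#' contingency table. Kappa is symmetric in the raters and invariant to
#' relabelling the categories. When both raters are constant and identical,
#' `pe = 1` and kappa is undefined (flagged, `NA`).
#'
#' @param x Ratings of rater 1, or a square matrix/table.
#' @param y Ratings of rater 2 (when `x` is a vector).
#' @return Object of class `agreement_result`: `kappa`, `po`, `pe`, `n`,
#'   `method`, `undefined` flag.
#' @export
#' @examples
#' cohen_kappa(matrix(c(40, 10, 5, 45), 2))  # kappa = 0.70
cohen_kappa <- function(x, y = NULL) {
  tab <- if (is.null(y)) {
    as.matrix(x)
  } else {
    stopifnot(length(x) == length(y), length(x) >= 1)
    lev <- sort(unique(c(as.character(x), as.character(y))))
    table(factor(as.character(x), levels = lev),
          factor(as.character(y), levels = lev))
  }
  stopifnot(nrow(tab) == ncol(tab), all(tab >= 0))
  n <- sum(tab)
  check_that(n >= 1, "ratings", "need at least one pair")
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  undefined <- abs(1 - pe) < 1e-12
  kappa <- if (undefined) NA_real_ else (po - pe) / (1 - pe)
  structure(list(kappa = kappa, po = po, pe = pe, n = n,
                 method = "cohen_unweighted", undefined = undefined),
            class = "agreement_result")
}

#' @method print agreement_result
#' @export
print.agreement_result <- function(x, ...) {
  if (!is.null(x$kappa)) {
    cat(sprintf("<agreement: kappa=%s (po=%.3f, pe=%.3f, n=%d)%s>\n",
                ifelse(is.na(x$kappa), "undefined", sprintf("%.3f", x$kappa)),
                x$po, x$pe, x$n,
                if (isTRUE(x$undefined)) " [undefined: pe = 1]" else ""))
  } else {
    cat(sprintf("<McNemar %s: p=%.4g (b=%d, c=%d)%s>\n",
                x$method, x$p_value, x$b, x$c,
                if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  }
  invisible(x)
}

#' McNemar's test on discordant pair counts
#'
#' Paired comparison of two classifiers on the same cases, using only the
#' discordant counts `b` and `c`. Small samples (`b + c < 25`) use the exact
#' two-sided binomial test `p = min(1, 2 P(X <= min(b, c)))` with
#' `X ~ Bin(b + c, 1/2)`; otherwise the chi-square statistic with continuity
#' correction `(|b - c| - 1)^2 / (b + c)` on 1 df. `b = c = 0` is degenerate
#' and returns `p = 1` with a flag.
#'
#' @param b,c Non-negative discordant counts.
#' @return Object of class `agreement_result`: `statistic` (`NA` for the
#'   exact test), `p_value`, `method`, `b`, `c`, `degenerate` flag.
#' @export
#' @examples
#' mcnemar_test(10, 0)$p_value  # 2 * 0.5^10
mcnemar_test <- function(b, c) {
  check_that(is_scalar_number(b) && b >= 0 && b == round(b), "b",
             "must be a non-negative integer")
  check_that(is_scalar_number(c) && c >= 0 && c == round(c), "c",
             "must be a non-negative integer")
  n <- b + c
  if (n == 0) {
    out <- list(statistic = NA_real_, p_value = 1, method = "degenerate",
                b = b, c = c, degenerate = TRUE)
  } else if (n < 25) {
    p <- min(1, 2 * pbinom(min(b, c), n, 0.5))
    out <- list(statistic = NA_real_, p_value = p, method = "exact_binomial",
                b = b, c = c, degenerate = FALSE)
  } else {
    stat <- (abs(b - c) - 1)^2 / n
    out <- list(statistic = stat,
                p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                method = "chisq_corrected", b = b, c = c, degenerate = FALSE)
  }
  structure(out, class = "agreement_result")
}

#' Empirical ROC analysis with the Youden operating cutoff
#'
#' Sweeps candidate thresholds (midpoints between adjacent sorted unique
#' scores; a score is called positive when `score >= threshold`), records
#' the full ROC, computes AUC by the trapezoid rule, and selects the cutoff
#' maximising Youden's `J = sensitivity + specificity - 1`, breaking ties
#' toward the lower cutoff (higher sensitivity). AUC is invariant to
#' strictly increasing transforms of the scores.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or coercible) true class, `TRUE` = positive.
#' @return Object of class `cyto_roc`: `points` tibble (`threshold`,
#'   `sensitivity`, `specificity`, `fpr`, `tpr`), `auc`, `youden_cutoff`,
#'   `youden_j`, `noninformative` flag, `n_pos`, `n_neg`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  pos <- scores[labels]; neg <- scores[!labels]
  if (length(pos) == 0 || length(neg) == 0) {
    abort("ROC needs both positive and negative examples")
  }
  u <- sort(unique(scores))
  if (length(u) < 2) abort("no discriminative cutoff: all scores are identical")
  cand <- (u[-length(u)] + u[-1]) / 2
  thresholds <- c(u[1] - 1, cand, u[length(u)] + 1)
  sens <- vapply(thresholds, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(neg < t), numeric(1))
  pts <- tibble(threshold = thresholds, sensitivity = sens,
                specificity = spec, fpr = 1 - spec, tpr = sens)
  ord <- order(pts$fpr, pts$tpr)
  auc <- sum(diff(pts$fpr[ord]) *
               (head(pts$tpr[ord], -1) + tail(pts$tpr[ord], -1)) / 2)
  j_cand <- vapply(cand, function(t) mean(pos >= t) + mean(neg < t) - 1,
                   numeric(1))
  best <- which.max(j_cand)  # first max = lowest cutoff on ties
  structure(
    list(points = pts, auc = auc,
         youden_cutoff = cand[best], youden_j = j_cand[best],
         noninformative = j_cand[best] <= 1e-12,
         n_pos = length(pos), n_neg = length(neg)),
    class = "cyto_roc"
  )
}

#' @method print cyto_roc
#' @export
print.cyto_roc <- function(x, ...) {
  cat(sprintf("<cyto_roc: AUC=%.3f, Youden cutoff=%.4g (J=%.3f), %d pos / %d neg>\n",
              x$auc, x$youden_cutoff, x$youden_j, x$n_pos, x$n_neg))
  invisible(x)
}

#' Group comparison and normality report for a per-patient feature
#'
#' Kruskal-Wallis rank test of the feature across classes, plus a per-group
#' normality check (Kolmogorov-Smirnov against a normal with the group's
#' estimated mean and sd; method-tagged, since estimating the parameters
#' makes the test approximate).
#'
#' @param data Data frame with the feature and grouping columns.
#' @param value,group Column names (strings).
#' @return List: `kruskal` (statistic, df, p_value, method), `normality`
#'   tibble (`group`, `n`, `statistic`, `p_value`, `method`). Groups with
#'   fewer than 2 values get `NA` with a flag.
#' @export
group_tests <- function(data, value, group) {
  stopifnot(value %in% names(data), group %in% names(data))
  v <- data[[value]]; g <- factor(data[[group]])
  keep <- !is.na(v)
  v <- v[keep]; g <- droplevels(g[keep])
  check_that(nlevels(g) >= 2, "group", "need at least 2 groups")
  kw <- kruskal.test(v, g)
  normality <- bind_rows(lapply(levels(g), function(lev) {
    x <- v[g == lev]
    if (length(x) < 2 || sd(x) < 1e-12) {
      return(tibble(group = lev, n = length(x), statistic = NA_real_,
                    p_value = NA_real_, method = "undefined"))
    }
    ks <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    tibble(group = lev, n = length(x), statistic = unname(ks$statistic),
           p_value = ks$p.value, method = "ks_estimated_params")
  }))
  list(
    kruskal = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p_value = kw$p.value,
                   method = "kruskal_wallis"),
    normality = normality
  )
}

#' Pearson correlation between two per-patient features
#'
#' @param data Data frame.
#' @param x,y Column names (strings).
#' @return List: `r`, `p_value`, `n`, `method`.
#' @export
feature_correlation <- function(data, x, y) {
  stopifnot(x %in% names(data), y %in% names(data))
  keep <- complete.cases(data[[x]], data[[y]])
  ct <- stats::cor.test(data[[x]][keep], data[[y]][keep], method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(keep),
       method = "pearson")
}

#' Wilson score interval for a proportion
#'
#' Companion interval for the reported diagnostic fractions (sensitivity,
#' specificity, ...). The Wilson interval behaves well at small n and at
#' proportions near 0 or 1, where the Wald interval collapses.
#'
#' @param x Number of successes.
#' @param n Number of trials (>= 1).
#' @param conf_level Confidence level (default 0.95).
#' @return List: `estimate`, `lower`, `upper`, `conf_level`.
#' @export
#' @examples
#' wilson_ci(14, 15)
wilson_ci <- function(x, n, conf_level = 0.95) {
  check_that(is_scalar_number(n) && n >= 1 && n == round(n), "n",
             "must be a positive integer")
  check_that(is_scalar_number(x) && x >= 0 && x <= n && x == round(x), "x",
             "must be an integer in [0, n]")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- x / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p, lower = max(0, centre - half),
       upper = min(1, centre + half), conf_level = conf_level)
}

#' Manual cytological atypia features
#'
#' The seven binary features a pathologist scores under direct microscopy:
#' multi-nucleation, mitotic figures, prominent nucleoli, altered
#' nuclear-cytoplasmic ratio, hyperchromatic nucleus, irregular nuclear
#' membrane, and abnormal cell shape. The six-feature variant (without
#' abnormal cell shape) is also supported.
#'
#' @param include_abnormal_shape Include the seventh feature (default TRUE).
#' @return Character vector of feature column names.
#' @export
manual_features <- function(include_abnormal_shape = TRUE) {
  c("multi_nucleation", "mitotic_figures", "prominent_nucleoli",
    "altered_nc_ratio", "hyperchromatic_nucleus",
    "irregular_nuclear_membrane",
    if (include_abnormal_shape) "abnormal_cell_shape")
}

#' Manual cytology score
#'
#' Sums the binary per-feature findings into a total cytology score per
#' case (0-7 with the full feature set) and flags cases scoring strictly
#' above 3 as manually positive.
#'
#' @param records Data frame containing the feature columns, all coded 0/1
#'   (or logical) with no missing values.
#' @param features Feature column names (default [manual_features()]).
#' @return Tibble with `score` (integer) and `positive` (score > 3).
#' @export
#' @examples
#' rec <- tibble::as_tibble(setNames(as.list(c(1, 1, 1, 1, 0, 0, 0)),
#'                                   manual_features()))
#' manual_cytology_score(rec)  # score 4, positive
manual_cytology_score <- function(records, features = manual_features()) {
  missing_cols <- setdiff(features, names(records))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing manual feature column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  m <- as.matrix(records[, features])
  storage.mode(m) <- "numeric"
  if (anyNA(m)) abort("manual features must not be missing")
  if (!all(m %in% c(0, 1))) abort("manual features must be binary (0/1)")
  score <- as.integer(rowSums(m))
  tibble(score = score, positive = score > 3)
}
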