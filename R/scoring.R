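#' Assign a score to its reporting bin
#'
#' Atypia scores are reported in five bins: `[0, 0.3)`, `[0.3, 0.5)`,
#' `[0.5, 0.7)`, `[0.7, 0.9)` and `[0.9, 1]` — half-open, closed on the
#' left, with the top bin closed so a perfect 1.0 lands in `">0.9"`.
#'
#' @param score Numeric vector in `[0, 1]`.
#' @return Factor with levels `"<0.3"`, `"0.3-0.5"`, `"0.5-0.7"`,
#'   `"0.7-0.9"`, `">0.9"`.
#' @export
#' @examples
#' assign_bin(c(0.2, 0.4, 0.95, 1.0))
assign_bin <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 1)) {
    abort("scores must lie in [0, 1]")
  }
  labels <- c("<0.3", "0.3-0.5", "0.5-0.7", "0.7-0.9", ">0.9")
  factor(labels[findInterval(score, c(0.3, 0.5, 0.7, 0.9)) + 1L],
         levels = labels)
}

score_bin_levels <- function() c("<0.3", "0.3-0.5", "0.5-0.7", "0.7-0.9", ">0.9")

# Morphometric feature block used by the reference scorer. The boundary
# irregularity is the isoperimetric quotient perimeter^2 / (4 pi area):
# 1 for a circle, larger for lobed outlines. Channel means are rescaled to
# [0, 1]; the nucleus/cell area ratio is invariant to uniform intensity
# rescaling by construction.
roi_features <- function(rois, criteria = qc_criteria()) {
  stopifnot(nrow(rois) > 0)
  irregularity <- map_dbl(rois$mask, function(m) {
    sh <- EBImage::computeFeatures.shape(as_ebi(m * 1))
    per <- sh[1, "s.perimeter"]
    per^2 / (4 * pi * sh[1, "s.area"])
  })
  nucleus_ratio <- if ("nucleus_ratio" %in% names(rois)) {
    rois$nucleus_ratio
  } else {
    map_dbl(seq_len(nrow(rois)), function(i) {
      v <- check_nucleus(rois[i, ], criteria)
      v$nucleus_area_px / rois$area_px[i]
    })
  }
  tibble(
    roi_id = rois$roi_id,
    area_um2 = rois$area_um2,
    aspect = rois$aspect,
    nucleus_ratio = nucleus_ratio,
    irregularity = irregularity,
    mean_r = rois$mean_r / 255,
    mean_g = rois$mean_g / 255,
    mean_b = rois$mean_b / 255
  )
}

#' Train the morphometric reference scorer
#'
#' A per-cell atypia scorer maps a cell ROI to a score in `[0, 1]` (0 most
#' likely normal, 1 most likely atypical). Production deployments of this
#' pipeline plug in a convolutional network behind the same contract; this
#' package ships a trainable desk-scale reference scorer: a ridge-regularised
#' logistic model on morphometric features (area, aspect ratio, nucleus/cell
#' area ratio, boundary irregularity `perimeter^2 / (4 pi area)`, per-channel
#' mean intensities), whose logistic output is the calibrated score.
#' Atypical cells carry enlarged, irregular nuclei, so these features carry
#' the discriminative signal.
#'
#' A stratified hold-out split (default 90/10) reports validation accuracy
#' at the 0.5 rule as training metadata; the returned scorer itself is
#' refitted on all examples. Training is deterministic given the seed.
#'
#' @param rois ROI tibble (QC survivors, with nucleus info).
#' @param labels Logical or factor of per-ROI atypia labels (`TRUE` /
#'   `"atypical"` for atypical); at least 2 examples per class.
#' @param seed Integer seed.
#' @param lambda Ridge penalty (default 0.01).
#' @param validation_fraction Held-out fraction for the reported validation
#'   accuracy (default 0.1).
#' @return An object of class `cyto_scorer` with coefficients,
#'   standardisation constants and training metadata.
#' @export
train_reference_scorer <- function(rois, labels, seed = 1L, lambda = 0.01,
                                   validation_fraction = 0.1) {
  y <- if (is.logical(labels)) labels else labels %in% c("atypical", "TRUE", "1")
  stopifnot(length(y) == nrow(rois))
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    abort("training needs at least 2 examples of each class (normal and atypical)")
  }
  feats <- roi_features(rois)
  x <- as.matrix(feats[, setdiff(names(feats), "roi_id")])
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ < 1e-9] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale_, `/`)

  fit_ridge <- function(xmat, yvec) {
    fit <- glmnet::glmnet(xmat, factor(yvec, levels = c(FALSE, TRUE)),
                          family = "binomial", alpha = 0, lambda = lambda,
                          standardize = FALSE)
    cf <- as.numeric(coef(fit, s = lambda))
    setNames(cf, c("(Intercept)", colnames(xmat)))
  }

  val_acc <- NA_real_
  withr::with_seed(seed, {
    if (validation_fraction > 0) {
      idx_pos <- which(y); idx_neg <- which(!y)
      val <- c(sample(idx_pos, max(1, round(validation_fraction * length(idx_pos)))),
               sample(idx_neg, max(1, round(validation_fraction * length(idx_neg)))))
      tr <- setdiff(seq_along(y), val)
      if (length(unique(y[tr])) == 2) {
        cf <- fit_ridge(xs[tr, , drop = FALSE], y[tr])
        p <- plogis(cf[1] + xs[val, , drop = FALSE] %*% cf[-1])
        val_acc <- mean((p > 0.5) == y[val])
      }
    }
  })
  cf <- fit_ridge(xs, y)

  structure(
    list(kind = "reference_morphometric",
         feature_names = colnames(x),
         center = center, scale = scale_, coef = cf,
         lambda = lambda, seed = as.integer(seed),
         n_normal = sum(!y), n_atypical = sum(y),
         validation_fraction = validation_fraction,
         validation_accuracy = val_acc),
    class = "cyto_scorer"
  )
}

#' @method print cyto_scorer
#' @export
print.cyto_scorer <- function(x, ...) {
  cat(sprintf(
    "<cyto_scorer '%s': %d normal + %d atypical training cells, lambda=%g%s>\n",
    x$kind, x$n_normal, x$n_atypical, x$lambda,
    if (is.na(x$validation_accuracy)) "" else
      sprintf(", validation accuracy %.3f", x$validation_accuracy)))
  invisible(x)
}

scorer_scores <- function(scorer, rois) {
  feats <- roi_features(rois)
  x <- as.matrix(feats[, scorer$feature_names])
  xs <- sweep(sweep(x, 2, scorer$center), 2, scorer$scale, `/`)
  as.numeric(plogis(scorer$coef[1] + xs %*% scorer$coef[-1]))
}

#' Score cells with a pluggable atypia scorer
#'
#' Applies the scorer to each ROI (order-preserving) and fills the atypia
#' flag and reporting bin. Cells scoring strictly above 0.5 are taken as
#' atypical; exactly 0.5 is not atypical. The scorer is either a trained
#' [train_reference_scorer()] object or, for external models honouring the
#' contract, any function `f(rois) -> numeric` returning one score in
#' `[0, 1]` per ROI; out-of-range external scores are rejected with the
#' offending `roi_id` named.
#'
#' @param rois ROI tibble (QC survivors).
#' @param scorer A `cyto_scorer` or a function of the ROI tibble.
#' @return Tibble `roi_id`, `score`, `atypical`, `bin`.
#' @export
score_cells <- function(rois, scorer) {
  if (nrow(rois) == 0) {
    return(tibble(roi_id = character(), score = numeric(),
                  atypical = logical(),
                  bin = factor(character(), levels = score_bin_levels())))
  }
  s <- if (inherits(scorer, "cyto_scorer")) {
    scorer_scores(scorer, rois)
  } else if (is.function(scorer)) {
    scorer(rois)
  } else {
    abort("scorer must be a cyto_scorer or a function returning scores")
  }
  if (length(s) != nrow(rois)) {
    abort("scorer must return exactly one score per ROI")
  }
  bad <- which(is.na(s) | s < 0 | s > 1)
  if (length(bad) > 0) {
    abort(sprintf("scorer returned out-of-range score for %s",
                  paste(rois$roi_id[bad], collapse = ", ")))
  }
  tibble(roi_id = rois$roi_id, score = s, atypical = s > 0.5,
         bin = assign_bin(s))
}
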