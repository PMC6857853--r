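#' Quality-control criteria for segmented cell ROIs
#'
#' Thresholds for the four-stage pass-criteria cascade that removes clumps,
#' shadow artifacts, unstained debris and anucleate fragments before scoring.
#' The checks run in order size/aspect -> shadow -> hematoxylin area ->
#' nucleus, short-circuiting at the first failure. All numeric defaults are
#' implementation choices calibrated to squamous-cell dimensions (20-70 um
#' diameter) at 1.9 px/um and are fully overridable.
#'
#' @param min_area_um2,max_area_um2 Cell area bounds in um^2 (defaults
#'   150-4000); inclusive.
#' @param max_aspect Maximum ellipse-fit aspect ratio (default 3.0,
#'   inclusive).
#' @param max_red_green_ratio Maximum mean-red / mean-green intensity ratio
#'   (default 1.15, inclusive); shadow artifacts are dark red-dominant
#'   patches with ratios well above stained cells.
#' @param min_hematoxylin_fraction Minimum fraction of ROI pixels that look
#'   hematoxylin-stained (blue >= red and luminance below the ROI's Otsu
#'   threshold; default 0.05, inclusive).
#' @param min_nucleus_area_um2 Minimum nuclear particle area in um^2
#'   (default 10) when thresholding the red channel of the crop.
#' @return An object of class `qc_criteria`.
#' @export
qc_criteria <- function(min_area_um2 = 150, max_area_um2 = 4000,
                        max_aspect = 3.0, max_red_green_ratio = 1.15,
                        min_hematoxylin_fraction = 0.05,
                        min_nucleus_area_um2 = 10) {
  check_that(min_area_um2 > 0 && max_area_um2 > min_area_um2,
             "area bounds", "need 0 < min_area_um2 < max_area_um2")
  check_that(max_aspect >= 1, "max_aspect", "must be >= 1")
  check_that(max_red_green_ratio > 0, "max_red_green_ratio", "must be > 0")
  check_that(min_hematoxylin_fraction > 0 && min_hematoxylin_fraction < 1,
             "min_hematoxylin_fraction", "must lie in (0, 1)")
  check_that(min_nucleus_area_um2 > 0, "min_nucleus_area_um2", "must be > 0")
  structure(list(min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 max_aspect = max_aspect,
                 max_red_green_ratio = max_red_green_ratio,
                 min_hematoxylin_fraction = min_hematoxylin_fraction,
                 min_nucleus_area_um2 = min_nucleus_area_um2),
            class = "qc_criteria")
}

roi_as_row <- function(roi) {
  if (is.data.frame(roi)) {
    stopifnot(nrow(roi) == 1)
    as.list(roi)
  } else {
    roi
  }
}

#' Size and aspect-ratio check
#'
#' Passes when the ROI area lies within the configured bounds (inclusive)
#' and the aspect ratio does not exceed the maximum (inclusive). Oversized
#' or extremely elongated components are typically unresolved clumps or
#' smeared debris.
#'
#' @param roi One ROI (single tibble row or list) with `area_um2`, `aspect`.
#' @param criteria A [qc_criteria()].
#' @return List with `pass` (logical) and `value` (c(area_um2, aspect)).
#' @export
check_size_aspect <- function(roi, criteria = qc_criteria()) {
  roi <- roi_as_row(roi)
  if (is.null(roi$area_um2) || is.null(roi$aspect) ||
      is.na(roi$area_um2) || is.na(roi$aspect)) {
    abort("ROI is missing area/aspect geometry")
  }
  pass <- roi$area_um2 >= criteria$min_area_um2 &&
    roi$area_um2 <= criteria$max_area_um2 &&
    roi$aspect <= criteria$max_aspect
  list(pass = pass, value = c(area_um2 = roi$area_um2, aspect = roi$aspect))
}

#' Shadow-artifact check on the red/green intensity ratio
#'
#' Out-of-focus shadows are chromatically flat, dark and red-dominant;
#' stained cytoplasm and nuclei are blue/green-dominant. The ROI passes when
#' mean_red / mean_green does not exceed the threshold (inclusive). A zero
#' mean green intensity is degenerate and fails.
#'
#' @inheritParams check_size_aspect
#' @return List with `pass` and `value` (the ratio; `Inf` when degenerate).
#' @export
check_shadow <- function(roi, criteria = qc_criteria()) {
  roi <- roi_as_row(roi)
  if (is.null(roi$mean_r) || is.null(roi$mean_g)) {
    abort("ROI is missing channel means")
  }
  if (roi$mean_g == 0) {
    return(list(pass = FALSE, value = Inf))
  }
  ratio <- roi$mean_r / roi$mean_g
  list(pass = ratio <= criteria$max_red_green_ratio, value = ratio)
}

# Hematoxylin-like pixels within the ROI mask: blue-dominant AND dark
# relative to the ROI's own Otsu luminance split.
hematoxylin_pixels <- function(crop, mask) {
  r <- crop[, , 1][mask]; g <- crop[, , 2][mask]; b <- crop[, , 3][mask]
  lum <- (r + g + b) / 3
  if (length(lum) == 0) return(logical(0))
  thr <- if (diff(range(lum)) < 5) -Inf else otsu_threshold(lum)
  if (is.na(thr)) thr <- -Inf
  # compare on the histogram-bin scale: otsu_threshold() returns a bin
  # boundary, and luminance can be fractional
  (b >= r) & (floor(lum) < thr)
}

#' Hematoxylin-stained area check
#'
#' Estimates the fraction of ROI pixels that look hematoxylin-stained
#' (blue >= red with luminance below the ROI's Otsu threshold). Unstained
#' debris carries essentially no such signal. Passes when the fraction
#' reaches the configured minimum (inclusive).
#'
#' @inheritParams check_size_aspect
#' @return List with `pass` and `value` (the stained fraction).
#' @export
check_hematoxylin_area <- function(roi, criteria = qc_criteria()) {
  roi <- roi_as_row(roi)
  crop <- roi$crop[[1]] %||% roi$crop
  mask <- roi$mask[[1]] %||% roi$mask
  stained <- hematoxylin_pixels(crop, mask)
  frac <- if (length(stained) == 0) 0 else mean(stained)
  list(pass = frac >= criteria$min_hematoxylin_fraction, value = frac)
}

#' Nucleus-presence check
#'
#' Thresholds the red channel of the ROI crop (nuclei have their strongest
#' contrast in red), runs particle analysis on the dark side, and passes
#' when at least one particle reaches the minimum nuclear area. The largest
#' qualifying particle is returned as the nucleus mask.
#'
#' @inheritParams check_size_aspect
#' @return List with `pass`, `value` (largest particle area in um^2),
#'   `nucleus_mask` (logical matrix within the ROI box, or `NULL`) and
#'   `nucleus_area_px`.
#' @export
check_nucleus <- function(roi, criteria = qc_criteria()) {
  roi <- roi_as_row(roi)
  crop <- roi$crop[[1]] %||% roi$crop
  mask <- roi$mask[[1]] %||% roi$mask
  scale <- roi$pixel_scale %||% 1.9
  red <- crop[, , 1]
  vals <- red[mask]
  fail <- list(pass = FALSE, value = 0, nucleus_mask = NULL,
               nucleus_area_px = 0)
  if (length(vals) == 0 || diff(range(vals)) < 10) return(fail)
  thr <- otsu_threshold(vals)
  cand <- mask & red < thr
  if (!any(cand)) return(fail)
  lab <- label_mask(cand)
  sizes <- tabulate(lab[lab > 0])
  min_px <- criteria$min_nucleus_area_um2 * scale^2
  if (max(sizes) < min_px) {
    return(list(pass = FALSE, value = max(sizes) / scale^2,
                nucleus_mask = NULL, nucleus_area_px = 0))
  }
  largest <- which.max(sizes)
  list(pass = TRUE, value = max(sizes) / scale^2,
       nucleus_mask = lab == largest, nucleus_area_px = max(sizes))
}

#' Apply the four-stage QC cascade to segmented ROIs
#'
#' Runs size/aspect, shadow, hematoxylin-area and nucleus checks in that
#' order, short-circuiting at the first failure, and tallies failures per
#' check. Verdicts are pure functions of (ROI, criteria); re-applying QC to
#' its own survivors changes nothing.
#'
#' @param rois ROI tibble from [extract_cell_rois()] / [segment_field()].
#' @param criteria A [qc_criteria()].
#' @return List with `rois` (passing ROIs, augmented with `nucleus_mask`,
#'   `nucleus_area_px` and `nucleus_ratio`), `results` (per-ROI verdict
#'   tibble: four check columns, `pass`, `failure_reason`; checks not reached
#'   are `NA`) and `tally` (named counts failed per check plus `passed`).
#' @export
apply_qc <- function(rois, criteria = qc_criteria()) {
  checks <- c("size_aspect", "shadow", "hematoxylin_area", "nucleus")
  n <- nrow(rois)
  res <- tibble(
    roi_id = rois$roi_id,
    size_aspect = rep(NA, n), shadow = rep(NA, n),
    hematoxylin_area = rep(NA, n), nucleus = rep(NA, n),
    pass = rep(FALSE, n), failure_reason = rep(NA_character_, n)
  )
  nucleus_masks <- vector("list", n)
  nucleus_area <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    roi <- rois[i, ]
    verdicts <- list(
      size_aspect = function() check_size_aspect(roi, criteria),
      shadow = function() check_shadow(roi, criteria),
      hematoxylin_area = function() check_hematoxylin_area(roi, criteria),
      nucleus = function() check_nucleus(roi, criteria)
    )
    ok <- TRUE
    for (chk in checks) {
      v <- verdicts[[chk]]()
      res[[chk]][i] <- v$pass
      if (chk == "nucleus" && v$pass) {
        nucleus_masks[[i]] <- v$nucleus_mask
        nucleus_area[i] <- v$nucleus_area_px
      }
      if (!v$pass) {
        res$failure_reason[i] <- chk
        ok <- FALSE
        break
      }
    }
    res$pass[i] <- ok
  }
  tally <- c(
    vapply(checks,
           function(chk) sum(res$failure_reason == chk, na.rm = TRUE),
           integer(1)),
    passed = sum(res$pass)
  )
  passing <- rois[res$pass, , drop = FALSE]
  if (nrow(passing) > 0) {
    keep <- which(res$pass)
    passing$nucleus_mask <- nucleus_masks[keep]
    passing$nucleus_area_px <- nucleus_area[keep]
    passing$nucleus_ratio <- nucleus_area[keep] / passing$area_px
  } else {
    passing$nucleus_mask <- list()
    passing$nucleus_area_px <- numeric(0)
    passing$nucleus_ratio <- numeric(0)
  }
  list(rois = passing, results = res, tally = tally)
}
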