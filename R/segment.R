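#' Threshold the cellular mass in the green channel
#'
#' Stained cell mass has its highest contrast against the illuminated
#' background in the green channel, so the foreground mask is obtained by
#' Otsu-thresholding the green channel and keeping the *dark* side. When the
#' image carries FOV metadata (after [trim_to_fov()]), only pixels at least
#' 2 px inside the circle enter the threshold estimate and the mask, so the
#' dark surround and rim blend never contaminate either.
#'
#' @param image A [field_image()], ideally trimmed to its FOV.
#' @return Logical `H x W` mask (attribute `stage = "thresholded"`), `TRUE`
#'   on cell mass. A field with no discernible foreground (near-uniform FOV)
#'   yields an empty mask with a warning.
#' @export
threshold_cell_mass <- function(image) {
  stopifnot(inherits(image, "field_image"))
  g <- image$pixels[, , 2]
  if (!is.null(image$fov)) {
    fov <- image$fov
    dist <- sqrt(outer((seq_len(nrow(g)) - fov$cy)^2,
                       (seq_len(ncol(g)) - fov$cx)^2, `+`))
    inside <- dist <= fov$radius - 2
  } else {
    inside <- matrix(TRUE, nrow(g), ncol(g))
  }
  vals <- g[inside]
  empty <- length(vals) == 0 || diff(range(vals)) < 10
  if (!empty) {
    thr <- otsu_threshold(vals)
    # contrast gate: on a cell-free field Otsu just splits the noise around
    # its mean; require a real gap between the two side means
    mu_low <- mean(vals[vals < thr])
    mu_high <- mean(vals[vals >= thr])
    empty <- !is.finite(mu_low) || !is.finite(mu_high) ||
      (mu_high - mu_low) < 25
  }
  if (empty) {
    warn("no cellular mass detected: field is near-uniform; returning empty mask")
    mask <- matrix(FALSE, nrow(g), ncol(g))
  } else {
    mask <- inside & g < thr
  }
  attr(mask, "stage") <- "thresholded"
  mask
}

#' Clear the background outside high-level regions of interest
#'
#' Builds high-level ROIs by removing speck components below a minimum area
#' and dilating what remains; image pixels outside the union of high-level
#' ROIs are set to background (0), so later per-cell crops contain no stray
#' debris signal.
#'
#' @param mask Logical foreground mask from [threshold_cell_mass()].
#' @param image The matching [field_image()].
#' @param speck_area_px Minimum component area kept, in px^2 (default 25).
#' @param dilate_radius High-level ROI dilation radius in px (default 5).
#' @return List with the cleaned `mask` (attribute `stage =
#'   "background_cleared"`) and the background-cleared `image`.
#' @export
clear_background <- function(mask, image, speck_area_px = 25, dilate_radius = 5) {
  stopifnot(all(dim(mask) == dim(image$pixels)[1:2]))
  cleaned <- mask
  if (any(mask)) {
    lab <- label_mask(mask)
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < speck_area_px)
    if (length(drop) > 0) cleaned[matrix(lab %in% drop, nrow(lab))] <- FALSE
    # fill interior holes (bright noise specks inside cytoplasm) so the
    # distance transform of each component has a clean ridge
    cleaned <- from_ebi(EBImage::fillHull(as_ebi(cleaned * 1))) > 0
  }
  px <- image$pixels
  if (any(cleaned)) {
    brush <- EBImage::makeBrush(2 * dilate_radius + 1, shape = "disc")
    roi <- from_ebi(EBImage::dilate(as_ebi(cleaned * 1), brush)) > 0
  } else {
    roi <- cleaned
  }
  for (k in 1:3) {
    ch <- px[, , k]
    ch[!roi] <- 0
    px[, , k] <- ch
  }
  attr(cleaned, "stage") <- "background_cleared"
  out_img <- field_image(px, pixel_scale = image$pixel_scale,
                         source_id = image$source_id, fov = image$fov)
  out_img$crop_origin <- image$crop_origin
  list(mask = cleaned, image = out_img)
}

#' Split touching cells with a distance-transform watershed
#'
#' Clumped cells appear as single connected components; the Euclidean
#' distance transform of the mask has one peak per constituent cell, and
#' flooding it with a watershed assigns each pixel to its nearest peak.
#' Peaks are detected within a neighbourhood of half the configured minimum
#' separation (default 10 um converted to pixels), so mild boundary
#' irregularity does not over-split single cells. One-pixel ridges between
#' adjacent labels are erased so the returned binary mask keeps the split
#' components disconnected under 8-connectivity.
#'
#' @param mask Logical foreground mask.
#' @param min_separation_px Minimum peak separation in pixels (default 19,
#'   i.e. 10 um at 1.9 px/um).
#' @return Logical mask (attribute `stage = "watershed"`); the component
#'   count never decreases and no foreground is created.
#' @export
split_clumps <- function(mask, min_separation_px = 19) {
  if (!any(mask)) {
    attr(mask, "stage") <- "watershed"
    return(mask)
  }
  dm <- EBImage::distmap(as_ebi(mask * 1))
  # tolerance 2 merges sub-pixel ridge fluctuations; clump saddles
  # (~0.3 cell radius at 1.5-radii overlap) are far deeper and stay split
  lab <- from_ebi(EBImage::watershed(dm, tolerance = 2,
                                     ext = max(1L, round(min_separation_px / 2))))
  storage.mode(lab) <- "integer"
  out <- lab > 0 & !ridge_pixels(lab)
  attr(out, "stage") <- "watershed"
  out
}

# Pixels whose 8-neighbourhood contains a different positive label.
ridge_pixels <- function(lab) {
  H <- nrow(lab); W <- ncol(lab)
  ridge <- matrix(FALSE, H, W)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  for (s in shifts) {
    dy <- s[1]; dx <- s[2]
    ys <- seq_len(H); xs <- seq_len(W)
    ys_src <- ys + dy; xs_src <- xs + dx
    keep_y <- ys_src >= 1 & ys_src <= H
    keep_x <- xs_src >= 1 & xs_src <= W
    a <- lab[ys[keep_y], xs[keep_x], drop = FALSE]
    b <- lab[ys_src[keep_y], xs_src[keep_x], drop = FALSE]
    conflict <- a > 0 & b > 0 & a != b
    ridge[ys[keep_y], xs[keep_x]] <- ridge[ys[keep_y], xs[keep_x]] | conflict
  }
  ridge
}

#' Extract per-cell regions of interest from a segmented mask
#'
#' Runs particle analysis on the (post-watershed) mask: one ROI per connected
#' component, with bounding box, pixel/physical area, centroid, ellipse-fit
#' axes and aspect ratio (from second moments of the pixel coordinates, with
#' the 1/12 px^2 pixel-extent correction), and per-channel mean intensities
#' over the component. ROI ids are assigned in `(y0, x0)` bounding-box order.
#'
#' @param mask Logical mask.
#' @param image The matching [field_image()].
#' @return A tibble with one row per ROI: `roi_id`, bounding box
#'   (`x0, y0, x1, y1`, 1-based inclusive), centroid, areas, axes, aspect,
#'   channel means, `pixel_scale`, and list-columns `mask` (component mask
#'   within the box) and `crop` (RGB crop within the box).
#' @export
extract_cell_rois <- function(mask, image) {
  stopifnot(all(dim(mask) == dim(image$pixels)[1:2]))
  lab <- label_mask(mask)
  n_comp <- max(lab)
  if (n_comp == 0) return(empty_roi_tibble())
  H <- nrow(lab)
  idx <- which(lab > 0)
  by_comp <- unname(split(idx, lab[idx]))
  px <- image$pixels
  rows <- map(by_comp, function(ii) {
    ys <- (ii - 1L) %% H + 1L
    xs <- (ii - 1L) %/% H + 1L
    x0 <- min(xs); x1 <- max(xs); y0 <- min(ys); y1 <- max(ys)
    area <- length(ii)
    # second-moment ellipse with pixel-extent correction
    vx <- var_pop(xs) + 1 / 12
    vy <- var_pop(ys) + 1 / 12
    vxy <- cov_pop(xs, ys)
    tr <- vx + vy
    det_ <- vx * vy - vxy^2
    disc <- sqrt(max(tr^2 / 4 - det_, 0))
    l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-9)
    submask <- matrix(FALSE, y1 - y0 + 1, x1 - x0 + 1)
    submask[cbind(ys - y0 + 1L, xs - x0 + 1L)] <- TRUE
    crop <- px[y0:y1, x0:x1, , drop = FALSE]
    list(
      x0 = x0, y0 = y0, x1 = x1, y1 = y1,
      cx = mean(xs), cy = mean(ys),
      area_px = area, area_um2 = area / image$pixel_scale^2,
      major_px = 4 * sqrt(l1), minor_px = 4 * sqrt(l2),
      aspect = sqrt(l1 / l2),
      mean_r = mean(px[ii]), mean_g = mean(px[ii + H * ncol(lab)]),
      mean_b = mean(px[ii + 2L * H * ncol(lab)]),
      mask = submask, crop = crop
    )
  })
  out <- tibble(
    x0 = map_dbl(rows, "x0"), y0 = map_dbl(rows, "y0"),
    x1 = map_dbl(rows, "x1"), y1 = map_dbl(rows, "y1"),
    cx = map_dbl(rows, "cx"), cy = map_dbl(rows, "cy"),
    area_px = map_dbl(rows, "area_px"), area_um2 = map_dbl(rows, "area_um2"),
    major_px = map_dbl(rows, "major_px"), minor_px = map_dbl(rows, "minor_px"),
    aspect = map_dbl(rows, "aspect"),
    mean_r = map_dbl(rows, "mean_r"), mean_g = map_dbl(rows, "mean_g"),
    mean_b = map_dbl(rows, "mean_b"),
    pixel_scale = image$pixel_scale,
    mask = map(rows, "mask"), crop = map(rows, "crop")
  )
  out <- arrange(out, y0, x0)
  out$roi_id <- sprintf("roi_%04d", seq_len(nrow(out)))
  select(out, "roi_id", dplyr::everything())
}

var_pop <- function(x) mean((x - mean(x))^2)
cov_pop <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

empty_roi_tibble <- function() {
  tibble(roi_id = character(), x0 = numeric(), y0 = numeric(),
         x1 = numeric(), y1 = numeric(), cx = numeric(), cy = numeric(),
         area_px = numeric(), area_um2 = numeric(),
         major_px = numeric(), minor_px = numeric(), aspect = numeric(),
         mean_r = numeric(), mean_g = numeric(), mean_b = numeric(),
         pixel_scale = numeric(), mask = list(), crop = list())
}

#' Segmentation parameters
#'
#' @param speck_area_px Minimum foreground component kept (px^2).
#' @param dilate_radius High-level ROI dilation radius (px).
#' @param min_separation_um Minimum watershed peak separation (um).
#' @return A named list of parameters for [segment_field()].
#' @export
segment_params <- function(speck_area_px = 25, dilate_radius = 5,
                           min_separation_um = 10) {
  list(speck_area_px = speck_area_px, dilate_radius = dilate_radius,
       min_separation_um = min_separation_um)
}

#' Segment a raw field image into cell ROIs
#'
#' Full pre-processing flow: locate three FOV edge pixels, fit their
#' circumcircle, trim to the circle, Otsu-threshold the green channel, clear
#' the background and drop specks, split clumps with a distance-transform
#' watershed, and extract per-cell ROIs. ROI coordinates are reported in the
#' original (untrimmed) frame. Per-stage object counts are attached as
#' attribute `stage_counts`; stage failures are re-signalled with the stage
#' name.
#'
#' @param image A raw [field_image()].
#' @param params A [segment_params()] list.
#' @return ROI tibble as from [extract_cell_rois()], plus the fitted FOV as
#'   attribute `fov` (in original-frame coordinates).
#' @export
segment_field <- function(image, params = segment_params()) {
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            parent = e)
    })
  }
  pts <- run_stage("fov_edge_points", find_fov_edge_points(image))
  fov <- run_stage("circumcircle",
                   circumcircle(pts[1, ], pts[2, ], pts[3, ]))
  trimmed <- run_stage("trim", {
    tr <- trim_to_fov(image, fov)
    tr$crop_origin <- c(x = max(1, floor(fov$cx - fov$radius)),
                        y = max(1, floor(fov$cy - fov$radius)))
    tr
  })
  mask <- run_stage("threshold", threshold_cell_mass(trimmed))
  cleared <- run_stage("clear_background",
                       clear_background(mask, trimmed,
                                        speck_area_px = params$speck_area_px,
                                        dilate_radius = params$dilate_radius))
  min_sep <- max(3, round(params$min_separation_um * image$pixel_scale))
  split <- run_stage("watershed", split_clumps(cleared$mask, min_sep))
  rois <- run_stage("extract_rois", extract_cell_rois(split, cleared$image))

  # translate back to the original frame
  if (nrow(rois) > 0) {
    ox <- trimmed$crop_origin["x"] - 1; oy <- trimmed$crop_origin["y"] - 1
    rois <- mutate(rois,
                   x0 = .data$x0 + ox, x1 = .data$x1 + ox,
                   cx = .data$cx + ox,
                   y0 = .data$y0 + oy, y1 = .data$y1 + oy,
                   cy = .data$cy + oy)
  }
  attr(rois, "fov") <- fov
  attr(rois, "stage_counts") <- c(
    threshold_components = max(label_mask(mask)),
    cleared_components = max(label_mask(cleared$mask)),
    watershed_components = max(label_mask(split)),
    rois = nrow(rois)
  )
  rois
}

#' Match segmented ROIs to ground-truth cells
#'
#' Greedy one-to-one matching of ROI centroids to ground-truth cell
#' centroids, nearest pair first, up to a maximum distance. Used by the
#' segmentation validation suite to compute recall (matched truth cells /
#' truth cells) and precision (matched ROIs / ROIs).
#'
#' @param rois ROI tibble ([segment_field()] output, original-frame coords).
#' @param truth A `field_truth` (from [generate_field_image()]).
#' @param max_dist Maximum centroid distance in px for a match (default 10).
#' @return List with `matches` tibble (`cell_id`, `roi_id`, `dist`),
#'   `recall`, `precision`, `n_truth`, `n_rois`.
#' @export
match_rois_to_truth <- function(rois, truth, max_dist = 10) {
  n_truth <- nrow(truth$cells); n_rois <- nrow(rois)
  if (n_truth == 0 || n_rois == 0) {
    return(list(matches = tibble(cell_id = numeric(), roi_id = character(),
                                 dist = numeric()),
                recall = if (n_truth == 0) NA_real_ else 0,
                precision = if (n_rois == 0) NA_real_ else 0,
                n_truth = n_truth, n_rois = n_rois))
  }
  d <- outer(truth$cells$cy, rois$cy, `-`)^2 + outer(truth$cells$cx, rois$cx, `-`)^2
  d <- sqrt(d)
  matches <- list()
  repeat {
    m <- which.min(d)
    if (!length(m) || !is.finite(d[m]) || d[m] > max_dist) break
    i <- (m - 1) %% nrow(d) + 1
    j <- (m - 1) %/% nrow(d) + 1
    matches[[length(matches) + 1]] <- tibble(
      cell_id = truth$cells$cell_id[i], roi_id = rois$roi_id[j], dist = d[m])
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  matches <- if (length(matches)) bind_rows(matches) else
    tibble(cell_id = numeric(), roi_id = character(), dist = numeric())
  list(matches = matches,
       recall = nrow(matches) / n_truth,
       precision = nrow(matches) / n_rois,
       n_truth = n_truth, n_rois = n_rois)
}
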