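# Shared fixtures: everything is generated in code at test time.

# A reduced field that renders in a fraction of a second: 640 x 480 at
# 1 px/um so default QC criteria still apply to the cell sizes.
small_scene <- function(n_cells = 6, seed = 1L, ...) {
  scene_spec(image_width = 640, image_height = 480,
             fov_radius = 215, pixel_scale = 1,
             n_cells = n_cells, seed = seed, ...)
}

# Uniform-colour RGB crop (0-255), h x w.
uniform_crop <- function(color, h = 20, w = 20) {
  arr <- array(0, dim = c(h, w, 3))
  for (k in 1:3) arr[, , k] <- color[k]
  arr
}

# Minimal ROI record (one-row tibble) for QC unit checks.
fake_roi <- function(area_um2 = 500, aspect = 1.4, mean_r = 110, mean_g = 120,
                     mean_b = 180, crop = uniform_crop(c(110, 120, 180)),
                     mask = matrix(TRUE, dim(crop)[1], dim(crop)[2]),
                     pixel_scale = 1, roi_id = "roi_0001") {
  tibble::tibble(roi_id = roi_id, area_um2 = area_um2, aspect = aspect,
                 area_px = sum(mask), mean_r = mean_r, mean_g = mean_g,
                 mean_b = mean_b, pixel_scale = pixel_scale,
                 mask = list(mask), crop = list(crop))
}

# A fake ROI that passes all four QC checks: stained-cell channel means,
# a dark blue-dominant nucleus particle inside the crop.
good_rois <- function(roi_id = "roi_good") {
  h <- 30; w <- 30
  crop <- uniform_crop(c(115, 130, 185), h, w)
  crop[12:19, 12:19, 1] <- 65
  crop[12:19, 12:19, 2] <- 80
  crop[12:19, 12:19, 3] <- 140
  fake_roi(area_um2 = 600, aspect = 1.3, mean_r = 110, mean_g = 122,
           mean_b = 180, crop = crop, mask = matrix(TRUE, h, w),
           roi_id = roi_id)
}

# Binary mask with filled discs at the given centres.
disc_mask <- function(h, w, centers, r) {
  m <- matrix(FALSE, h, w)
  for (c0 in centers) {
    d <- sqrt(outer((seq_len(h) - c0[1])^2, (seq_len(w) - c0[2])^2, `+`))
    m <- m | (d <= r)
  }
  m
}

# Plain field_image wrapper around a constant-background array with
# optional dark discs (for thresholding fixtures).
disc_field <- function(h = 200, w = 200, bg = 210, centers = list(),
                       r = 30, fg = 80, pixel_scale = 1) {
  px <- array(bg, dim = c(h, w, 3))
  if (length(centers) > 0) {
    m <- disc_mask(h, w, centers, r)
    for (k in 1:3) {
      ch <- px[, , k]
      ch[m] <- fg
      px[, , k] <- ch
    }
  }
  field_image(px, pixel_scale = pixel_scale, source_id = "fixture")
}

# Segment several mixed fields and return QC-passing ROIs joined with their
# ground-truth atypia labels (for scorer training tests).
labelled_qc_rois <- function(n_fields = 8, n_cells = 12, p_atypical = 0.5,
                             seed_base = 100) {
  out <- list()
  for (s in seq_len(n_fields)) {
    f <- generate_field_image(small_scene(n_cells = n_cells,
                                          p_atypical = p_atypical,
                                          seed = seed_base + s))
    rois <- segment_field(f$image)
    q <- apply_qc(rois)
    if (nrow(q$rois) == 0) next
    m <- match_rois_to_truth(q$rois, f$truth)
    if (nrow(m$matches) == 0) next
    truth <- f$truth$cells[match(m$matches$cell_id, f$truth$cells$cell_id), ]
    rr <- q$rois[match(m$matches$roi_id, q$rois$roi_id), ]
    rr$truth_atypical <- truth$atypical
    out[[length(out) + 1]] <- rr
  }
  dplyr::bind_rows(out)
}

# Per-patient feature tibble with perfectly separable (but not collinear)
# Test-1 features.
separable_cohort <- function(n_per_class = 8) {
  classes <- c("BNG", "LGD", "HGD", "OSCC")
  n <- 4 * n_per_class
  withr::with_seed(202, {
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      class = rep(classes, each = n_per_class),
      mean_all = rep(c(0.10, 0.15, 0.20, 0.60), each = n_per_class) +
        runif(n, 0, 0.02),
      pct_atypical = rep(c(5, 10, 15, 70), each = n_per_class) +
        runif(n, 0, 3),
      mean_atypical = rep(c(0.55, 0.60, 0.85, 0.90), each = n_per_class) +
        runif(n, 0, 0.01)
    )
  })
}
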