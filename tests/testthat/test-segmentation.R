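test_that("green-channel threshold recovers a dark disc's area", {
  f <- disc_field(h = 200, w = 200, centers = list(c(100, 100)), r = 30)
  mask <- threshold_cell_mass(f)
  lab <- oralcyto:::label_mask(mask)
  expect_equal(max(lab), 1)
  expect_lt(abs(sum(mask) - pi * 30^2) / (pi * 30^2), 0.1)
})

test_that("threshold uses only the green channel and handles uniform fields", {
  f <- disc_field(h = 120, w = 120, centers = list(c(60, 60)), r = 20)
  mask <- threshold_cell_mass(f)
  # permute red and blue: the mask must be unchanged
  swapped <- f
  swapped$pixels <- f$pixels[, , c(3, 2, 1)]
  expect_identical(as.vector(threshold_cell_mass(swapped)),
                   as.vector(mask))
  uni <- disc_field(h = 80, w = 80)
  expect_warning(m2 <- threshold_cell_mass(uni), "near-uniform")
  expect_false(any(m2))
})

test_that("clear_background removes specks and zeroes non-ROI pixels", {
  f <- disc_field(h = 150, w = 150, centers = list(c(75, 75)), r = 25)
  mask <- disc_mask(150, 150, list(c(75, 75)), 25)
  mask[10, 10] <- mask[10, 11] <- mask[11, 10] <- mask[11, 11] <- TRUE # 4 px speck
  out <- clear_background(mask, f)
  expect_false(out$mask[10, 10])          # speck below 25 px^2 removed
  expect_true(out$mask[75, 75])
  expect_equal(out$image$pixels[140, 140, 1], 0)  # far background zeroed
  expect_gt(out$image$pixels[75, 75, 1], 0)
  # empty mask -> fully background image
  empty <- clear_background(matrix(FALSE, 150, 150), f)
  expect_true(all(empty$image$pixels == 0))
})

test_that("watershed splits touching discs and leaves singles alone", {
  clump <- disc_mask(160, 220, list(c(80, 80), c(80, 125)), 30) # 1.5 r apart
  out <- split_clumps(clump, min_separation_px = 19)
  expect_equal(max(oralcyto:::label_mask(out)), 2)
  singles <- disc_mask(200, 200, list(c(50, 50), c(150, 150)), 25)
  out2 <- split_clumps(singles, min_separation_px = 19)
  expect_equal(max(oralcyto:::label_mask(out2)), 2)
  empty <- split_clumps(matrix(FALSE, 40, 40))
  expect_false(any(empty))
})

test_that("watershed never loses components nor creates foreground", {
  withr::with_seed(31, {
    for (i in 1:5) {
      n <- sample(1:4, 1)
      ctrs <- replicate(n, c(sample(30:170, 1), sample(30:170, 1)),
                        simplify = FALSE)
      m <- disc_mask(200, 200, ctrs, sample(12:30, 1))
      before <- max(oralcyto:::label_mask(m))
      out <- split_clumps(m, min_separation_px = 10)
      expect_gte(max(oralcyto:::label_mask(out)), before)
      expect_true(all(m[out]))   # no pixels invented outside the input
    }
  })
})

test_that("particle analysis reports geometry and a stable ROI order", {
  m <- matrix(FALSE, 100, 120)
  m[10:19, 10:29] <- TRUE     # 10 x 20 rectangle -> aspect ~ 2
  m[50:59, 15:24] <- TRUE     # square
  m[12:17, 80:85] <- TRUE     # small square, same band as first
  f <- field_image(array(100, dim = c(100, 120, 3)), pixel_scale = 1)
  rois <- extract_cell_rois(m, f)
  expect_equal(nrow(rois), 3)
  expect_identical(rois$roi_id, sprintf("roi_%04d", 1:3))
  expect_true(all(diff(rois$y0) >= 0))          # (y0, x0) ordering
  expect_lt(abs(rois$aspect[1] - 2) / 2, 0.05)  # ellipse-axes oracle
  expect_equal(rois$area_px[1], 200)
  expect_equal(nrow(extract_cell_rois(matrix(FALSE, 10, 10),
                                      disc_field(h = 10, w = 10))), 0)
})

test_that("segment_field finds every well-separated cell within 5 px", {
  spec <- small_scene(n_cells = 8, seed = 19)
  f <- generate_field_image(spec)
  rois <- segment_field(f$image)
  expect_equal(nrow(rois), 8)
  m <- match_rois_to_truth(rois, f$truth, max_dist = 5)
  expect_equal(nrow(m$matches), 8)
  expect_true(all(m$matches$dist <= 5))
  counts <- attr(rois, "stage_counts")
  expect_true(all(c("threshold_components", "watershed_components", "rois")
                  %in% names(counts)))
})

test_that("an empty field yields zero ROIs", {
  f <- generate_field_image(small_scene(n_cells = 0, seed = 2))
  rois <- suppressWarnings(segment_field(f$image))
  expect_equal(nrow(rois), 0)
})

test_that("every emitted ROI lies inside the fitted FOV circle", {
  f <- generate_field_image(small_scene(n_cells = 6, seed = 23))
  rois <- segment_field(f$image)
  fov <- attr(rois, "fov")
  for (i in seq_len(nrow(rois))) {
    m <- rois$mask[[i]]
    ys <- row(m)[m] + rois$y0[i] - 1
    xs <- col(m)[m] + rois$x0[i] - 1
    expect_true(all(sqrt((xs - fov$cx)^2 + (ys - fov$cy)^2) <=
                      fov$radius + 1))
  }
})
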