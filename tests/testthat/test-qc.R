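test_that("size/aspect check enforces inclusive bounds", {
  expect_true(check_size_aspect(fake_roi(area_um2 = 500, aspect = 1.4))$pass)
  expect_false(check_size_aspect(fake_roi(area_um2 = 9000))$pass)  # clump-sized
  expect_false(check_size_aspect(fake_roi(area_um2 = 100))$pass)   # debris-sized
  expect_true(check_size_aspect(fake_roi(aspect = 3.0))$pass)      # inclusive
  expect_false(check_size_aspect(fake_roi(aspect = 3.0001))$pass)
  bad <- fake_roi(); bad$area_um2 <- NA_real_
  expect_error(check_size_aspect(bad), "geometry")
})

test_that("shadow check compares the red/green mean ratio", {
  gray <- check_shadow(fake_roi(mean_r = 80, mean_g = 80))
  expect_equal(gray$value, 1.0)
  expect_true(gray$pass)                       # 1.0 <= default 1.15
  red <- check_shadow(fake_roi(mean_r = 120, mean_g = 60))
  expect_equal(red$value, 2.0)
  expect_false(red$pass)
  edge <- check_shadow(fake_roi(mean_r = 115, mean_g = 100))
  expect_true(edge$pass)                       # exactly at 1.15, inclusive
  degen <- check_shadow(fake_roi(mean_g = 0))
  expect_false(degen$pass)
})

test_that("hematoxylin-area check measures the stained fraction", {
  h <- 10; w <- 10
  crop <- uniform_crop(c(200, 200, 190), h, w)  # blue < red: unstained
  # 5 of 100 pixels dark and blue-dominant
  for (i in 1:5) crop[1, i, ] <- c(50, 50, 100)
  v <- check_hematoxylin_area(fake_roi(crop = crop,
                                       mask = matrix(TRUE, h, w)))
  expect_equal(v$value, 0.05)
  expect_true(v$pass)                           # inclusive at the threshold
  white <- check_hematoxylin_area(fake_roi(crop = uniform_crop(c(255, 255, 255))))
  expect_equal(white$value, 0)
  expect_false(white$pass)
})

test_that("nucleus check runs particle analysis on the red channel", {
  h <- 30; w <- 30
  crop <- uniform_crop(c(120, 130, 180), h, w)
  crop[10:19, 10:19, 1] <- 60   # one 100 px^2 dark-red particle
  crop[10:19, 10:19, 3] <- 140
  v <- check_nucleus(fake_roi(crop = crop, mask = matrix(TRUE, h, w)))
  expect_true(v$pass)
  expect_equal(v$nucleus_area_px, 100)
  # anucleate fragment: flat red channel
  flat <- check_nucleus(fake_roi(crop = uniform_crop(c(120, 130, 180), h, w),
                                 mask = matrix(TRUE, h, w)))
  expect_false(flat$pass)
  # two particles: pass, largest stored
  crop2 <- uniform_crop(c(120, 130, 180), h, w)
  crop2[3:8, 3:8, 1] <- 60       # 36 px^2
  crop2[15:24, 15:24, 1] <- 60   # 100 px^2
  v2 <- check_nucleus(fake_roi(crop = crop2, mask = matrix(TRUE, h, w)))
  expect_true(v2$pass)
  expect_equal(v2$nucleus_area_px, 100)
})

test_that("detected nuclei overlap the generator's ground truth", {
  f <- generate_field_image(small_scene(n_cells = 4, seed = 33))
  rois <- segment_field(f$image)
  q <- apply_qc(rois)
  m <- match_rois_to_truth(q$rois, f$truth)
  expect_gte(nrow(m$matches), 3)
  for (k in seq_len(nrow(m$matches))) {
    i <- match(m$matches$roi_id[k], q$rois$roi_id)
    j <- match(m$matches$cell_id[k], f$truth$cells$cell_id)
    # project both nucleus masks into field coordinates and compare
    nm <- q$rois$nucleus_mask[[i]]
    roi_pix <- cbind(row(nm)[nm] + q$rois$y0[i] - 1,
                     col(nm)[nm] + q$rois$x0[i] - 1)
    tb <- f$truth$cells$nucleus_bbox[[j]]
    tm <- f$truth$cells$nucleus_mask[[j]]
    tru_pix <- cbind(row(tm)[tm] + tb["y0"] - 1, col(tm)[tm] + tb["x0"] - 1)
    a <- paste(roi_pix[, 1], roi_pix[, 2])
    b <- paste(tru_pix[, 1], tru_pix[, 2])
    iou <- length(intersect(a, b)) / length(union(a, b))
    expect_gte(iou, 0.5)
  }
})

test_that("the QC cascade short-circuits in order and tallies failures", {
  rois <- dplyr::bind_rows(
    fake_roi(area_um2 = 9000, roi_id = "r01"),              # size
    fake_roi(area_um2 = 8000, roi_id = "r02"),              # size
    fake_roi(aspect = 5, mean_r = 150, mean_g = 60, roi_id = "r03"), # size first
    fake_roi(mean_r = 150, mean_g = 60, roi_id = "r04"),    # shadow
    good_rois("r05"), good_rois("r06"), good_rois("r07"),
    good_rois("r08"), good_rois("r09"), good_rois("r10")
  )
  q <- apply_qc(rois)
  expect_equal(unname(q$tally["size_aspect"]), 3L)
  expect_equal(unname(q$tally["shadow"]), 1L)
  expect_equal(unname(q$tally["passed"]), 6L)
  expect_equal(nrow(q$rois), 6)
  # short-circuit: r03 fails size, so its shadow verdict is never evaluated
  expect_true(is.na(q$results$shadow[q$results$roi_id == "r03"]))
  # overall pass iff all four checks pass
  passed <- q$results[q$results$pass, ]
  expect_true(all(passed$size_aspect & passed$shadow &
                    passed$hematoxylin_area & passed$nucleus))
})

test_that("QC is idempotent and verdicts are pure", {
  rois <- dplyr::bind_rows(good_rois("a"), good_rois("b"),
                           fake_roi(mean_r = 150, mean_g = 60, roi_id = "c"))
  q1 <- apply_qc(rois)
  q2 <- apply_qc(q1$rois)
  expect_equal(nrow(q2$rois), nrow(q1$rois))
  expect_identical(q2$results$pass, rep(TRUE, nrow(q1$rois)))
  expect_identical(apply_qc(rois)$results, q1$results)
  empty <- apply_qc(rois[0, ])
  expect_equal(nrow(empty$rois), 0)
  expect_equal(unname(empty$tally["passed"]), 0L)
})
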