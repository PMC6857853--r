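test_that("scene specs are validated with the offending field named", {
  expect_error(scene_spec(fov_radius = -1), "fov_radius")
  expect_error(scene_spec(image_width = 500, image_height = 500,
                          fov_radius = 400), "fov_radius")
  expect_error(scene_spec(nucleus_fraction_range = c(0, 0.5)),
               "nucleus_fraction_range")
  expect_error(scene_spec(n_cells = -2), "n_cells")
  expect_error(scene_spec(cell_diameter_range = c(60, 25)),
               "cell_diameter_range")
})

test_that("default scene renders at the platform's native frame size", {
  f <- generate_field_image(scene_spec(n_cells = 0, seed = 1))
  expect_equal(dim(f$image$pixels), c(1936, 2592, 3))
  expect_equal(f$image$pixel_scale, 1.9)
  expect_equal(nrow(f$truth$cells), 0)
  # vignette outside the FOV stays dark, inside is illuminated
  px <- f$image$pixels
  expect_lt(px[5, 5, 2], 40)
  expect_gt(px[968, 1296, 2], 150)
})

test_that("identical spec and seed render byte-identical fields", {
  a <- generate_field_image(small_scene(n_cells = 5, seed = 9))
  b <- generate_field_image(small_scene(n_cells = 5, seed = 9))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_equal(a$truth$cells$cx, b$truth$cells$cx)
  c <- generate_field_image(small_scene(n_cells = 5, seed = 10))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("ground-truth mask areas equal a brute-force pixel scan", {
  # no antialiasing and no noise so rendered pixels and masks coincide
  spec <- small_scene(n_cells = 6, seed = 3, antialias = FALSE, noise_sd = 0)
  f <- generate_field_image(spec)
  px <- f$image$pixels
  # background colour = most frequent in-FOV pixel value per channel
  dist <- sqrt(outer((seq_len(nrow(px)) - spec$fov_center[2])^2,
                     (seq_len(ncol(px)) - spec$fov_center[1])^2, `+`))
  inside <- dist <= spec$fov_radius - 2
  bg <- vapply(1:3, function(k) {
    v <- px[, , k][inside]
    as.numeric(names(which.max(table(v))))
  }, numeric(1))
  non_bg <- inside &
    (px[, , 1] != bg[1] | px[, , 2] != bg[2] | px[, , 3] != bg[3])
  expect_equal(sum(non_bg), sum(f$truth$cells$area_px))
})

test_that("every ground-truth cell pixel lies inside the FOV circle", {
  f <- generate_field_image(small_scene(n_cells = 8, seed = 4,
                                        n_shadow_artifacts = 2))
  fov <- f$truth$fov
  for (i in seq_len(nrow(f$truth$cells))) {
    bb <- f$truth$cells$bbox[[i]]
    m <- f$truth$cells$mask[[i]]
    ys <- row(m)[m] + bb["y0"] - 1
    xs <- col(m)[m] + bb["x0"] - 1
    expect_true(all(sqrt((xs - fov$cx)^2 + (ys - fov$cy)^2) <= fov$radius))
  }
})

test_that("slides derive per-field seeds deterministically from the master", {
  spec <- small_scene(n_cells = 3, seed = 77)
  slide <- generate_slide(spec, n_fields = 3)
  expect_length(slide, 3)
  again <- generate_slide(spec, n_fields = 3)
  for (i in 1:3) {
    expect_identical(slide[[i]]$image$pixels, again[[i]]$image$pixels)
  }
  # a single-field slide equals the field generated with the derived seed
  one <- generate_slide(spec, n_fields = 1)
  spec1 <- spec
  spec1$seed <- oralcyto:::derive_seed(spec$seed, 1)
  direct <- generate_field_image(spec1)
  expect_identical(one[[1]]$image$pixels, direct$image$pixels)
  expect_error(generate_slide(spec, n_fields = 0), "n_fields")
})

test_that("cohort spec rejects infeasible mixtures", {
  cls <- default_cohort_classes()
  cls$atypical_mean[cls$class == "OSCC"] <- 0.4
  expect_error(cohort_spec(classes = cls), "atypical_mean")
  cls <- default_cohort_classes()
  cls$all_mean[cls$class == "OSCC"] <- 0.9   # implies normal mean > 0.5
  expect_error(cohort_spec(classes = cls), "all_mean")
})

test_that("score cohorts match their class-conditional parameters", {
  cls <- default_cohort_classes()
  cls$n_patients <- 50L
  coh <- generate_score_cohort(cohort_spec(classes = cls, seed = 42))
  feats <- aggregate_cohort(coh)

  oscc <- feats[feats$class == "OSCC", ]
  frac <- oscc$pct_atypical / 100
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.39), 3 * se)

  ma <- oscc$mean_atypical
  se_ma <- sd(ma) / sqrt(length(ma))
  expect_lt(abs(mean(ma) - 0.71), 3 * se_ma)

  # determinism
  again <- generate_score_cohort(cohort_spec(classes = cls, seed = 42))
  expect_identical(coh$score, again$score)
})

test_that("degenerate atypical fractions behave as stated", {
  cls <- tibble::tibble(class = c("X", "Y"), n_patients = c(5L, 5L),
                        cells_per_patient = 100L,
                        atypical_fraction = c(0, 1),
                        atypical_fraction_sd = 0,
                        atypical_mean = c(0.9, 0.9), atypical_sd = 0.005,
                        all_mean = c(0.2, 0.9), all_sd = 0.01)
  coh <- generate_score_cohort(cohort_spec(classes = cls, seed = 7))
  feats <- aggregate_cohort(coh)
  expect_true(all(feats$pct_atypical[feats$class == "X"] == 0))
  y <- feats[feats$class == "Y", ]
  se <- max(sd(y$mean_all) / sqrt(nrow(y)), 1e-3)
  expect_lt(abs(mean(y$mean_all) - 0.9), 3 * se)
})
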