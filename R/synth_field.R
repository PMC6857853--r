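#' Generate one synthetic cytology field with ground truth
#'
#' Renders an 8-bit RGB microscope field: a bright circular field of view
#' (FOV) on a dark vignette, stained cells drawn as rotated ellipses with
#' darker nuclei (atypical cells get larger nuclei and irregular, lobed
#' boundaries), optional clumps of touching cells, optional shadow artifacts
#' (dark red-dominant blobs), and Gaussian pixel noise. Every drawn object is
#' reported in a ground-truth record so that segmentation, quality control
#' and scoring can be validated pixel-for-pixel.
#'
#' Rendering is deterministic: the same `scene_spec` (including its seed)
#' yields a byte-identical image. Ground-truth cell masks are the `d <= 1`
#' contour of each (possibly radially modulated) ellipse; with antialiasing
#' the one-pixel blend band straddles that contour symmetrically.
#'
#' @param spec A [scene_spec()].
#' @return A list with elements `image` (a [field_image()]) and `truth`
#'   (class `field_truth`: `fov`, a `cells` tibble with per-cell geometry,
#'   masks and atypia labels, and an `artifacts` tibble).
#' @export
#' @examples
#' f <- generate_field_image(scene_spec(image_width = 400, image_height = 300,
#'                                      fov_radius = 130, n_cells = 3,
#'                                      pixel_scale = 1, seed = 7))
#' f$truth$cells$atypical
generate_field_image <- function(spec) {
  spec <- validate_scene_spec(spec)
  withr::with_seed(spec$seed, render_field(spec))
}

#' Generate a slide as a sequence of fields
#'
#' Portable slide scanners raster-scan a slide into on the order of 100-125
#' fields. Each field gets an independent seed derived deterministically from
#' the master seed (`derive_seed(master, i)`), so a slide is reproducible
#' from `(spec, n_fields)` alone and any single field can be regenerated in
#' isolation.
#'
#' @param spec A [scene_spec()]; its `seed` acts as the master seed.
#' @param n_fields Number of fields (>= 1).
#' @return List of `n_fields` results of [generate_field_image()].
#' @export
generate_slide <- function(spec, n_fields) {
  spec <- validate_scene_spec(spec)
  check_that(is_scalar_number(n_fields) && n_fields >= 1, "n_fields", "must be >= 1")
  lapply(seq_len(n_fields), function(i) {
    fspec <- spec
    fspec$seed <- derive_seed(spec$seed, i)
    out <- generate_field_image(fspec)
    out$image$source_id <- sprintf("field_%04d", i)
    out
  })
}

# ---- internal rendering ----------------------------------------------------

draw_palette <- function(range_mat) {
  vapply(1:3, function(k) runif(1, range_mat["lo", k], range_mat["hi", k]),
         numeric(1))
}

# Sample geometry for one cell (sizes in pixels).
sample_cell_params <- function(spec) {
  d_um <- runif(1, spec$cell_diameter_range[1], spec$cell_diameter_range[2])
  a <- d_um * spec$pixel_scale / 2            # major semi-axis, px
  aspect <- runif(1, 1, 1.8)
  b <- a / aspect
  atypical <- runif(1) < spec$p_atypical
  nf_range <- if (atypical) spec$atypical_nucleus_fraction_range else
    spec$nucleus_fraction_range
  list(
    a = a, b = b, theta = runif(1, 0, pi), atypical = atypical,
    nucleus_fraction = runif(1, nf_range[1], nf_range[2]),
    amp = if (atypical) runif(1, 0.10, 0.18) else runif(1, 0, 0.03),
    lobes = sample(5:8, 1), phase = runif(1, 0, 2 * pi),
    color = draw_palette(spec$stain_palette$cytoplasm),
    nucleus_color = draw_palette(spec$stain_palette$nucleus)
  )
}

# Effective outer radius used for placement margins.
cell_reach <- function(p) p$a * (1 + p$amp) + 2

# Rejection-sample a centre inside the FOV, at `margin` from the rim and at
# pairwise clearance from previously placed objects.
place_center <- function(spec, margin, placed, clearance, tries = 400) {
  cx <- spec$fov_center[1]; cy <- spec$fov_center[2]
  rmax <- spec$fov_radius - margin
  if (rmax <= 0) abort("cells too large for the FOV radius")
  for (t in seq_len(tries)) {
    ang <- runif(1, 0, 2 * pi)
    rad <- sqrt(runif(1)) * rmax
    x <- cx + rad * cos(ang); y <- cy + rad * sin(ang)
    ok <- TRUE
    if (nrow(placed) > 0) {
      d <- sqrt((placed$x - x)^2 + (placed$y - y)^2)
      ok <- all(d >= placed$reach + clearance)
    }
    if (ok) return(c(x, y))
  }
  abort("could not place all objects without overlap; reduce n_cells or cell size")
}

# Normalised radial distance of bounding-box pixels to a rotated, radially
# modulated ellipse. Returns list(xs, ys, d) for pixels of the bbox.
ellipse_field <- function(x0, y0, p, H, W) {
  reach <- ceiling(p$a * (1 + p$amp) + 2)
  xs <- max(1L, floor(x0 - reach)):min(W, ceiling(x0 + reach))
  ys <- max(1L, floor(y0 - reach)):min(H, ceiling(y0 + reach))
  dx <- outer(rep(1, length(ys)), xs - x0)
  dy <- outer(ys - y0, rep(1, length(xs)))
  u <- dx * cos(p$theta) + dy * sin(p$theta)
  v <- -dx * sin(p$theta) + dy * cos(p$theta)
  d0 <- sqrt((u / p$a)^2 + (v / p$b)^2)
  if (p$amp > 0) {
    phi <- atan2(v, u)
    d0 <- d0 / (1 + p$amp * sin(p$lobes * phi + p$phase))
  }
  list(xs = xs, ys = ys, d = d0)
}

ellipse_alpha <- function(ef, antialias, edge_scale, opacity = 1) {
  alpha <- if (antialias) clamp((1 - ef$d) * edge_scale + 0.5, 0, 1) else
    (ef$d <= 1) * 1
  alpha * opacity
}

# Nucleus geometry derived from the parent cell's parameters.
nucleus_params <- function(p) {
  np <- p
  np$a <- p$a * sqrt(p$nucleus_fraction)
  np$b <- p$b * sqrt(p$nucleus_fraction)
  np$amp <- if (p$atypical) min(p$amp, 0.12) else 0
  max_off <- max(0.4 * (p$b - np$b * (1 + np$amp)), 0)
  off_ang <- runif(1, 0, 2 * pi)
  off_len <- runif(1, 0, max_off)
  np$dx <- off_len * cos(off_ang)
  np$dy <- off_len * sin(off_ang)
  np
}

render_field <- function(spec) {
  H <- as.integer(spec$image_height); W <- as.integer(spec$image_width)
  cx <- spec$fov_center[1]; cy <- spec$fov_center[2]; r <- spec$fov_radius

  # --- phase 1: sample scene layout (all RNG except pixel noise) ------------
  bg <- draw_palette(spec$stain_palette$background)
  px_ <- py_ <- reach_ <- numeric(0)  # placed-object registry
  register <- function(x, y, reach) {
    px_ <<- c(px_, x); py_ <<- c(py_, y); reach_ <<- c(reach_, reach)
  }
  placed_tbl <- function() tibble(x = px_, y = py_, reach = reach_)

  objs <- list()
  for (i in seq_len(spec$n_cells)) {
    p <- sample_cell_params(spec)
    ctr <- place_center(spec, cell_reach(p) + 4, placed_tbl(), cell_reach(p) + 6)
    p$x <- ctr[1]; p$y <- ctr[2]; p$clump_id <- NA_integer_
    p$nucleus <- nucleus_params(p)
    register(p$x, p$y, cell_reach(p))
    objs[[length(objs) + 1]] <- list(kind = "cell", p = p)
  }
  # clumps: pairs of touching cells (centres at 0.75 * (a1 + a2))
  for (j in seq_len(spec$n_clumps)) {
    p1 <- sample_cell_params(spec)
    p2 <- sample_cell_params(spec)
    sep <- 0.75 * (p1$a + p2$a)
    margin <- cell_reach(p1) + sep + cell_reach(p2) + 4
    ctr <- place_center(spec, margin, placed_tbl(),
                        cell_reach(p1) + sep + cell_reach(p2) + 6)
    ang <- runif(1, 0, 2 * pi)
    p1$x <- ctr[1]; p1$y <- ctr[2]
    p2$x <- ctr[1] + sep * cos(ang); p2$y <- ctr[2] + sep * sin(ang)
    p1$clump_id <- p2$clump_id <- j
    p1$nucleus <- nucleus_params(p1)
    p2$nucleus <- nucleus_params(p2)
    register(p1$x, p1$y, cell_reach(p1))
    register(p2$x, p2$y, cell_reach(p2))
    objs[[length(objs) + 1]] <- list(kind = "cell", p = p1)
    objs[[length(objs) + 1]] <- list(kind = "cell", p = p2)
  }
  # shadow artifacts: dark red-dominant, irregular, semi-transparent blobs
  for (s in seq_len(spec$n_shadow_artifacts)) {
    d_um <- runif(1, 30, 55)
    p <- list(a = d_um * spec$pixel_scale / 2,
              b = d_um * spec$pixel_scale / 2 / runif(1, 1, 1.4),
              theta = runif(1, 0, pi), amp = runif(1, 0.2, 0.3),
              lobes = sample(3:6, 1), phase = runif(1, 0, 2 * pi),
              color = draw_palette(spec$stain_palette$shadow))
    ctr <- place_center(spec, p$a * (1 + p$amp) + 6, placed_tbl(),
                        p$a * (1 + p$amp) + 8)
    p$x <- ctr[1]; p$y <- ctr[2]
    objs[[length(objs) + 1]] <- list(kind = "shadow", p = p)
  }

  # --- phase 2: render (direct in-place subscript assignment) ---------------
  dist <- sqrt(outer((seq_len(H) - cy)^2, (seq_len(W) - cx)^2, `+`))
  inside <- dist <= r
  ch1 <- matrix(spec$vignette_level, H, W); ch1[inside] <- bg[1]
  ch2 <- matrix(spec$vignette_level, H, W); ch2[inside] <- bg[2]
  ch3 <- matrix(spec$vignette_level, H, W); ch3[inside] <- bg[3]

  cells <- list()
  artifacts <- list()
  cell_id <- 0L
  for (obj in objs) {
    p <- obj$p
    if (obj$kind == "cell") {
      cell_id <- cell_id + 1L
      ef <- ellipse_field(p$x, p$y, p, H, W)
      alpha <- ellipse_alpha(ef, spec$antialias, max(min(p$a, p$b), 1))
      col <- p$color
      ch1[ef$ys, ef$xs] <- (1 - alpha) * ch1[ef$ys, ef$xs] + alpha * col[1]
      ch2[ef$ys, ef$xs] <- (1 - alpha) * ch2[ef$ys, ef$xs] + alpha * col[2]
      ch3[ef$ys, ef$xs] <- (1 - alpha) * ch3[ef$ys, ef$xs] + alpha * col[3]
      mask <- ef$d <= 1

      np <- p$nucleus
      nef <- ellipse_field(p$x + np$dx, p$y + np$dy, np, H, W)
      nalpha <- ellipse_alpha(nef, spec$antialias, max(min(np$a, np$b), 1))
      ncol <- p$nucleus_color
      ch1[nef$ys, nef$xs] <- (1 - nalpha) * ch1[nef$ys, nef$xs] + nalpha * ncol[1]
      ch2[nef$ys, nef$xs] <- (1 - nalpha) * ch2[nef$ys, nef$xs] + nalpha * ncol[2]
      ch3[nef$ys, nef$xs] <- (1 - nalpha) * ch3[nef$ys, nef$xs] + nalpha * ncol[3]
      nmask <- nef$d <= 1

      cells[[cell_id]] <- list(
        cell_id = cell_id, cx = p$x, cy = p$y,
        area_px = sum(mask), area_um2 = sum(mask) / spec$pixel_scale^2,
        aspect = p$a / p$b, atypical = p$atypical, clump_id = p$clump_id,
        nucleus_area_px = sum(nmask),
        bbox = c(x0 = min(ef$xs), y0 = min(ef$ys),
                 x1 = max(ef$xs), y1 = max(ef$ys)),
        mask = mask,
        nucleus_bbox = c(x0 = min(nef$xs), y0 = min(nef$ys),
                         x1 = max(nef$xs), y1 = max(nef$ys)),
        nucleus_mask = nmask
      )
    } else {
      ef <- ellipse_field(p$x, p$y, p, H, W)
      alpha <- ellipse_alpha(ef, spec$antialias, max(min(p$a, p$b), 1),
                             opacity = 0.9)
      col <- p$color
      ch1[ef$ys, ef$xs] <- (1 - alpha) * ch1[ef$ys, ef$xs] + alpha * col[1]
      ch2[ef$ys, ef$xs] <- (1 - alpha) * ch2[ef$ys, ef$xs] + alpha * col[2]
      ch3[ef$ys, ef$xs] <- (1 - alpha) * ch3[ef$ys, ef$xs] + alpha * col[3]
      artifacts[[length(artifacts) + 1]] <- list(
        artifact_id = length(artifacts) + 1L, cx = p$x, cy = p$y,
        bbox = c(x0 = min(ef$xs), y0 = min(ef$ys),
                 x1 = max(ef$xs), y1 = max(ef$ys)),
        mask = ef$d <= 1
      )
    }
  }

  # imaging noise, clip, quantise to 8 bits
  px <- array(0L, dim = c(H, W, 3))
  for (k in 1:3) {
    v <- switch(k, ch1, ch2, ch3)
    if (spec$noise_sd > 0) v <- v + rnorm(H * W, 0, spec$noise_sd)
    px[, , k] <- as.integer(round(clamp(v, 0, 255)))
  }

  truth <- structure(
    list(
      fov = circle_fov(cx, cy, r),
      cells = if (cell_id > 0) cell_records_tibble(cells) else empty_cells_tibble(),
      artifacts = if (length(artifacts) > 0) artifact_records_tibble(artifacts) else
        tibble(artifact_id = integer(), cx = numeric(), cy = numeric(),
               bbox = list(), mask = list())
    ),
    class = "field_truth"
  )

  list(
    image = field_image(px, pixel_scale = spec$pixel_scale,
                        source_id = sprintf("synthetic_seed%d", spec$seed),
                        fov = NULL),
    truth = truth
  )
}

cell_records_tibble <- function(cells) {
  tibble(
    cell_id = map_dbl(cells, "cell_id"),
    cx = map_dbl(cells, "cx"),
    cy = map_dbl(cells, "cy"),
    area_px = map_dbl(cells, "area_px"),
    area_um2 = map_dbl(cells, "area_um2"),
    aspect = map_dbl(cells, "aspect"),
    atypical = map_lgl(cells, "atypical"),
    clump_id = map_dbl(cells, function(c) as.numeric(c$clump_id)),
    nucleus_area_px = map_dbl(cells, "nucleus_area_px"),
    bbox = map(cells, "bbox"),
    mask = map(cells, "mask"),
    nucleus_bbox = map(cells, "nucleus_bbox"),
    nucleus_mask = map(cells, "nucleus_mask")
  )
}

empty_cells_tibble <- function() {
  tibble(cell_id = numeric(), cx = numeric(), cy = numeric(),
         area_px = numeric(), area_um2 = numeric(), aspect = numeric(),
         atypical = logical(), clump_id = numeric(),
         nucleus_area_px = numeric(), bbox = list(), mask = list(),
         nucleus_bbox = list(), nucleus_mask = list())
}

artifact_records_tibble <- function(artifacts) {
  tibble(
    artifact_id = map_dbl(artifacts, "artifact_id"),
    cx = map_dbl(artifacts, "cx"),
    cy = map_dbl(artifacts, "cy"),
    bbox = map(artifacts, "bbox"),
    mask = map(artifacts, "mask")
  )
}
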