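#' Scene specification for the synthetic cytology field generator
#'
#' Describes one synthetic microscope field: the circular field of view (FOV)
#' on a dark surround, the number of stained cells (plus optional clumps of
#' touching cells and shadow artifacts), cell geometry in micrometres, the
#' stain palette and the imaging noise level. The defaults emulate a portable
#' slide-scanning cytology platform: 2592 x 1936 8-bit RGB frames at
#' 1.9 px/um, squamous-cell diameters of 25-60 um and a nucleus occupying
#' 8-20% of the cell area (25-45% for atypical cells, which are also rendered
#' with irregular boundaries so that morphometric scoring has signal).
#'
#' @param image_width,image_height Frame size in pixels.
#' @param fov_center Numeric `(x, y)`: FOV circle centre in pixels
#'   (x = column, y = row, 1-based).
#' @param fov_radius FOV circle radius in pixels; the circle must fit inside
#'   the frame.
#' @param n_cells Number of isolated (non-touching) cells.
#' @param n_clumps Number of clumps; each clump is a pair of touching cells
#'   whose centres sit 0.75 of the sum of their major semi-axes apart.
#' @param n_shadow_artifacts Number of out-of-focus shadow blobs (dark,
#'   red-dominant patches that should fail quality control).
#' @param cell_diameter_range Major-axis diameter range in micrometres.
#' @param nucleus_fraction_range,atypical_nucleus_fraction_range Nucleus area
#'   as a fraction of the cell area for normal and atypical cells; both must
#'   lie strictly inside (0, 1).
#' @param p_atypical Probability that a rendered cell is atypical.
#' @param stain_palette Named list of 2 x 3 matrices (`rbind(lo, hi)` per RGB
#'   channel, 0-255) for `background`, `cytoplasm`, `nucleus` and `shadow`;
#'   see `default_stain_palette()`.
#' @param pixel_scale Pixels per micrometre (default 1.9).
#' @param noise_sd Gaussian pixel noise standard deviation on the 0-255 scale
#'   (default 5).
#' @param antialias Render ellipse edges with a one-pixel linear blend
#'   (default `TRUE`). Ground-truth masks are the `d <= 1` contour either way.
#' @param vignette_level Intensity (0-255) outside the FOV circle.
#' @param seed Integer seed; identical specs render byte-identical fields.
#'
#' @return An object of class `scene_spec` (a validated named list).
#' @seealso [generate_field_image()], [generate_slide()]
#' @export
scene_spec <- function(image_width = 2592,
                       image_height = 1936,
                       fov_center = c(image_width / 2, image_height / 2),
                       fov_radius = 900,
                       n_cells = 12,
                       n_clumps = 0,
                       n_shadow_artifacts = 0,
                       cell_diameter_range = c(25, 60),
                       nucleus_fraction_range = c(0.08, 0.20),
                       atypical_nucleus_fraction_range = c(0.25, 0.45),
                       p_atypical = 0,
                       stain_palette = default_stain_palette(),
                       pixel_scale = 1.9,
                       noise_sd = 5,
                       antialias = TRUE,
                       vignette_level = 8,
                       seed = 1L) {
  spec <- list(
    image_width = image_width, image_height = image_height,
    fov_center = as.numeric(fov_center), fov_radius = fov_radius,
    n_cells = n_cells, n_clumps = n_clumps,
    n_shadow_artifacts = n_shadow_artifacts,
    cell_diameter_range = as.numeric(cell_diameter_range),
    nucleus_fraction_range = as.numeric(nucleus_fraction_range),
    atypical_nucleus_fraction_range = as.numeric(atypical_nucleus_fraction_range),
    p_atypical = p_atypical,
    stain_palette = stain_palette,
    pixel_scale = pixel_scale, noise_sd = noise_sd,
    antialias = isTRUE(antialias), vignette_level = vignette_level,
    seed = as.integer(seed)
  )
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  check_that(is_scalar_number(spec$image_width) && spec$image_width >= 3,
             "image_width", "must be a number >= 3")
  check_that(is_scalar_number(spec$image_height) && spec$image_height >= 3,
             "image_height", "must be a number >= 3")
  check_that(length(spec$fov_center) == 2 && all(is.finite(spec$fov_center)),
             "fov_center", "must be a finite (x, y) pair")
  check_that(is_scalar_number(spec$fov_radius) && spec$fov_radius > 0,
             "fov_radius", "must be > 0")
  cx <- spec$fov_center[1]; cy <- spec$fov_center[2]; r <- spec$fov_radius
  check_that(cx - r >= 0 && cx + r <= spec$image_width + 1 &&
               cy - r >= 0 && cy + r <= spec$image_height + 1,
             "fov_radius", "FOV circle must fit inside the image")
  check_that(is_scalar_number(spec$n_cells) && spec$n_cells >= 0,
             "n_cells", "must be >= 0")
  check_that(is_scalar_number(spec$n_clumps) && spec$n_clumps >= 0,
             "n_clumps", "must be >= 0")
  check_that(is_scalar_number(spec$n_shadow_artifacts) && spec$n_shadow_artifacts >= 0,
             "n_shadow_artifacts", "must be >= 0")
  check_that(length(spec$cell_diameter_range) == 2 &&
               all(spec$cell_diameter_range > 0) && !is.unsorted(spec$cell_diameter_range),
             "cell_diameter_range", "must be an increasing positive pair (um)")
  for (f in c("nucleus_fraction_range", "atypical_nucleus_fraction_range")) {
    check_that(length(spec[[f]]) == 2 && all(spec[[f]] > 0) && all(spec[[f]] < 1) &&
                 !is.unsorted(spec[[f]]), f, "must lie strictly inside (0, 1)")
  }
  check_that(is_scalar_number(spec$p_atypical) &&
               spec$p_atypical >= 0 && spec$p_atypical <= 1,
             "p_atypical", "must lie in [0, 1]")
  check_that(is_scalar_number(spec$pixel_scale) && spec$pixel_scale > 0,
             "pixel_scale", "must be > 0")
  check_that(is_scalar_number(spec$noise_sd) && spec$noise_sd >= 0,
             "noise_sd", "must be >= 0")
  needed <- c("background", "cytoplasm", "nucleus", "shadow")
  check_that(is.list(spec$stain_palette) && all(needed %in% names(spec$stain_palette)),
             "stain_palette", "must name background, cytoplasm, nucleus, shadow")
  spec
}

#' Default stain palette for the synthetic generator
#'
#' Per-channel 0-255 intensity ranges (rows: low, high; columns: R, G, B).
#' Cytoplasm is rendered blue-green (Papanicolaou-like basophilic tint) with
#' red/green mean ratio well below 1; nuclei are dark and blue-dominant and
#' have their strongest contrast in the red channel (the channel used for
#' nucleus detection); shadows are dark red-dominant patches with red/green
#' around 1.5 so the quality-control shadow test can reject them.
#'
#' @return Named list of 2 x 3 numeric matrices.
#' @export
default_stain_palette <- function() {
  rng <- function(lo, hi) rbind(lo = lo, hi = hi)
  list(
    background = rng(c(205, 205, 200), c(215, 215, 210)),
    cytoplasm  = rng(c(100, 115, 170), c(125, 150, 200)),
    nucleus    = rng(c(55, 70, 125),  c(80, 95, 160)),
    shadow     = rng(c(85, 55, 60),   c(105, 70, 80))
  )
}

#' Cohort specification for synthetic per-cell score tables
#'
#' Class-conditional parameters for simulating per-patient cell-score tables
#' without images: each patient's cells are drawn from a two-component
#' mixture, a normal-cell component (scores clipped to `[0, 0.5]`) and an
#' atypical-cell component (scores clipped to `(0.5, 1]`). Per class the
#' atypical fraction, the atypical-component mean and the all-cell mean are
#' matched in expectation; the normal-component mean is derived as
#' `(all_mean - frac * atypical_mean) / (1 - frac)`. The `*_sd` columns are
#' between-patient standard deviations (patient-level random effects);
#' `cell_sd` controls within-patient score spread.
#'
#' Defaults reproduce the published class statistics for oral cytology
#' cohorts: atypical-cell percentages 14% (benign and low-grade dysplasia),
#' 16% (high-grade dysplasia) and 39% (carcinoma); mean atypical-cell scores
#' 0.78/0.76/0.71 and all-cell means 0.17/0.21/0.40 for LGD/HGD/OSCC, with an
#' average of 200 cells per patient.
#'
#' @param classes Data frame with one row per class and columns `class`,
#'   `n_patients`, `cells_per_patient`, `atypical_fraction`,
#'   `atypical_fraction_sd`, `atypical_mean`, `atypical_sd`, `all_mean`,
#'   `all_sd`. Missing columns fall back to the defaults shown by
#'   `default_cohort_classes()`.
#' @param cell_sd Within-patient cell-score standard deviation (default 0.05).
#' @param seed Integer seed.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_score_cohort()]
#' @export
cohort_spec <- function(classes = default_cohort_classes(),
                        cell_sd = 0.05,
                        seed = 1L) {
  classes <- as_tibble(classes)
  base <- default_cohort_classes()
  for (col in setdiff(names(base), names(classes))) {
    classes[[col]] <- base[[col]][match(classes$class, base$class)]
  }
  spec <- list(classes = classes, cell_sd = cell_sd, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
}

#' @rdname cohort_spec
#' @export
default_cohort_classes <- function() {
  tibble(
    class = c("BNG", "LGD", "HGD", "OSCC"),
    n_patients = 15L,
    cells_per_patient = 200L,
    atypical_fraction = c(0.14, 0.14, 0.16, 0.39),
    atypical_fraction_sd = c(0.09, 0.09, 0.09, 0.11),
    atypical_mean = c(0.78, 0.78, 0.76, 0.71),
    atypical_sd = c(0.03, 0.03, 0.03, 0.02),
    all_mean = c(0.17, 0.17, 0.21, 0.40),
    all_sd = c(0.09, 0.09, 0.08, 0.08)
  )
}

validate_cohort_spec <- function(spec) {
  cl <- spec$classes
  check_that(nrow(cl) >= 1, "classes", "needs at least one class row")
  check_that(!anyDuplicated(cl$class), "classes", "class labels must be unique")
  check_that(all(cl$n_patients >= 0), "n_patients", "must be >= 0")
  check_that(all(cl$cells_per_patient >= 1), "cells_per_patient", "must be >= 1")
  check_that(all(cl$atypical_fraction >= 0 & cl$atypical_fraction <= 1),
             "atypical_fraction", "must lie in [0, 1]")
  bad <- cl$atypical_fraction > 0 & cl$atypical_mean <= 0.5
  check_that(!any(bad), "atypical_mean",
             "must exceed 0.5 (atypical cells score above the 0.5 atypia rule)")
  # derived normal-component mean must be a feasible sub-threshold score
  p <- cl$atypical_fraction
  mu_n <- ifelse(p < 1, (cl$all_mean - p * cl$atypical_mean) / (1 - p), 0)
  check_that(all(mu_n >= 0 & mu_n <= 0.5),
             "all_mean",
             "implies a normal-component mean outside [0, 0.5]; infeasible mixture")
  check_that(is_scalar_number(spec$cell_sd) && spec$cell_sd >= 0,
             "cell_sd", "must be >= 0")
  spec
}

#' Construct a field image object
#'
#' A `field_image` wraps an `H x W x 3` 8-bit RGB intensity array (values
#' 0-255; channel order R, G, B; rows are image y, columns image x, 1-based)
#' together with its pixel scale and, once estimated, its circular FOV.
#'
#' @param pixels `H x W x 3` numeric/integer array with values in 0-255.
#' @param pixel_scale Pixels per micrometre.
#' @param source_id Identifier string carried through manifests.
#' @param fov Optional [circle_fov()].
#' @return An object of class `field_image`.
#' @export
field_image <- function(pixels, pixel_scale = 1.9, source_id = "field", fov = NULL) {
  check_that(is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3,
             "pixels", "must be an H x W x 3 array")
  check_that(dim(pixels)[1] >= 3 && dim(pixels)[2] >= 3,
             "pixels", "image must be at least 3 x 3")
  check_that(min(pixels) >= 0 && max(pixels) <= 255,
             "pixels", "intensities must lie in [0, 255]")
  structure(
    list(pixels = pixels, pixel_scale = pixel_scale,
         source_id = source_id, fov = fov),
    class = "field_image"
  )
}

#' @method print field_image
#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<field_image '%s': %d x %d px, %.2f px/um%s>\n",
              x$source_id, d[2], d[1], x$pixel_scale,
              if (is.null(x$fov)) "" else
                sprintf(", FOV c=(%.1f, %.1f) r=%.1f",
                        x$fov$cx, x$fov$cy, x$fov$radius)))
  invisible(x)
}

#' Circular field-of-view parameters
#'
#' @param cx,cy Circle centre in pixels (x = column, y = row).
#' @param radius Circle radius in pixels (> 0).
#' @return An object of class `circle_fov`.
#' @export
circle_fov <- function(cx, cy, radius) {
  check_that(is_scalar_number(cx) && is_scalar_number(cy), "center",
             "cx and cy must be finite numbers")
  check_that(is_scalar_number(radius) && radius > 0, "radius", "must be > 0")
  structure(list(cx = cx, cy = cy, radius = radius), class = "circle_fov")
}

#' @method print circle_fov
#' @export
print.circle_fov <- function(x, ...) {
  cat(sprintf("<circle_fov center=(%.2f, %.2f) radius=%.2f>\n", x$cx, x$cy, x$radius))
  invisible(x)
}
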