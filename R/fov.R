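#' Find three pixels on the circular field-of-view boundary
#'
#' Portable microscope frames show a bright circular illuminated region on a
#' dark vignette. The FOV boundary is located by casting rays inward from the
#' image border along six equally spaced directions and recording the first
#' pixel whose green intensity exceeds the global Otsu threshold; of the
#' candidate boundary hits, the three maximizing their minimum pairwise
#' angular separation (about the candidates' centroid) are returned.
#'
#' @param image A [field_image()].
#' @return A 3 x 2 numeric matrix of `(x, y)` boundary points, with attribute
#'   `confidence` (`"high"`, or `"low"` when no vignette is present and the
#'   points degenerate to the image border).
#' @details Errors with message "FOV not detected" when the image lacks the
#'   bright-on-dark bimodal structure (e.g. a uniform frame). On a frame that
#'   is bright to its very border (no vignette) the rays terminate on the
#'   border itself; points are returned but flagged low confidence.
#' @seealso [circumcircle()], [trim_to_fov()]
#' @export
find_fov_edge_points <- function(image) {
  stopifnot(inherits(image, "field_image"))
  g <- image$pixels[, , 2]
  H <- nrow(g); W <- ncol(g)
  if (diff(range(g)) < 30) {
    abort("FOV not detected: image intensity is not bimodal (uniform frame?)")
  }
  thr <- otsu_threshold(g)

  # degenerate full-bright frame: border already above threshold
  border <- c(g[1, ], g[H, ], g[, 1], g[, W])
  if (mean(border > thr) > 0.5) {
    pts <- rbind(c(1, ceiling(H / 2)), c(W, ceiling(H / 2)), c(ceiling(W / 2), 1))
    colnames(pts) <- c("x", "y")
    attr(pts, "confidence") <- "low"
    warn("no dark vignette found; FOV edge points fall on the image border")
    return(pts)
  }

  scan_once <- function(offset) {
    angles <- 2 * pi * (0:5) / 6 + offset
    cx0 <- (W + 1) / 2; cy0 <- (H + 1) / 2
    hits <- list()
    for (phi in angles) {
      dx <- cos(phi); dy <- sin(phi)
      # distance from centre to border along (dx, dy)
      tx <- if (abs(dx) > 1e-12) max((1 - cx0) / dx, (W - cx0) / dx) else Inf
      ty <- if (abs(dy) > 1e-12) max((1 - cy0) / dy, (H - cy0) / dy) else Inf
      tmax <- min(tx, ty)
      for (t in seq(floor(tmax), 0, by = -1)) {
        x <- round(cx0 + t * dx); y <- round(cy0 + t * dy)
        if (x < 1 || x > W || y < 1 || y > H) next
        if (g[y, x] > thr) {
          hits[[length(hits) + 1]] <- c(x = x, y = y)
          break
        }
      }
    }
    if (length(hits) < 3) return(NULL)
    pts <- do.call(rbind, hits)
    # pick the 3 hits maximizing the minimum pairwise angular separation
    ctr <- colMeans(pts)
    ang <- atan2(pts[, "y"] - ctr["y"], pts[, "x"] - ctr["x"])
    combos <- utils::combn(nrow(pts), 3)
    sep <- apply(combos, 2, function(idx) {
      a <- sort(ang[idx])
      gaps <- c(diff(a), 2 * pi - (a[3] - a[1]))
      min(gaps)
    })
    best <- pts[combos[, which.max(sep)], , drop = FALSE]
    if (collinear(best)) return(NULL)
    best
  }

  pts <- scan_once(pi / 12)
  if (is.null(pts)) pts <- scan_once(pi / 4)  # alternate scan lines
  if (is.null(pts)) abort("FOV not detected: could not find three non-collinear edge points")
  colnames(pts) <- c("x", "y")
  attr(pts, "confidence") <- "high"
  pts
}

collinear <- function(pts, tol = 1e-9) {
  a <- pts[1, ]; b <- pts[2, ]; c <- pts[3, ]
  abs((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])) <
    tol * (1 + max(abs(pts)))
}

#' Circumscribed circle through three points
#'
#' Closed-form circumcentre: the intersection of the perpendicular bisectors
#' of the chords, i.e. the standard circle `(x - cx)^2 + (y - cy)^2 = r^2`
#' through all three points.
#'
#' @param p1,p2,p3 Numeric `(x, y)` pairs, not collinear.
#' @return A [circle_fov()].
#' @export
#' @examples
#' circumcircle(c(0, 1), c(1, 0), c(0, -1))  # unit circle at the origin
circumcircle <- function(p1, p2, p3) {
  pts <- rbind(p1, p2, p3)
  stopifnot(ncol(pts) == 2, nrow(pts) == 3)
  dimnames(pts) <- NULL
  ax <- pts[1, 1]; ay <- pts[1, 2]
  bx <- pts[2, 1]; by <- pts[2, 2]
  cx <- pts[3, 1]; cy <- pts[3, 2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-9 * (1 + max(abs(pts))^2)) {
    abort("degenerate circle: the three points are collinear")
  }
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  circle_fov(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
}

#' Trim a field image to its circular field of view
#'
#' Crops the image to the bounding box of the FOV circle (intersected with
#' the frame) and zeroes every pixel outside the circle, so downstream
#' thresholding only ever sees illuminated pixels. The circle parameters,
#' re-expressed in the cropped coordinate frame, are stored in the returned
#' image's `fov` field.
#'
#' @param image A [field_image()].
#' @param fov A [circle_fov()] in the coordinates of `image`.
#' @return A cropped [field_image()] with `fov` set.
#' @export
trim_to_fov <- function(image, fov) {
  stopifnot(inherits(image, "field_image"), inherits(fov, "circle_fov"))
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  x0 <- max(1L, floor(fov$cx - fov$radius))
  x1 <- min(W, ceiling(fov$cx + fov$radius))
  y0 <- max(1L, floor(fov$cy - fov$radius))
  y1 <- min(H, ceiling(fov$cy + fov$radius))
  if (x0 > x1 || y0 > y1) abort("FOV circle lies entirely outside the image")
  px <- image$pixels[y0:y1, x0:x1, , drop = FALSE]
  cx <- fov$cx - x0 + 1; cy <- fov$cy - y0 + 1
  dist <- sqrt(outer((seq_len(nrow(px)) - cy)^2, (seq_len(ncol(px)) - cx)^2, `+`))
  outside <- dist > fov$radius
  for (k in 1:3) {
    ch <- px[, , k]
    ch[outside] <- 0
    px[, , k] <- ch
  }
  field_image(px, pixel_scale = image$pixel_scale,
              source_id = image$source_id,
              fov = circle_fov(cx, cy, fov$radius))
}
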