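#' Plot a synthetic or acquired field image
#'
#' Renders the RGB frame (optionally downsampled for speed) with optional
#' ground-truth overlays: the FOV circle and cell centroids coloured by
#' atypia label.
#'
#' @param image A [field_image()].
#' @param truth Optional `field_truth` to overlay.
#' @param downsample Integer stride for display (default 4).
#' @return A ggplot object.
#' @export
plot_field <- function(image, truth = NULL, downsample = 4) {
  px <- image$pixels[seq(1, dim(image$pixels)[1], by = downsample),
                     seq(1, dim(image$pixels)[2], by = downsample), ,
                     drop = FALSE]
  H <- dim(image$pixels)[1]; W <- dim(image$pixels)[2]
  rast <- grDevices::rgb(px[, , 1] / 255, px[, , 2] / 255, px[, , 3] / 255)
  dim(rast) <- dim(px)[1:2]
  p <- ggplot2::ggplot() +
    ggplot2::annotation_raster(rast, xmin = 0.5, xmax = W + 0.5,
                               ymin = -(H + 0.5), ymax = -0.5) +
    ggplot2::coord_fixed(xlim = c(0, W), ylim = c(-H, 0), expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "y (px)", title = image$source_id) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    th <- seq(0, 2 * pi, length.out = 181)
    circ <- tibble(x = truth$fov$cx + truth$fov$radius * cos(th),
                   y = -(truth$fov$cy + truth$fov$radius * sin(th)))
    p <- p + ggplot2::geom_path(data = circ,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                colour = "orange", linewidth = 0.4)
    if (nrow(truth$cells) > 0) {
      cells <- mutate(truth$cells, y = -.data$cy,
                      label = ifelse(.data$atypical, "atypical", "normal"))
      p <- p + ggplot2::geom_point(
        data = cells,
        ggplot2::aes(x = .data$cx, y = .data$y, colour = .data$label),
        shape = 3, size = 2) +
        ggplot2::scale_colour_manual(
          values = c(normal = "steelblue", atypical = "red"), name = NULL)
    }
  }
  p
}

#' Histogram of per-cell atypia scores by reporting bin
#'
#' @param scores Tibble from [score_cells()] (or any frame with `score`).
#' @param binwidth Histogram bin width (default 0.05).
#' @return A ggplot object.
#' @export
plot_score_distribution <- function(scores, binwidth = 0.05) {
  df <- mutate(as_tibble(scores), bin = assign_bin(.data$score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$bin)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            colour = "grey30", linewidth = 0.1) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1,
                               name = "score bin") +
    ggplot2::labs(x = "atypia score", y = "cells") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cyto_roc <- function(object, ...) {
  best <- object$points[which.min(abs(object$points$threshold -
                                        object$youden_cutoff)), ]
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point(data = best, colour = "red", size = 2) +
    ggplot2::annotate("text", x = 0.7, y = 0.1,
                      label = sprintf("AUC = %.3f\ncutoff = %.3f (J = %.2f)",
                                      object$auc, object$youden_cutoff,
                                      object$youden_j)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cyto_cascade <- function(object, records = NULL, ...) {
  if (is.null(records)) abort("provide `records` to plot the decision plane")
  t1 <- object$test1
  # decision line in original units: w1*(x-c1)/s1 + w2*(y-c2)/s2 + b = 0
  w <- t1$weights / t1$scale
  b0 <- t1$intercept - sum(t1$weights * t1$center / t1$scale)
  df <- as_tibble(records)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_all,
                                        y = .data$pct_atypical)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 2)
  if (abs(w[2]) > 1e-12) {
    p <- p + ggplot2::geom_abline(slope = -w[1] / w[2], intercept = -b0 / w[2],
                                  linetype = "dashed")
  } else {
    p <- p + ggplot2::geom_vline(xintercept = -b0 / w[1], linetype = "dashed")
  }
  p + ggplot2::labs(x = "mean score of all cells", y = "% atypical cells",
                    subtitle = sprintf("Test-2 cutoff on mean atypical score: %.3f",
                                       object$test2$cutoff)) +
    ggplot2::theme_minimal()
}
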