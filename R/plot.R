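#' Display a detection image with optional boxes
#'
#' @param x A `detection_image`.
#' @param boxes Optional corner-form box data frame to overlay (ground
#'   truth or detections).
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.detection_image <- function(x, boxes = NULL, main = "", ...) {
  h <- nrow(x$pixels); w <- ncol(x$pixels)
  graphics::image(x = seq_len(w) - 0.5, y = seq_len(h) - 0.5,
                  z = t(x$pixels[rev(seq_len(h)), , drop = FALSE]),
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  xlab = "x [px]", ylab = "y [px]", main = main,
                  useRaster = TRUE, asp = 1, ...)
  if (!is.null(boxes) && nrow(boxes) > 0) {
    graphics::rect(boxes$x1, h - boxes$y2, boxes$x2, h - boxes$y1,
                   border = "red", lwd = 2)
  }
  invisible(x)
}

#' Precision-recall curve of a metrics report
#'
#' @param x A `metrics_report` from [evaluate_detections()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.metrics_report <- function(x, ...) {
  graphics::plot(x$pr$recall, x$pr$precision, type = "s",
                 xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Recall", ylab = "Precision",
                 main = sprintf("AP@0.5 = %.1f%%", x$ap), ...)
  invisible(x)
}

#' Range-projected view of an image volume
#'
#' @param x An `image_volume`.
#' @param mode Projection mode for [project_to_image()].
#' @param ... Passed on to [plot.detection_image()].
#' @return Invisibly, `x`.
#' @export
plot.image_volume <- function(x, mode = "max", ...) {
  plot(project_to_image(x, mode), ...)
  invisible(x)
}
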