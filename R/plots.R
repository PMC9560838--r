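#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

frame_raster_df <- function(m, value = "intensity") {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
  names(df)[3] <- value
  df
}

#' Plot a synthetic echo frame with its label and tip
#'
#' Grayscale image with the catheter mask outlined and the ground-truth tip
#' marked. The row axis is reversed so depth increases downward, as on a
#' scanner display.
#'
#' @param object An `echo_frame`.
#' @param show_mask Overlay the ground-truth catheter pixels.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.echo_frame <- function(object, show_mask = TRUE, ...) {
  df <- frame_raster_df(object$image)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (px)", y = "row (px)", fill = "intensity") +
    ggplot2::theme_minimal()
  if (show_mask && any(object$mask > 0)) {
    mdf <- frame_raster_df(object$mask, "fg")
    mdf <- dplyr::filter(mdf, .data$fg > 0)
    p <- p + ggplot2::geom_tile(data = mdf, fill = "orange", alpha = 0.45)
  }
  p + ggplot2::annotate("point", x = object$tip_pixel[2],
                        y = object$tip_pixel[1], colour = "red", shape = 3,
                        size = 3)
}

#' Plot training and validation Dice-loss curves
#'
#' @param object A `unet_fit`.
#' @param ... Unused.
#' @return A ggplot object with one line per split and the best validation
#'   iteration marked.
#' @export
autoplot.unet_fit <- function(object, ...) {
  ggplot2::ggplot(object$history,
                  ggplot2::aes(x = .data$iteration, y = .data$dice_loss,
                               colour = .data$split)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = object$best_iteration,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "iteration", y = "Dice loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-frame tracking performance
#'
#' Dice accuracy and tip error (px) across the frames of a tracked
#' sequence; missing detections appear as gaps.
#'
#' @param object A `track_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.track_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$per_frame,
    cols = c("dice_accuracy", "tip_error_px"),
    names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame_index,
                                     y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "frame", y = NULL) +
    ggplot2::theme_minimal()
}
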