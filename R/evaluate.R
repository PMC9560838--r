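#' Extract the catheter tip from a binary mask
#'
#' Selects the largest 8-connected component (ties broken deterministically
#' by scan order, i.e. topmost-leftmost first occurrence), computes its
#' principal axis from the covariance of its pixel coordinates, and takes
#' the two extremal foreground pixels along that axis as tip candidates.
#' With a `reference` point (for example the EM-mapped tip from
#' [map_tip_to_image()]) the nearer candidate wins; without one, the
#' candidate deeper in the image (larger row) is returned, matching the
#' downward-pointing catheter convention.
#'
#' @param mask Binary matrix.
#' @param reference Optional `(row, col)` prior for the tip.
#' @return `(row, col)` of the tip, or `NULL` for an empty mask.
#' @export
extract_tip <- function(mask, reference = NULL) {
  stopifnot(is.matrix(mask))
  if (!any(mask > 0)) return(NULL)
  lab <- label_components8(1 * (mask > 0))
  sizes <- tabulate(lab[lab > 0])
  biggest <- which.max(sizes)   # first maximum = topmost-leftmost seed
  pix <- which(lab == biggest, arr.ind = TRUE)
  if (nrow(pix) == 1) return(as.numeric(pix[1, ]))
  ctr <- colMeans(pix)
  cv <- stats::cov(pix)
  axis <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  proj <- as.numeric((pix[, 1] - ctr[1]) * axis[1] +
                       (pix[, 2] - ctr[2]) * axis[2])
  cand <- rbind(pix[which.min(proj), ], pix[which.max(proj), ])
  if (!is.null(reference)) {
    d <- (cand[, 1] - reference[1])^2 + (cand[, 2] - reference[2])^2
    return(as.numeric(cand[which.min(d), ]))
  }
  as.numeric(cand[which.max(cand[, 1]), ])
}

#' Tip localisation error
#'
#' Euclidean distance between predicted and ground-truth tips, in pixels and
#' (via the pixel spacing) millimetres. A missing prediction propagates as
#' `NA`.
#'
#' @param predicted_tip,gt_tip `(row, col)` coordinates; `predicted_tip` may
#'   be `NULL` (missing detection).
#' @param pixel_spacing mm per pixel.
#' @return A list with `px` and `mm`.
#' @export
tip_error <- function(predicted_tip, gt_tip, pixel_spacing = 1) {
  if (is.null(predicted_tip) || anyNA(predicted_tip)) {
    return(list(px = NA_real_, mm = NA_real_))
  }
  px <- sqrt(sum((predicted_tip - gt_tip)^2))
  list(px = px, mm = px * pixel_spacing)
}

#' Track the catheter tip across a frame sequence
#'
#' Runs segmentation, tip extraction and Dice scoring on every frame of a
#' sequence and aggregates the summary statistics (mean/max/min Dice, mean
#' tip error, number of frames with no detection).
#'
#' @param model A trained `unet_model` or `unet_fit`.
#' @param frames An `echo_sequence` or list of `echo_frame`s sharing one
#'   geometry.
#' @param reference_tips Optional data frame (or matrix) with one
#'   `(row, col)` prior per frame, e.g. EM-mapped tip locations; used to
#'   disambiguate the tip end of each predicted component.
#' @return An object of class `track_report`: list with `per_frame` (tibble:
#'   `frame_index, pred_row, pred_col, gt_row, gt_col, dice_accuracy,
#'   tip_error_px, tip_error_mm, missing`), `summary` (list with
#'   `mean_dice, max_dice, min_dice, mean_tip_error_px, mean_tip_error_mm`)
#'   and `n_missing`.
#' @export
track_sequence <- function(model, frames, reference_tips = NULL) {
  if (length(frames) == 0) stop("empty frame sequence", call. = FALSE)
  if (inherits(model, "unet_fit")) model <- model$model
  spacing <- frames[[1]]$geometry$pixel_spacing
  rows <- purrr::map(seq_along(frames), function(i) {
    fr <- frames[[i]]
    pred <- predict(model, fr)
    ref <- if (!is.null(reference_tips)) {
      as.numeric(unlist(reference_tips[i, c(1, 2)]))
    }
    score_frame(pred, fr, spacing, ref)
  })
  per_frame <- dplyr::bind_rows(rows)
  new_track_report(per_frame)
}

#' Score already-predicted masks against ground truth
#'
#' The evaluation half of [track_sequence()] for externally produced masks
#' (e.g. read from disk): Dice accuracy, tip extraction and tip error per
#' frame.
#'
#' @param predictions List of binary mask matrices, one per frame.
#' @param frames Matching list of `echo_frame`s carrying ground truth.
#' @param reference_tips Optional per-frame `(row, col)` priors.
#' @return A `track_report` (see [track_sequence()]).
#' @export
evaluate_predictions <- function(predictions, frames,
                                 reference_tips = NULL) {
  stopifnot(length(predictions) == length(frames))
  if (length(frames) == 0) stop("empty frame sequence", call. = FALSE)
  spacing <- frames[[1]]$geometry$pixel_spacing
  rows <- purrr::map(seq_along(frames), function(i) {
    ref <- if (!is.null(reference_tips)) {
      as.numeric(unlist(reference_tips[i, c(1, 2)]))
    }
    score_frame(predictions[[i]], frames[[i]], spacing, ref)
  })
  new_track_report(dplyr::bind_rows(rows))
}

score_frame <- function(pred, fr, spacing, ref = NULL) {
  gt_tip <- fr$tip_pixel
  ptip <- extract_tip(pred, reference = ref)
  err <- tip_error(ptip, gt_tip, spacing)
  tibble::tibble(
    frame_index = fr$frame_index,
    pred_row = if (is.null(ptip)) NA_real_ else ptip[1],
    pred_col = if (is.null(ptip)) NA_real_ else ptip[2],
    gt_row = gt_tip[1], gt_col = gt_tip[2],
    dice_accuracy = dice_accuracy(pred, fr$mask),
    tip_error_px = err$px, tip_error_mm = err$mm,
    missing = is.null(ptip)
  )
}

new_track_report <- function(per_frame) {
  structure(list(
    per_frame = per_frame,
    summary = list(
      mean_dice = mean(per_frame$dice_accuracy),
      max_dice = max(per_frame$dice_accuracy),
      min_dice = min(per_frame$dice_accuracy),
      mean_tip_error_px = mean(per_frame$tip_error_px, na.rm = TRUE),
      mean_tip_error_mm = mean(per_frame$tip_error_mm, na.rm = TRUE)
    ),
    n_missing = sum(per_frame$missing)
  ), class = "track_report")
}

#' @export
print.track_report <- function(x, ...) {
  cat(sprintf(
    "<track_report: %d frames, %d missing, Dice mean %.3f [%.3f, %.3f], mean tip error %.2f mm>\n",
    nrow(x$per_frame), x$n_missing, x$summary$mean_dice,
    x$summary$min_dice, x$summary$max_dice, x$summary$mean_tip_error_mm))
  invisible(x)
}

#' Per-frame rows of a track report
#' @param x A `track_report`.
#' @param ... Unused.
#' @return The `per_frame` tibble.
#' @export
tidy.track_report <- function(x, ...) {
  x$per_frame
}

#' One-row summary of a track report
#' @param x A `track_report`.
#' @param ... Unused.
#' @return Tibble with `n_frames`, `n_missing`, `mean_dice`, `max_dice`,
#'   `min_dice`, `mean_tip_error_px`, `mean_tip_error_mm`.
#' @export
glance.track_report <- function(x, ...) {
  tibble::tibble(n_frames = nrow(x$per_frame), n_missing = x$n_missing,
                 mean_dice = x$summary$mean_dice,
                 max_dice = x$summary$max_dice,
                 min_dice = x$summary$min_dice,
                 mean_tip_error_px = x$summary$mean_tip_error_px,
                 mean_tip_error_mm = x$summary$mean_tip_error_mm)
}

#' Write a track report as JSON
#'
#' @param report A `track_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_report <- function(report, path) {
  stopifnot(inherits(report, "track_report"))
  jsonlite::write_json(list(
    per_frame = report$per_frame,
    summary = report$summary,
    n_missing = report$n_missing
  ), path, auto_unbox = TRUE, digits = NA, dataframe = "rows", na = "null")
  invisible(path)
}
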