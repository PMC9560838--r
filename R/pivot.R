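#' Build the stacked pivot-calibration least-squares system
#'
#' Each valid pose contributes the rigid pivot constraint
#' \eqn{R_i \, p_{offset} + t_i = p_{fix}}, rewritten as the block row
#' \eqn{[R_i \; | \; -I] \, (p_{offset}, p_{fix}) = -t_i}. Stacking N poses
#' gives a 3N x 6 design matrix and a 3N right-hand side.
#'
#' @param poses Pose tibble (see [validate_pose_log()]); at least 3 poses.
#' @return An object of class `stacked_system`: list with `design` (3N x 6)
#'   and `rhs` (length 3N, mm).
#' @export
build_stacked_system <- function(poses) {
  validate_pose_log(poses)
  n <- nrow(poses)
  if (n < 3) {
    stop("insufficient data: pivot calibration needs at least 3 poses",
         call. = FALSE)
  }
  design <- matrix(0, nrow = 3 * n, ncol = 6)
  rhs <- numeric(3 * n)
  for (i in seq_len(n)) {
    R <- quaternion_to_rotation(
      c(poses$q0[i], poses$qx[i], poses$qy[i], poses$qz[i]))
    rows <- (3 * i - 2):(3 * i)
    design[rows, 1:3] <- R
    design[rows, 4:6] <- -diag(3)
    rhs[rows] <- -c(poses$tx[i], poses$ty[i], poses$tz[i])
  }
  structure(list(design = design, rhs = rhs, n_poses = n),
            class = "stacked_system")
}

#' Solve a pivot calibration by stacked least squares
#'
#' Recovers the sensor-to-tip offset `p_offset` (sensor frame) and the fixed
#' pivot point `p_fix` (tracker frame) as the minimum-norm least-squares
#' solution of the stacked system built by [build_stacked_system()], using a
#' singular-value pseudo-inverse with relative cutoff `1e-10`. Per-pose
#' residuals are the Euclidean norms of
#' \eqn{R_i \, p_{offset} + t_i - p_{fix}}.
#'
#' Pose sets whose rotations are (numerically) all identical leave the tip
#' offset unobservable; these raise a degenerate-motion error instead of
#' returning an arbitrary minimum-norm answer.
#'
#' @param poses Pose tibble with at least 3 poses of varied orientation.
#' @param min_condition_warn Emit a warning when the design-matrix condition
#'   number exceeds this threshold (poorly excited motion).
#' @param trim_outliers If `TRUE`, refit once after discarding the worst 5%
#'   of poses by residual. Off by default: the reference procedure uses all
#'   recorded poses.
#' @return An object of class `pivot_calibration`: list with `p_offset`,
#'   `p_fix` (mm), `rms_residual` (mm), `per_pose_residuals` (mm),
#'   `condition_number`, `n_poses`.
#' @examples
#' sim <- simulate_pivot_motion(c(10, 5, 20), c(0, 0, -50), 100,
#'                              noise_sd = 0, seed = 7)
#' fit <- solve_pivot(sim$poses)
#' glance(fit)
#' @export
solve_pivot <- function(poses, min_condition_warn = 1e6,
                        trim_outliers = FALSE) {
  sys <- build_stacked_system(poses)
  sol <- solve_stacked(sys)
  if (trim_outliers && sys$n_poses >= 10) {
    res <- per_pose_residuals(poses, sol$x)
    keep <- res <= stats::quantile(res, 0.95)
    poses <- poses[keep, , drop = FALSE]
    sys <- build_stacked_system(poses)
    sol <- solve_stacked(sys)
  }
  if (sol$condition_number > min_condition_warn) {
    warning(sprintf(
      "ill-conditioned pivot motion (condition number %.3g): rotate the tool over a wider range",
      sol$condition_number), call. = FALSE)
  }
  res <- per_pose_residuals(poses, sol$x)
  structure(list(
    p_offset = sol$x[1:3],
    p_fix = sol$x[4:6],
    rms_residual = sqrt(mean(res^2)),
    per_pose_residuals = res,
    condition_number = sol$condition_number,
    n_poses = nrow(poses)
  ), class = "pivot_calibration")
}

# Minimum-norm least squares via SVD pseudo-inverse, relative cutoff 1e-10.
# Rank below 6 means the rotations do not excite the offset: degenerate.
solve_stacked <- function(sys, rel_cutoff = 1e-10) {
  sv <- svd(sys$design)
  keep <- sv$d > rel_cutoff * sv$d[1]
  if (sum(keep) < 6) {
    stop(paste0(
      "degenerate motion: the recorded rotations are (numerically) ",
      "identical, so the tip offset is unobservable; re-record while ",
      "pivoting the tool about its tip"), call. = FALSE)
  }
  x <- sv$v %*% ((crossprod(sv$u, sys$rhs))[, 1] / sv$d)
  list(x = as.numeric(x), condition_number = sv$d[1] / sv$d[6])
}

per_pose_residuals <- function(poses, x) {
  p_offset <- x[1:3]
  p_fix <- x[4:6]
  vapply(seq_len(nrow(poses)), function(i) {
    R <- quaternion_to_rotation(
      c(poses$q0[i], poses$qx[i], poses$qy[i], poses$qz[i]))
    t <- c(poses$tx[i], poses$ty[i], poses$tz[i])
    sqrt(sum((as.numeric(R %*% p_offset) + t - p_fix)^2))
  }, numeric(1))
}

#' Tracked tip position in the tracker frame
#'
#' Applies the calibrated sensor-to-tip offset to each pose:
#' \eqn{tip_i = R_i \, p_{offset} + t_i}. During noiseless pivoting this is
#' constant and equal to the pivot point.
#'
#' @param poses Pose tibble.
#' @param p_offset Calibrated offset (mm), length 3, e.g.
#'   `solve_pivot(...)$p_offset`.
#' @return A tibble with columns `timestamp, tip_x, tip_y, tip_z` (mm).
#' @export
tip_position <- function(poses, p_offset) {
  validate_pose_log(poses)
  stopifnot(length(p_offset) == 3, all(is.finite(p_offset)))
  tips <- t(vapply(seq_len(nrow(poses)), function(i) {
    R <- quaternion_to_rotation(
      c(poses$q0[i], poses$qx[i], poses$qy[i], poses$qz[i]))
    as.numeric(R %*% p_offset) + c(poses$tx[i], poses$ty[i], poses$tz[i])
  }, numeric(3)))
  tibble::tibble(timestamp = poses$timestamp,
                 tip_x = tips[, 1], tip_y = tips[, 2], tip_z = tips[, 3])
}

#' @export
print.pivot_calibration <- function(x, ...) {
  cat(calibration_report(x), sep = "\n")
  invisible(x)
}

#' Human-readable pivot-calibration summary
#'
#' @param result A `pivot_calibration` object.
#' @return Character vector of report lines (also used by the `print`
#'   method). The offset magnitude line is the quantity comparable to a
#'   physically measured tip length.
#' @export
calibration_report <- function(result) {
  stopifnot(inherits(result, "pivot_calibration"))
  c(
    "Pivot calibration",
    sprintf("  Poses used:        %d", result$n_poses),
    sprintf("  Tip offset (mm):   [%.4f, %.4f, %.4f] (sensor frame)",
            result$p_offset[1], result$p_offset[2], result$p_offset[3]),
    sprintf("  Offset magnitude:  %.4f mm", sqrt(sum(result$p_offset^2))),
    sprintf("  Pivot point (mm):  [%.4f, %.4f, %.4f] (tracker frame)",
            result$p_fix[1], result$p_fix[2], result$p_fix[3]),
    sprintf("  RMS residual: %.3f mm", result$rms_residual),
    sprintf("  Condition number:  %.3g", result$condition_number)
  )
}

#' Write a calibration result as JSON
#'
#' Schema: `{p_offset, p_offset_norm_mm, p_fix, rms_residual_mm, n_poses,
#' condition_number}`.
#'
#' @param result A `pivot_calibration` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(result, path) {
  stopifnot(inherits(result, "pivot_calibration"))
  jsonlite::write_json(list(
    p_offset = result$p_offset,
    p_offset_norm_mm = sqrt(sum(result$p_offset^2)),
    p_fix = result$p_fix,
    rms_residual_mm = result$rms_residual,
    per_pose_residuals_mm = result$per_pose_residuals,
    n_poses = result$n_poses,
    condition_number = result$condition_number
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration result written by [write_calibration_json()]
#' @param path JSON path.
#' @return A `pivot_calibration` object.
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(
    p_offset = as.numeric(j$p_offset),
    p_fix = as.numeric(j$p_fix),
    rms_residual = j$rms_residual_mm,
    per_pose_residuals = as.numeric(j$per_pose_residuals_mm),
    condition_number = j$condition_number,
    n_poses = j$n_poses
  ), class = "pivot_calibration")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a pivot calibration: one row per estimated coordinate
#'
#' @param x A `pivot_calibration` object.
#' @param ... Unused.
#' @return Tibble with columns `term` and `estimate` (mm).
#' @export
tidy.pivot_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("p_offset_x", "p_offset_y", "p_offset_z",
             "p_fix_x", "p_fix_y", "p_fix_z"),
    estimate = c(x$p_offset, x$p_fix)
  )
}

#' One-row summary of a pivot calibration
#'
#' @param x A `pivot_calibration` object.
#' @param ... Unused.
#' @return Tibble with `n_poses`, `p_offset_norm_mm`, `rms_residual_mm`,
#'   `condition_number`.
#' @export
glance.pivot_calibration <- function(x, ...) {
  tibble::tibble(
    n_poses = x$n_poses,
    p_offset_norm_mm = sqrt(sum(x$p_offset^2)),
    rms_residual_mm = x$rms_residual,
    condition_number = x$condition_number
  )
}
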