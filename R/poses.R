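#' Normalize a quaternion to unit norm with a fixed sign convention
#'
#' Scales a scalar-first quaternion `(q0, qx, qy, qz)` to unit norm and flips
#' its sign so that `q0 >= 0`. Both `q` and `-q` encode the same rotation, so
#' the sign convention makes stored poses canonical.
#'
#' @param q Numeric vector of length 4, scalar-first `(q0, qx, qy, qz)`.
#' @return A unit-norm numeric vector of length 4 with `q[1] >= 0`.
#' @examples
#' normalize_quaternion(c(2, 0, 0, 0))
#' normalize_quaternion(c(1, 1, 1, 1))
#' @export
normalize_quaternion <- function(q) {
  if (length(q) != 4 || !is.numeric(q)) {
    stop("`q` must be a numeric vector of length 4 (q0, qx, qy, qz)",
         call. = FALSE)
  }
  nrm <- sqrt(sum(q^2))
  if (!is.finite(nrm) || nrm == 0) {
    stop("invalid pose: quaternion has zero or non-finite norm", call. = FALSE)
  }
  q <- q / nrm
  if (q[1] < 0) q <- -q
  q
}

#' Convert a unit quaternion to a 3x3 rotation matrix
#'
#' Standard scalar-first unit-quaternion-to-matrix formula. The returned
#' matrix is orthonormal with determinant +1.
#'
#' @param q Unit-norm numeric vector of length 4, scalar-first.
#' @param tol Tolerance on `|q| - 1` before the input is rejected.
#' @return A 3x3 rotation matrix.
#' @examples
#' quaternion_to_rotation(c(1, 0, 0, 0))      # identity
#' quaternion_to_rotation(c(0, 1, 0, 0))      # 180 degrees about x
#' @export
quaternion_to_rotation <- function(q, tol = 1e-6) {
  if (length(q) != 4 || !is.numeric(q)) {
    stop("`q` must be a numeric vector of length 4", call. = FALSE)
  }
  if (abs(sqrt(sum(q^2)) - 1) > tol) {
    stop("`q` must be unit-norm (use normalize_quaternion())", call. = FALSE)
  }
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix back to a unit quaternion
#'
#' Inverse of [quaternion_to_rotation()], using the numerically stable
#' largest-pivot (Shepperd) branch selection. Returns the scalar-first
#' quaternion with `q0 >= 0`.
#'
#' @param R A 3x3 rotation matrix.
#' @return Unit quaternion of length 4.
#' @export
rotation_to_quaternion <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] >= R[2, 2] && R[1, 1] >= R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] >= R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  normalize_quaternion(q)
}

pose_log_columns <- c("timestamp", "q0", "qx", "qy", "qz",
                      "tx", "ty", "tz", "status")

new_pose_log <- function(df, source = NA_character_, frame_id = "tracker") {
  out <- tibble::as_tibble(df)
  attr(out, "source") <- source
  attr(out, "frame_id") <- frame_id
  class(out) <- c("pose_log", class(out))
  out
}

#' Validate a 6-DOF pose log
#'
#' Checks the invariants of a pose table: required columns present, at least
#' one pose, non-decreasing timestamps, unit-norm quaternions (to 1e-6) and
#' finite translations. Called internally by every consumer of pose logs.
#'
#' @param poses A data frame with columns
#'   `timestamp, q0, qx, qy, qz, tx, ty, tz` (translations in mm).
#' @return The validated tibble, invisibly.
#' @export
validate_pose_log <- function(poses) {
  need <- setdiff(pose_log_columns, c("status"))
  missing <- setdiff(need, names(poses))
  if (length(missing) > 0) {
    stop("pose log is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(poses) < 1) stop("pose log must contain at least one pose",
                            call. = FALSE)
  if (is.unsorted(poses$timestamp)) {
    stop("pose log timestamps must be non-decreasing", call. = FALSE)
  }
  qn <- sqrt(poses$q0^2 + poses$qx^2 + poses$qy^2 + poses$qz^2)
  if (any(abs(qn - 1) > 1e-6)) {
    stop("pose log contains non-unit quaternions; normalize on ingest",
         call. = FALSE)
  }
  tmat <- as.matrix(poses[, c("tx", "ty", "tz")])
  if (!all(is.finite(tmat))) {
    stop("pose log contains non-finite translations", call. = FALSE)
  }
  invisible(tibble::as_tibble(poses))
}

#' Parse an EM tracker pose log
#'
#' Reads the plain-text pose log dialect written by the tracker export:
#' a header line `timestamp,q0,qx,qy,qz,tx,ty,tz,status` followed by one
#' comma-separated record per line. Records with `status` `MISSING` (sensor
#' out of the field) are dropped with a warning that reports the count;
#' quaternions are normalized on ingest.
#'
#' @param path Path to the CSV file, or a character vector of lines.
#' @return A `pose_log` tibble with columns
#'   `timestamp, q0, qx, qy, qz, tx, ty, tz` (translations in mm).
#' @seealso [write_pose_log()], [simulate_pivot_motion()]
#' @export
parse_pose_log <- function(path) {
  lines <- if (length(path) == 1 && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty pose log", call. = FALSE)
  header <- strsplit(trimws(lines[1]), ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), pose_log_columns)) {
    stop("malformed pose log header (line 1): expected `",
         paste(pose_log_columns, collapse = ","), "`", call. = FALSE)
  }
  if (length(lines) == 1) stop("pose log has a header but no records",
                               call. = FALSE)
  rec <- strsplit(trimws(lines[-1]), ",", fixed = TRUE)
  rows <- purrr::imap(rec, function(fields, i) {
    lineno <- i + 1
    if (length(fields) != 9) {
      stop("parse error at line ", lineno, ": expected 9 fields, got ",
           length(fields), call. = FALSE)
    }
    status <- trimws(fields[9])
    if (!status %in% c("OK", "MISSING")) {
      stop("parse error at line ", lineno, ": status must be OK or MISSING",
           call. = FALSE)
    }
    num <- suppressWarnings(as.numeric(fields[1:8]))
    if (anyNA(num)) {
      stop("parse error at line ", lineno, ": non-numeric field", call. = FALSE)
    }
    c(num, status == "OK")
  })
  m <- do.call(rbind, rows)
  ok <- m[, 9] == 1
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    warning(n_dropped, " record(s) flagged MISSING were dropped",
            call. = FALSE)
  }
  m <- m[ok, , drop = FALSE]
  if (nrow(m) == 0) {
    df <- tibble::tibble(timestamp = double(), q0 = double(), qx = double(),
                         qy = double(), qz = double(), tx = double(),
                         ty = double(), tz = double())
    return(new_pose_log(df))
  }
  qs <- t(apply(m[, 2:5, drop = FALSE], 1, normalize_quaternion))
  df <- tibble::tibble(
    timestamp = m[, 1],
    q0 = qs[, 1], qx = qs[, 2], qy = qs[, 3], qz = qs[, 4],
    tx = m[, 6], ty = m[, 7], tz = m[, 8]
  )
  validate_pose_log(df)
  new_pose_log(df)
}

#' Write a pose log in the tracker CSV dialect
#'
#' Serializes a pose tibble to the same dialect [parse_pose_log()] reads, so
#' that `parse_pose_log(write_pose_log(x, f))` round-trips. All records are
#' written with status `OK`.
#'
#' @param poses Pose tibble (see [validate_pose_log()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pose_log <- function(poses, path) {
  validate_pose_log(poses)
  lines <- c(paste(pose_log_columns, collapse = ","),
             sprintf("%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g,OK",
                     poses$timestamp, poses$q0, poses$qx, poses$qy, poses$qz,
                     poses$tx, poses$ty, poses$tz))
  writeLines(lines, path)
  invisible(path)
}

#' Draw a rotation uniformly from SO(3)
#'
#' Normalized 4-dimensional Gaussian quaternion method: a standard normal
#' 4-vector, normalized, is uniform on the unit 3-sphere and hence uniform
#' over the rotation group.
#'
#' @return A unit quaternion (scalar-first).
#' @keywords internal
random_unit_quaternion <- function() {
  normalize_quaternion(stats::rnorm(4))
}

#' Simulate a pivot-calibration recording
#'
#' Emulates moving a tracked sensor about a physically fixed pivot point, the
#' motion used to calibrate the sensor-to-tip offset. Each pose gets a random
#' rotation \eqn{R_i} uniform over the rotation group and a translation
#' \eqn{t_i = p_{fix} - R_i \, p_{offset} + \epsilon_i} with isotropic
#' Gaussian noise, so that the rigid pivot constraint
#' \eqn{R_i \, p_{offset} + t_i = p_{fix}} holds exactly at zero noise.
#'
#' @param true_offset Sensor-to-tip offset in the sensor frame (mm), length 3.
#' @param fixed_point Pivot-point location in the tracker frame (mm), length 3.
#' @param n Number of poses to simulate (at least 3).
#' @param noise_sd Standard deviation of isotropic translation noise (mm).
#' @param seed Integer seed; the sequence is reproducible given the seed.
#' @param rate Sampling rate in Hz used to assign timestamps.
#' @return A list with `poses` (a `pose_log` tibble) and `truth`
#'   (list with `true_offset`, `fixed_point`, `noise_sd`, `seed`).
#' @examples
#' sim <- simulate_pivot_motion(c(10, 5, 20), c(0, 0, -50), n = 50,
#'                              noise_sd = 0, seed = 1)
#' fit <- solve_pivot(sim$poses)
#' max(abs(fit$p_offset - sim$truth$true_offset))
#' @export
simulate_pivot_motion <- function(true_offset, fixed_point, n,
                                  noise_sd = 0, seed = NULL, rate = 40) {
  stopifnot(length(true_offset) == 3, length(fixed_point) == 3,
            is.numeric(noise_sd), noise_sd >= 0)
  if (n < 3) {
    stop("degenerate design: pivot calibration needs at least 3 poses",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map(seq_len(n), function(i) {
    q <- random_unit_quaternion()
    R <- quaternion_to_rotation(q)
    t <- as.numeric(fixed_point - R %*% true_offset) +
      stats::rnorm(3, sd = noise_sd)
    c(q, t)
  })
  m <- do.call(rbind, rows)
  df <- tibble::tibble(
    timestamp = (seq_len(n) - 1) / rate,
    q0 = m[, 1], qx = m[, 2], qy = m[, 3], qz = m[, 4],
    tx = m[, 5], ty = m[, 6], tz = m[, 7]
  )
  list(
    poses = new_pose_log(df, source = "simulate_pivot_motion"),
    truth = list(true_offset = as.numeric(true_offset),
                 fixed_point = as.numeric(fixed_point),
                 noise_sd = noise_sd, seed = seed)
  )
}
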