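test_that("quaternion normalization scales, fixes sign, and rejects zeros", {
  expect_equal(normalize_quaternion(c(2, 0, 0, 0)), c(1, 0, 0, 0))
  expect_equal(normalize_quaternion(c(-1, 0, 0, 0)), c(1, 0, 0, 0))
  expect_equal(normalize_quaternion(c(1, 1, 1, 1)), c(0.5, 0.5, 0.5, 0.5))
  expect_error(normalize_quaternion(c(0, 0, 0, 0)), "zero or non-finite")
  set.seed(11)
  for (i in 1:20) {
    q <- normalize_quaternion(rnorm(4))
    expect_equal(sum(q^2), 1, tolerance = 1e-12)
    expect_gte(q[1], 0)
  }
})

test_that("quaternion-to-matrix matches the sandwich-product oracle", {
  expect_equal(quaternion_to_rotation(c(1, 0, 0, 0)), diag(3))
  expect_equal(quaternion_to_rotation(c(0, 1, 0, 0)), diag(c(1, -1, -1)))
  expect_error(quaternion_to_rotation(c(2, 0, 0, 0)), "unit-norm")
  # oracle: rotate a vector via quaternion multiplication q v q*
  quat_mul <- function(a, b) {
    c(a[1] * b[1] - sum(a[2:4] * b[2:4]),
      a[1] * b[2:4] + b[1] * a[2:4] +
        c(a[3] * b[4] - a[4] * b[3],
          a[4] * b[2] - a[2] * b[4],
          a[2] * b[3] - a[3] * b[2]))
  }
  rotate_by_quat <- function(q, v) {
    quat_mul(quat_mul(q, c(0, v)), c(q[1], -q[2:4]))[2:4]
  }
  set.seed(5)
  for (i in 1:25) {
    q <- normalize_quaternion(rnorm(4))
    R <- quaternion_to_rotation(q)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-9)
    expect_equal(det(R), 1, tolerance = 1e-9)
    v <- rnorm(3)
    expect_equal(as.numeric(R %*% v), rotate_by_quat(q, v),
                 tolerance = 1e-12)
  }
})

test_that("matrix-to-quaternion round-trips up to sign", {
  set.seed(9)
  for (i in 1:25) {
    q <- normalize_quaternion(rnorm(4))
    q2 <- rotation_to_quaternion(quaternion_to_rotation(q))
    expect_lt(min(sqrt(sum((q - q2)^2)), sqrt(sum((q + q2)^2))), 1e-9)
  }
})

test_that("pose log parser handles valid rows, MISSING flags, and errors", {
  txt <- c("timestamp,q0,qx,qy,qz,tx,ty,tz,status",
           "0.0,1,0,0,0,1.5,2.5,3.5,OK",
           "0.1,2,0,0,0,0,0,0,OK",
           "0.2,0,1,0,0,-1,-2,-3,OK")
  poses <- parse_pose_log(paste(txt, collapse = "\n"))
  expect_equal(nrow(poses), 3)
  expect_equal(poses$q0[2], 1)   # (2,0,0,0) normalized on ingest
  expect_equal(poses$tx[1], 1.5)

  txt_missing <- c(txt[1], "0.0,1,0,0,0,0,0,0,MISSING")
  expect_warning(empty <- parse_pose_log(paste(txt_missing, collapse = "\n")),
                 "1 record")
  expect_equal(nrow(empty), 0)

  expect_error(parse_pose_log("bad,header\n1,2"), "header")
  bad_field <- paste(c(txt[1], "0.0,1,0,0,0,oops,0,0,OK"), collapse = "\n")
  expect_error(parse_pose_log(bad_field), "line 2")
})

test_that("pose log serialization round-trips exactly", {
  sim <- simulate_pivot_motion(c(4, -3, 12), c(10, 20, -40), 25,
                               noise_sd = 0.3, seed = 13)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pose_log(sim$poses, f)
  back <- parse_pose_log(f)
  expect_equal(as.data.frame(back), as.data.frame(sim$poses),
               tolerance = 1e-15, ignore_attr = TRUE)
})

test_that("simulated pivot motion satisfies the pivot identity at zero noise", {
  off <- c(10, 5, 20)
  fix <- c(0, 0, -50)
  sim <- simulate_pivot_motion(off, fix, 50, noise_sd = 0, seed = 2)
  for (i in c(1, 17, 50)) {
    p <- sim$poses[i, ]
    R <- quaternion_to_rotation(c(p$q0, p$qx, p$qy, p$qz))
    expect_equal(as.numeric(R %*% off) + c(p$tx, p$ty, p$tz), fix,
                 tolerance = 1e-12)
  }
  # zero offset: all translations equal the fixed point
  sim0 <- simulate_pivot_motion(c(0, 0, 0), fix, 10, noise_sd = 0, seed = 3)
  expect_equal(unique(round(sim0$poses$tx, 12)), fix[1])
  expect_equal(unique(round(sim0$poses$tz, 12)), fix[3])
  # reproducibility under a fixed seed
  a <- simulate_pivot_motion(off, fix, 100, noise_sd = 0.5, seed = 42)
  b <- simulate_pivot_motion(off, fix, 100, noise_sd = 0.5, seed = 42)
  expect_identical(a$poses, b$poses)
  expect_error(simulate_pivot_motion(off, fix, 2, seed = 1), "degenerate")
})
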