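test_that("stacked system has the [R | -I] block structure", {
  id <- tibble::tibble(timestamp = 0, q0 = 1, qx = 0, qy = 0, qz = 0,
                       tx = 1, ty = 2, tz = 3)
  poses <- dplyr::bind_rows(id, id, id)
  poses$timestamp <- c(0, 1, 2)
  sys <- build_stacked_system(poses)
  expect_equal(dim(sys$design), c(9, 6))
  expect_equal(sys$design[1:3, 1:3], diag(3))
  expect_equal(sys$design[1:3, 4:6], -diag(3))
  expect_equal(sys$rhs[1:3], -c(1, 2, 3))

  sim <- simulate_pivot_motion(c(1, 2, 3), c(5, 5, 5), 5, seed = 1)
  sys5 <- build_stacked_system(sim$poses)
  expect_equal(dim(sys5$design), c(15, 6))
  expect_equal(length(sys5$rhs), 15)
  # noiseless truth satisfies every block row
  expect_equal(as.numeric(sys5$design %*% c(1, 2, 3, 5, 5, 5)), sys5$rhs,
               tolerance = 1e-12)
  expect_error(build_stacked_system(poses[1:2, ]), "at least 3")
})

test_that("noiseless calibration recovers the tip offset to numerical precision", {
  off <- c(10, 5, 20)
  fix <- c(0, 0, -50)
  sim <- simulate_pivot_motion(off, fix, 100, noise_sd = 0, seed = 7)
  fit <- solve_pivot(sim$poses)
  expect_lt(sqrt(sum((fit$p_offset - off)^2)), 1e-6)
  expect_lt(sqrt(sum((fit$p_fix - fix)^2)), 1e-6)
  expect_lt(fit$rms_residual, 1e-9)
  expect_equal(length(fit$per_pose_residuals), 100)
  expect_equal(fit$rms_residual, sqrt(mean(fit$per_pose_residuals^2)))
})

test_that("zero offset gives zero solution and the mean translation as pivot", {
  sim <- simulate_pivot_motion(c(0, 0, 0), c(3, -4, 12), 50, noise_sd = 0,
                               seed = 5)
  fit <- solve_pivot(sim$poses)
  expect_equal(fit$p_offset, c(0, 0, 0), tolerance = 1e-8)
  expect_equal(fit$p_fix,
               c(mean(sim$poses$tx), mean(sim$poses$ty), mean(sim$poses$tz)),
               tolerance = 1e-8)
})

test_that("identical rotations raise a degenerate-motion error", {
  poses <- tibble::tibble(timestamp = 0:9 / 10, q0 = 1, qx = 0, qy = 0,
                          qz = 0, tx = rnorm(10), ty = rnorm(10),
                          tz = rnorm(10))
  expect_error(solve_pivot(poses), "degenerate motion")
  # any single repeated rotation is equally degenerate
  q <- normalize_quaternion(c(1, 2, 3, 4))
  poses2 <- tibble::tibble(timestamp = 0:9 / 10, q0 = q[1], qx = q[2],
                           qy = q[3], qz = q[4], tx = rnorm(10),
                           ty = rnorm(10), tz = rnorm(10))
  expect_error(solve_pivot(poses2), "degenerate motion")
})

test_that("pseudo-inverse solution matches the normal-equations oracle", {
  set.seed(21)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    sim <- simulate_pivot_motion(runif(3, -20, 20), runif(3, -50, 50), n,
                                 noise_sd = 0.5, seed = 300 + rep)
    sys <- build_stacked_system(sim$poses)
    fit <- solve_pivot(sim$poses)
    if (fit$condition_number < 1e6) {
      x_ne <- solve(crossprod(sys$design), crossprod(sys$design, sys$rhs))
      expect_equal(c(fit$p_offset, fit$p_fix), as.numeric(x_ne),
                   tolerance = 1e-8)
    }
  }
})

test_that("the least-squares solution is a residual minimum", {
  sim <- simulate_pivot_motion(c(7, -2, 15), c(10, 0, -30), 40,
                               noise_sd = 1, seed = 9)
  sys <- build_stacked_system(sim$poses)
  fit <- solve_pivot(sim$poses)
  x <- c(fit$p_offset, fit$p_fix)
  ssr <- function(v) sum((sys$design %*% v - sys$rhs)^2)
  base <- ssr(x)
  for (k in 1:6) {
    for (s in c(-1, 1)) {
      xp <- x
      xp[k] <- xp[k] + s
      expect_gte(ssr(xp), base)
    }
  }
})

test_that("offset error shrinks with more poses under fixed noise", {
  med_err <- vapply(c(10, 100, 1000), function(n) {
    errs <- vapply(1:50, function(r) {
      sim <- simulate_pivot_motion(c(10, 5, 20), c(0, 0, -50), n,
                                   noise_sd = 0.5, seed = 7000 + 50 * n + r)
      fit <- solve_pivot(sim$poses)
      sqrt(sum((fit$p_offset - c(10, 5, 20))^2))
    }, numeric(1))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) <= 0))
})

test_that("tip position applies the offset through each pose", {
  pose <- tibble::tibble(timestamp = 0, q0 = 1, qx = 0, qy = 0, qz = 0,
                         tx = 0, ty = 0, tz = 0)
  expect_equal(unlist(tip_position(pose, c(1, 2, 3))[1, 2:4],
                      use.names = FALSE), c(1, 2, 3))
  rot_x <- tibble::tibble(timestamp = 0, q0 = 0, qx = 1, qy = 0, qz = 0,
                          tx = 0, ty = 0, tz = 0)
  expect_equal(unlist(tip_position(rot_x, c(0, 1, 0))[1, 2:4],
                      use.names = FALSE), c(0, -1, 0), tolerance = 1e-12)
  # during noiseless pivoting the tracked tip is the fixed point, every pose
  sim <- simulate_pivot_motion(c(10, 5, 20), c(0, 0, -50), 30, seed = 4)
  tips <- tip_position(sim$poses, c(10, 5, 20))
  expect_lt(max(abs(tips$tip_x - 0)), 1e-10)
  expect_lt(max(abs(tips$tip_z - (-50))), 1e-10)
})

test_that("calibration report formats and JSON round-trips", {
  res <- structure(list(p_offset = c(3, 4, 0), p_fix = c(1, 1, 1),
                        rms_residual = 0, per_pose_residuals = rep(0, 5),
                        condition_number = 2.5, n_poses = 5),
                   class = "pivot_calibration")
  rep_txt <- calibration_report(res)
  expect_true(any(grepl("RMS residual: 0.000 mm", rep_txt, fixed = TRUE)))
  expect_true(any(grepl("5.0000 mm", rep_txt, fixed = TRUE)))
  f <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(res, f)
  back <- read_calibration_json(f)
  expect_equal(back$p_offset, res$p_offset)
  expect_equal(back$rms_residual, res$rms_residual)
  expect_equal(back$n_poses, res$n_poses)
  expect_equal(tidy(res)$estimate, c(3, 4, 0, 1, 1, 1))
  expect_equal(glance(res)$p_offset_norm_mm, 5)
})
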