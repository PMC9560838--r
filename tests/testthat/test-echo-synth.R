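test_that("sector mask matches the annular-sector area formula", {
  geo <- sector_geometry(image_height = 220, image_width = 300,
                         apex = c(10, 150), opening_angle = 90,
                         min_depth = 40, max_depth = 180, pixel_spacing = 0.5)
  m <- make_sector_mask(geo)
  analytic <- (90 * pi / 180) / 2 * (180^2 - 40^2)
  expect_lt(abs(sum(m) - analytic) / analytic, 0.02)
  expect_lt(sum(m), length(m))   # strictly contained in the image
  # shrinking the opening angle shrinks the area toward zero
  small <- sector_geometry(opening_angle = 2)
  expect_lt(sum(make_sector_mask(small)), sum(make_sector_mask(
    sector_geometry(opening_angle = 70))) / 10)
  expect_error(sector_geometry(opening_angle = 190), "opening_angle")
  expect_error(sector_geometry(min_depth = 100, max_depth = 50), "min_depth")
})

test_that("rendered frames respect mask, sector, and clipping invariants", {
  geo <- synth_geometry()
  sector <- make_sector_mask(geo)
  fr <- render_frame(scene_config(seed = 3), geo, c(100, 80), tip_angle = 10)
  expect_true(all(fr$image >= 0 & fr$image <= 1))
  expect_true(all(fr$mask[!sector] == 0))
  expect_equal(fr$mask[fr$tip_pixel[1], fr$tip_pixel[2]], 1L)
  expect_gt(sum(fr$mask), 0)
  # catheter with zero intensity is invisible and unlabeled
  fr0 <- render_frame(scene_config(seed = 3, catheter_intensity = 0), geo,
                      c(100, 80))
  expect_equal(sum(fr0$mask), 0)
  # placement outside the sector is rejected
  expect_error(render_frame(scene_config(seed = 1), geo, c(1, 1)),
               "outside the sector")
})

test_that("frames are reproducible under a fixed seed", {
  geo <- synth_geometry()
  a <- render_frame(scene_config(seed = 11), geo, c(110, 90))
  b <- render_frame(scene_config(seed = 11), geo, c(110, 90))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
})

test_that("the reverberation artifact is never labeled foreground", {
  geo <- synth_geometry()
  # catheter placed shallow so it cannot cross the artifact band
  band_row <- geo$apex[1] + 0.55 * geo$max_depth
  for (i in 1:100) {
    fr <- render_frame(
      scene_config(seed = i, catheter_length = 30, artifact_intensity = 0.8),
      geo, c(60, 80), tip_angle = 0)
    rows <- max(1, floor(band_row - 2)):min(nrow(fr$mask),
                                            ceiling(band_row + 2))
    expect_equal(sum(fr$mask[rows, ]), 0)
  }
})

test_that("speckle statistics match the multiplicative model", {
  geo <- synth_geometry()
  fr <- render_frame(
    scene_config(seed = 5, catheter_intensity = 0, artifact_intensity = 0,
                 background_structures = 0, speckle_scale = 0.22),
    geo, c(100, 80))
  bg <- fr$image[make_sector_mask(geo)]
  expect_lt(abs(mean(bg) - 0.22) / 0.22, 0.10)
  skew <- mean((bg - mean(bg))^3) / sd(bg)^3
  expect_gt(skew, 0)
})

test_that("sequence simulation keeps trajectory bookkeeping and cadence", {
  geo <- synth_geometry()
  motion <- tibble::tibble(row = seq(90, 117, by = 3), col = seq(70, 88, by = 2))
  seq10 <- simulate_sequence(scene_config(seed = 8), geo, motion,
                             frame_rate = 10)
  expect_length(seq10, 10)
  tips <- t(vapply(seq10, function(f) f$tip_pixel, numeric(2)))
  expect_true(all(diff(tips[, 1]) > 0))   # monotone downward motion
  traj <- attr(seq10, "trajectory")
  expect_equal(traj$time_s, seq(0, 0.9, by = 0.1))   # 0.1 s cadence
  # speckle is temporally incoherent but masks track only the motion
  expect_false(identical(seq10[[1]]$image, seq10[[2]]$image))
  still <- simulate_sequence(scene_config(seed = 8), geo,
                             tibble::tibble(row = c(100, 100),
                                            col = c(80, 80)))
  expect_identical(still[[1]]$mask, still[[2]]$mask)
  expect_error(simulate_sequence(scene_config(seed = 1), geo,
                                 tibble::tibble(row = numeric(0),
                                                col = numeric(0))),
               "at least one")
})

test_that("sequence generation is deterministic given the scene seed", {
  geo <- synth_geometry()
  motion <- tibble::tibble(row = c(100, 105, 110), col = c(80, 82, 84))
  a <- simulate_sequence(scene_config(seed = 31), geo, motion)
  b <- simulate_sequence(scene_config(seed = 31), geo, motion)
  for (i in seq_along(a)) expect_identical(a[[i]]$image, b[[i]]$image)
})

test_that("tracked tips map to pixels with plane and sector flags", {
  geo <- synth_geometry()
  # identity transform, tip on the plane at the apex
  at_apex <- map_tip_to_image(c(0, 0, 0), geometry = geo)
  expect_equal(c(at_apex$row, at_apex$col), geo$apex)
  expect_true(at_apex$in_plane)
  # 10 mm out of plane exceeds the 2 mm tolerance
  off_plane <- map_tip_to_image(c(0, 20, 10), geometry = geo)
  expect_false(off_plane$in_plane)
  # in-plane point inside the fan: mm -> pixel -> mm round trip
  p <- map_tip_to_image(c(5, 40, 0), geometry = geo)
  expect_true(p$in_plane && p$in_sector)
  mm <- pixel_to_mm(p$row, p$col, geo)
  expect_equal(c(mm$lateral_mm, mm$depth_mm), c(5, 40), tolerance = 1e-12)
  px <- mm_to_pixel(mm$lateral_mm, mm$depth_mm, geo)
  expect_equal(c(px$row, px$col), c(p$row, p$col), tolerance = 1e-12)
})

test_that("dataset writer/reader round-trips frames, masks and metadata", {
  geo <- synth_geometry()
  motion <- tibble::tibble(row = c(100, 104, 108), col = c(80, 81, 82))
  frames <- simulate_sequence(scene_config(seed = 17), geo, motion)
  d <- withr::local_tempdir()
  write_echo_dataset(frames, d)
  back <- read_echo_dataset(d)
  expect_length(back, 3)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, frames[[i]]$mask)
    expect_lte(max(abs(back[[i]]$image - frames[[i]]$image)), 1 / 65535)
    expect_equal(back[[i]]$tip_pixel, frames[[i]]$tip_pixel)
  }
  expect_equal(attr(back, "frame_rate"), 10)
  expect_equal(back[[1]]$geometry$pixel_spacing, geo$pixel_spacing)
})
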