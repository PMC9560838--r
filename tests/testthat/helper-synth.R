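# Synthetic fixtures are generated in code. The desk-scale UNet fit is
# trained once per test session and shared by the tests that need a trained
# model (training is the expensive step).

synth_geometry <- function() sector_geometry()

# One random catheter placement inside the sector, away from the fan edges.
random_tip_scene <- function(i, geo = synth_geometry()) {
  row <- stats::runif(1, 60, 140)
  dr <- row - geo$apex[1]
  half <- min(dr * tan(geo$opening_angle / 2 * pi / 180),
              sqrt(max((geo$max_depth - 4)^2 - dr^2, 1)),
              geo$image_width - geo$apex[2] - 2,
              geo$apex[2] - 2) - 6
  col <- geo$apex[2] + stats::runif(1, -half, half)
  list(scene = scene_config(seed = 1000L + i,
                            catheter_curvature = stats::runif(1, -0.25, 0.25)),
       tip = c(row, col),
       angle = stats::runif(1, -25, 25))
}

make_frame_set <- function(n, seed = 101L, geo = synth_geometry()) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    s <- random_tip_scene(i, geo)
    render_frame(s$scene, geo, s$tip, tip_angle = s$angle,
                 frame_index = as.integer(i))
  })
}

# A 10-frame moving-catheter sequence at 10 Hz (0.1 s cadence).
make_tracking_sequence <- function(seed = 202L, geo = synth_geometry()) {
  motion <- tibble::tibble(row = 95 + 2.5 * (0:9),
                           col = 70 + 1.5 * (0:9),
                           angle = 10)
  simulate_sequence(scene_config(seed = seed), geo, motion, frame_rate = 10)
}

.desk_cache <- new.env(parent = emptyenv())

# Desk-scale study: 40 synthetic frames (26 train / 6 validation / 8 test),
# offline augmentation x4 of the training split, depth-3 UNet on 64x64
# patches for up to 600 iterations.
get_desk_study <- function() {
  if (!is.null(.desk_cache$study)) return(.desk_cache$study)
  frames <- make_frame_set(40, seed = 101L)
  cfg <- desk_config()
  train_aug <- augment_dataset(frames[1:26], factor = cfg$augmentation_factor,
                               seed = 7L)
  fit <- train_unet(cfg, train_aug, frames[27:32])
  .desk_cache$study <- list(fit = fit, frames = frames,
                            test_frames = frames[33:40], config = cfg)
  .desk_cache$study
}
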