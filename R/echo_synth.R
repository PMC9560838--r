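#' Sector (fan) geometry of a phased-array ultrasound image
#'
#' Describes the fan-shaped field of view: the apex (virtual transducer
#' position, in pixel coordinates), the opening angle, the radial depth range
#' and the physical pixel spacing. Image coordinates are `(row, col)`,
#' 1-based, row increasing downward (deeper); pixels are isotropic.
#'
#' @param image_height,image_width Image size in pixels.
#' @param apex `(row, col)` of the sector apex.
#' @param opening_angle Full opening angle in degrees, in (0, 180).
#' @param min_depth,max_depth Radial range from the apex, pixels.
#' @param pixel_spacing Physical size of one pixel, mm.
#' @return An object of class `sector_geometry`.
#' @export
sector_geometry <- function(image_height = 160, image_width = 160,
                            apex = c(4, 80), opening_angle = 70,
                            min_depth = 12, max_depth = 150,
                            pixel_spacing = 0.5) {
  if (!(opening_angle > 0 && opening_angle < 180)) {
    stop("opening_angle must be in (0, 180) degrees", call. = FALSE)
  }
  if (!(min_depth < max_depth)) {
    stop("min_depth must be smaller than max_depth", call. = FALSE)
  }
  if (max_depth > sqrt(image_height^2 + image_width^2)) {
    stop("max_depth exceeds the image extent", call. = FALSE)
  }
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive", call. = FALSE)
  structure(list(image_height = image_height, image_width = image_width,
                 apex = apex, opening_angle = opening_angle,
                 min_depth = min_depth, max_depth = max_depth,
                 pixel_spacing = pixel_spacing),
            class = "sector_geometry")
}

#' Scene content parameters for a synthetic echo frame
#'
#' Parameterizes what [render_frame()] draws: the catheter ribbon (a thin
#' bright curvilinear structure; an ablation catheter of ~2.5 mm diameter is
#' about 5 px wide at 0.5 mm/px), a horizontal reverberation artifact band
#' (visible but never labelled), multiplicative speckle, and a few
#' low-contrast elliptical background structures standing in for cardiac
#' anatomy.
#'
#' @param catheter_length Catheter segment length, pixels.
#' @param catheter_width Ribbon width, pixels (>= 1).
#' @param catheter_intensity Peak added intensity of the catheter, in [0, 1];
#'   0 renders no catheter (and an empty mask).
#' @param catheter_curvature Dimensionless bend of the quadratic ribbon;
#'   0 gives a straight segment.
#' @param artifact_intensity Peak added intensity of the reverberation band.
#' @param artifact_depth_frac Band centre depth as a fraction of `max_depth`.
#' @param speckle_scale Mean background intensity of the speckle field.
#' @param background_structures Number of random low-contrast ellipses.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(catheter_length = 60, catheter_width = 5,
                         catheter_intensity = 0.9, catheter_curvature = 0.15,
                         artifact_intensity = 0.5, artifact_depth_frac = 0.55,
                         speckle_scale = 0.22, background_structures = 3,
                         seed = NULL) {
  stopifnot(catheter_width >= 1,
            catheter_intensity >= 0, catheter_intensity <= 1,
            artifact_intensity >= 0, artifact_intensity <= 1,
            speckle_scale >= 0, background_structures >= 0)
  structure(list(catheter_length = catheter_length,
                 catheter_width = catheter_width,
                 catheter_intensity = catheter_intensity,
                 catheter_curvature = catheter_curvature,
                 artifact_intensity = artifact_intensity,
                 artifact_depth_frac = artifact_depth_frac,
                 speckle_scale = speckle_scale,
                 background_structures = background_structures,
                 seed = seed),
            class = "scene_config")
}

# Polar coordinates of every pixel about the apex: depth (px) and bearing
# (degrees from the downward axis, positive toward larger columns).
sector_polar <- function(geometry) {
  dr <- outer(seq_len(geometry$image_height) - geometry$apex[1],
              rep(1, geometry$image_width))
  dc <- outer(rep(1, geometry$image_height),
              seq_len(geometry$image_width) - geometry$apex[2])
  list(depth = sqrt(dr^2 + dc^2), bearing = atan2(dc, dr) * 180 / pi)
}

#' Binary mask of the sector field of view
#'
#' A pixel is inside the sector iff its radial distance from the apex lies in
#' `[min_depth, max_depth]` and its bearing is within half the opening angle
#' of the downward axis.
#'
#' @param geometry A [sector_geometry()].
#' @return Logical matrix of size `image_height x image_width`.
#' @export
make_sector_mask <- function(geometry) {
  stopifnot(inherits(geometry, "sector_geometry"))
  pol <- sector_polar(geometry)
  pol$depth >= geometry$min_depth & pol$depth <= geometry$max_depth &
    abs(pol$bearing) <= geometry$opening_angle / 2
}

in_sector <- function(geometry, row, col) {
  dr <- row - geometry$apex[1]
  dc <- col - geometry$apex[2]
  depth <- sqrt(dr^2 + dc^2)
  bearing <- atan2(dc, dr) * 180 / pi
  depth >= geometry$min_depth & depth <= geometry$max_depth &
    abs(bearing) <= geometry$opening_angle / 2
}

# Fully-developed-speckle stand-in: exponential-distributed texture smoothed
# by a small Gaussian kernel, normalized to unit mean.
speckle_field <- function(h, w, sigma = 1) {
  spk <- matrix(stats::rexp(h * w), h, w)
  spk <- EBImage::gblur(spk, sigma = sigma)
  spk / mean(spk)
}

# Anti-aliased distance-based alpha map of a quadratic Bezier ribbon ending
# at the tip. Returns a full-size matrix in [0,1].
catheter_alpha <- function(geometry, tip, angle_deg, length_px, width_px,
                           curvature) {
  h <- geometry$image_height
  w <- geometry$image_width
  th <- angle_deg * pi / 180
  d <- c(-cos(th), sin(th))             # from tip toward the shaft entry
  perp <- c(-d[2], d[1])
  p2 <- tip
  p0 <- tip + length_px * d
  p1 <- tip + 0.5 * length_px * d + curvature * length_px * perp
  tt <- seq(0, 1, length.out = max(40, 2 * ceiling(length_px)))
  # Bezier from entry (t=0) to tip (t=1)
  br <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
  bc <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
  pad <- width_px / 2 + 2
  r0 <- max(1, floor(min(br) - pad)); r1 <- min(h, ceiling(max(br) + pad))
  c0 <- max(1, floor(min(bc) - pad)); c1 <- min(w, ceiling(max(bc) + pad))
  alpha <- matrix(0, h, w)
  if (r0 > r1 || c0 > c1) return(alpha)
  rows <- r0:r1; cols <- c0:c1
  # min distance from each box pixel to the sampled curve
  dr <- outer(rows, rep(1, length(cols))) # row coords
  dc <- outer(rep(1, length(rows)), cols)
  dmin <- matrix(Inf, length(rows), length(cols))
  for (k in seq_along(tt)) {
    dk <- sqrt((dr - br[k])^2 + (dc - bc[k])^2)
    dmin <- pmin(dmin, dk)
  }
  alpha[rows, cols] <- pmin(1, pmax(0, width_px / 2 + 0.5 - dmin))
  alpha
}

#' Render one synthetic echocardiography frame
#'
#' Composes, inside the sector field of view, (a) multiplicative speckle with
#' mean `speckle_scale`, (b) low-contrast elliptical background structures,
#' (c) a bright anti-aliased curvilinear catheter ribbon ending at
#' `tip_position`, and (d) a horizontal reverberation artifact band that is
#' visible in the image but never part of the label. The ground-truth mask
#' covers only the catheter ribbon.
#'
#' @param scene A [scene_config()].
#' @param geometry A [sector_geometry()].
#' @param tip_position `(row, col)` of the catheter tip; must be inside the
#'   sector.
#' @param tip_angle Catheter axis direction at the tip, degrees; 0 means the
#'   shaft runs straight up toward the probe (the tip is the deepest point).
#' @param frame_index Integer stored in the frame metadata.
#' @return An object of class `echo_frame`: list with `image` (matrix in
#'   [0,1]), `mask` (0/1 integer matrix), `geometry`, `tip_pixel`,
#'   `tip_angle`, `frame_index`.
#' @examples
#' geo <- sector_geometry()
#' fr <- render_frame(scene_config(seed = 1), geo, tip_position = c(100, 80))
#' range(fr$image); sum(fr$mask)
#' @export
render_frame <- function(scene, geometry, tip_position, tip_angle = 0,
                         frame_index = 0L) {
  stopifnot(inherits(scene, "scene_config"),
            inherits(geometry, "sector_geometry"),
            length(tip_position) == 2)
  if (!in_sector(geometry, tip_position[1], tip_position[2])) {
    stop("catheter tip placed outside the sector field of view",
         call. = FALSE)
  }
  if (!is.null(scene$seed)) set.seed(scene$seed)
  h <- geometry$image_height
  w <- geometry$image_width
  sector <- make_sector_mask(geometry)
  spk <- speckle_field(h, w)
  img <- scene$speckle_scale * spk

  # low-contrast elliptical structures, speckle-modulated
  if (scene$background_structures > 0) {
    sector_idx <- which(sector, arr.ind = TRUE)
    for (i in seq_len(scene$background_structures)) {
      ctr <- sector_idx[sample.int(nrow(sector_idx), 1), ]
      a <- stats::runif(1, 8, 28)
      b <- stats::runif(1, 8, 28)
      phi <- stats::runif(1, 0, pi)
      amp <- stats::runif(1, -0.07, 0.13)
      rr <- outer(seq_len(h) - ctr[1], rep(1, w))
      cc <- outer(rep(1, h), seq_len(w) - ctr[2])
      xr <- cos(phi) * rr + sin(phi) * cc
      yr <- -sin(phi) * rr + cos(phi) * cc
      q <- (xr / a)^2 + (yr / b)^2
      img <- img + amp * pmax(0, 1 - q) * spk
    }
  }

  # reverberation artifact: horizontal band, excluded from labels
  if (scene$artifact_intensity > 0) {
    band_row <- geometry$apex[1] + scene$artifact_depth_frac * geometry$max_depth
    prof <- exp(-((seq_len(h) - band_row)^2) / (2 * 2^2))
    band <- outer(prof, rep(1, w)) * spk
    img <- img + scene$artifact_intensity * band
  }

  # catheter ribbon + label
  mask <- matrix(0L, h, w)
  if (scene$catheter_intensity > 0) {
    alpha <- catheter_alpha(geometry, tip_position, tip_angle,
                            scene$catheter_length, scene$catheter_width,
                            scene$catheter_curvature)
    alpha[!sector] <- 0
    img <- img + scene$catheter_intensity * alpha
    mask[alpha >= 0.5] <- 1L
    tp <- pmin(pmax(round(tip_position), 1), c(h, w))
    if (sector[tp[1], tp[2]]) mask[tp[1], tp[2]] <- 1L
  }

  img[!sector] <- 0
  img <- pmin(pmax(img, 0), 1)   # first arg carries the dim attributes
  structure(list(image = img, mask = mask, geometry = geometry,
                 tip_pixel = as.numeric(round(tip_position)),
                 tip_angle = tip_angle, frame_index = as.integer(frame_index)),
            class = "echo_frame")
}

#' Simulate a moving-catheter echo sequence
#'
#' Renders one frame per motion entry with temporally incoherent speckle
#' (re-drawn each frame from a per-frame seed derived from `scene$seed`).
#' The default frame rate of 10 Hz gives the 0.1 s inter-frame cadence at
#' which tracked sequences are evaluated.
#'
#' @param scene A [scene_config()]; its `seed` controls the whole sequence.
#' @param geometry A [sector_geometry()].
#' @param motion Data frame with columns `row`, `col` and optionally `angle`
#'   (degrees), one row per frame: the tip trajectory.
#' @param frame_rate Frames per second (Hz).
#' @return An object of class `echo_sequence`: a list of `echo_frame`s with
#'   attributes `frame_rate` and `trajectory` (tibble with `frame_index`,
#'   `time_s`, `row`, `col`, `angle`).
#' @export
simulate_sequence <- function(scene, geometry, motion, frame_rate = 10) {
  stopifnot(inherits(scene, "scene_config"),
            inherits(geometry, "sector_geometry"))
  motion <- tibble::as_tibble(motion)
  if (nrow(motion) == 0) stop("motion must contain at least one tip position",
                              call. = FALSE)
  if (!all(c("row", "col") %in% names(motion))) {
    stop("motion needs columns `row` and `col`", call. = FALSE)
  }
  if (!"angle" %in% names(motion)) motion$angle <- 0
  if (!all(in_sector(geometry, motion$row, motion$col))) {
    stop("all tip positions must lie inside the sector", call. = FALSE)
  }
  n <- nrow(motion)
  if (!is.null(scene$seed)) set.seed(scene$seed)
  frame_seeds <- sample.int(.Machine$integer.max - 1, n)
  frames <- purrr::map(seq_len(n), function(i) {
    sc <- scene
    sc$seed <- frame_seeds[i]
    render_frame(sc, geometry, c(motion$row[i], motion$col[i]),
                 tip_angle = motion$angle[i], frame_index = i - 1L)
  })
  traj <- tibble::tibble(frame_index = seq_len(n) - 1L,
                         time_s = (seq_len(n) - 1) / frame_rate,
                         row = motion$row, col = motion$col,
                         angle = motion$angle)
  structure(frames, frame_rate = frame_rate, trajectory = traj,
            class = "echo_sequence")
}

#' Map a tracked 3-D tip into image pixel coordinates
#'
#' Applies a user-supplied rigid transform from the tracker frame to the
#' image frame (x = lateral mm from the apex, y = depth mm from the apex,
#' z = elevation out of the imaging plane) and converts to pixels through the
#' isotropic pixel spacing. A point farther from the plane than
#' `plane_tolerance` is flagged out-of-plane; an in-plane point outside the
#' fan is flagged out-of-sector.
#'
#' @param tip_tracker Length-3 tip position in the tracker frame, mm.
#' @param tracker_to_image List with `R` (3x3 rotation) and `t` (length-3
#'   translation, mm): the probe-to-image calibration, supplied by the user.
#' @param geometry A [sector_geometry()].
#' @param plane_tolerance Half slice thickness, mm.
#' @return One-row tibble: `row`, `col` (pixels, possibly fractional),
#'   `elevation_mm`, `in_plane`, `in_sector`.
#' @export
map_tip_to_image <- function(tip_tracker,
                             tracker_to_image = list(R = diag(3),
                                                     t = c(0, 0, 0)),
                             geometry = sector_geometry(),
                             plane_tolerance = 2) {
  stopifnot(length(tip_tracker) == 3)
  p <- as.numeric(tracker_to_image$R %*% tip_tracker + tracker_to_image$t)
  row <- geometry$apex[1] + p[2] / geometry$pixel_spacing
  col <- geometry$apex[2] + p[1] / geometry$pixel_spacing
  tibble::tibble(row = row, col = col, elevation_mm = p[3],
                 in_plane = abs(p[3]) <= plane_tolerance,
                 in_sector = in_sector(geometry, row, col))
}

#' Convert between pixel and physical image coordinates
#'
#' `pixel_to_mm()` returns lateral/depth mm offsets from the apex;
#' `mm_to_pixel()` is its inverse.
#'
#' @param row,col Pixel coordinates.
#' @param lateral_mm,depth_mm Physical coordinates relative to the apex.
#' @param geometry A [sector_geometry()].
#' @return A named list.
#' @export
pixel_to_mm <- function(row, col, geometry) {
  list(lateral_mm = (col - geometry$apex[2]) * geometry$pixel_spacing,
       depth_mm = (row - geometry$apex[1]) * geometry$pixel_spacing)
}

#' @rdname pixel_to_mm
#' @export
mm_to_pixel <- function(lateral_mm, depth_mm, geometry) {
  list(row = geometry$apex[1] + depth_mm / geometry$pixel_spacing,
       col = geometry$apex[2] + lateral_mm / geometry$pixel_spacing)
}

#' Write an echo dataset to disk
#'
#' Layout: `frames/NNNN.tif` (16-bit grayscale TIFF), `masks/NNNN.png`
#' (binary PNG) and `meta.json` (geometry, trajectory, frame rate). Images
#' are quantized to the 16-bit grid on write; masks and metadata round-trip
#' exactly.
#'
#' @param frames An `echo_sequence` or list of `echo_frame`s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_echo_dataset <- function(frames, dir) {
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  geo <- frames[[1]]$geometry
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    tiff::writeTIFF(fr$image, file.path(dir, "frames", sprintf("%04d.tif", i)),
                    bits.per.sample = 16L)
    png::writePNG(fr$mask * 1.0, file.path(dir, "masks",
                                           sprintf("%04d.png", i)))
  }
  traj <- attr(frames, "trajectory")
  meta <- list(
    n_frames = length(frames),
    geometry = unclass(geo),
    frame_rate = attr(frames, "frame_rate"),
    tip_pixels = lapply(frames, function(f) f$tip_pixel),
    tip_angles = vapply(frames, function(f) f$tip_angle, numeric(1)),
    frame_indices = vapply(frames, function(f) f$frame_index, integer(1))
  )
  if (!is.null(traj)) meta$trajectory <- traj
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read an echo dataset written by [write_echo_dataset()]
#'
#' @param dir Dataset directory.
#' @return An `echo_sequence`.
#' @export
read_echo_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  g <- meta$geometry
  geo <- sector_geometry(g$image_height, g$image_width, as.numeric(g$apex),
                         g$opening_angle, g$min_depth, g$max_depth,
                         g$pixel_spacing)
  tip_px <- meta$tip_pixels   # simplifies to a matrix when all lengths agree
  frames <- purrr::map(seq_len(meta$n_frames), function(i) {
    img <- tiff::readTIFF(file.path(dir, "frames", sprintf("%04d.tif", i)))
    msk <- png::readPNG(file.path(dir, "masks", sprintf("%04d.png", i)))
    structure(list(image = img,
                   mask = matrix(as.integer(msk > 0.5), nrow(msk), ncol(msk)),
                   geometry = geo,
                   tip_pixel = if (is.matrix(tip_px)) as.numeric(tip_px[i, ])
                               else as.numeric(tip_px[[i]]),
                   tip_angle = meta$tip_angles[i],
                   frame_index = as.integer(meta$frame_indices[i])),
              class = "echo_frame")
  })
  traj <- if (!is.null(meta$trajectory)) tibble::as_tibble(meta$trajectory)
  structure(frames, frame_rate = meta$frame_rate, trajectory = traj,
            class = "echo_sequence")
}

#' @export
print.echo_frame <- function(x, ...) {
  cat(sprintf(
    "<echo_frame %dx%d px, %.2f mm/px, %d catheter px, tip at (%g, %g)>\n",
    nrow(x$image), ncol(x$image), x$geometry$pixel_spacing, sum(x$mask),
    x$tip_pixel[1], x$tip_pixel[2]))
  invisible(x)
}

#' @export
print.echo_sequence <- function(x, ...) {
  cat(sprintf("<echo_sequence of %d frames at %g Hz>\n", length(x),
              attr(x, "frame_rate")))
  invisible(x)
}
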