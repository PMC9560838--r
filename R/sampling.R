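#' Draw one training patch from a frame
#'
#' With probability `config$positive_rate` draws a positive patch (its mask
#' contains at least one catheter pixel), otherwise a negative one. Corners
#' are uniform over the valid range of the zero-padded frame; positivity is
#' sought by rejection sampling, falling back after 50 rejections to a patch
#' centred on a random foreground pixel (positive draws) or to whatever the
#' last draw produced (negative draws on nearly-full masks). A frame with an
#' empty mask yields only negative patches.
#'
#' Consumes the current RNG stream; seed it (or let [train_unet()] do so)
#' for reproducibility.
#'
#' @param frame An `echo_frame`, or a list with `image` and `mask` matrices.
#' @param config A [train_config()]; `patch_shape` sets the patch size.
#' @return A list of class `patch_sample`: `image_patch`, `mask_patch`,
#'   `is_positive`, `source_frame` (the frame's `frame_index`, if any),
#'   `corner` (top-left `(row, col)` in the padded frame).
#' @export
sample_patch <- function(frame, config) {
  stopifnot(inherits(config, "train_config"))
  image <- frame$image
  mask <- frame$mask
  ph <- config$patch_shape[2]
  pw <- config$patch_shape[3]
  h <- max(nrow(image), ph)
  w <- max(ncol(image), pw)
  if (h > nrow(image) || w > ncol(image)) {
    pad_i <- matrix(0, h, w)
    pad_m <- matrix(0L, h, w)
    pad_i[seq_len(nrow(image)), seq_len(ncol(image))] <- image
    pad_m[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
    image <- pad_i
    mask <- pad_m
  }
  want_positive <- stats::runif(1) < config$positive_rate && any(mask > 0)
  draw <- function() {
    r0 <- sample.int(h - ph + 1, 1)
    c0 <- sample.int(w - pw + 1, 1)
    list(r0 = r0, c0 = c0,
         m = mask[r0:(r0 + ph - 1), c0:(c0 + pw - 1), drop = FALSE])
  }
  d <- draw()
  tries <- 1
  target <- function(m) if (want_positive) any(m > 0) else !any(m > 0)
  while (!target(d$m) && tries < 50) {
    d <- draw()
    tries <- tries + 1
  }
  if (want_positive && !any(d$m > 0)) {
    # fallback: centre on a random foreground pixel
    fg <- which(mask > 0, arr.ind = TRUE)
    pick <- fg[sample.int(nrow(fg), 1), ]
    r0 <- min(max(1, pick[1] - ph %/% 2), h - ph + 1)
    c0 <- min(max(1, pick[2] - pw %/% 2), w - pw + 1)
    d <- list(r0 = r0, c0 = c0,
              m = mask[r0:(r0 + ph - 1), c0:(c0 + pw - 1), drop = FALSE])
  }
  ip <- image[d$r0:(d$r0 + ph - 1), d$c0:(d$c0 + pw - 1), drop = FALSE]
  structure(list(image_patch = ip, mask_patch = d$m,
                 is_positive = any(d$m > 0),
                 source_frame = frame$frame_index %||% NA_integer_,
                 corner = c(d$r0, d$c0)),
            class = "patch_sample")
}

# Bilinear sampling of `img` at (possibly fractional) source coordinates;
# out-of-range samples read as `fill`.
warp_bilinear <- function(img, src_r, src_c, fill = 0) {
  h <- nrow(img)
  w <- ncol(img)
  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0; fc <- src_c - c0
  at <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- matrix(fill, nrow(src_r), ncol(src_r))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  at(r0, c0) * (1 - fr) * (1 - fc) + at(r0 + 1, c0) * fr * (1 - fc) +
    at(r0, c0 + 1) * (1 - fr) * fc + at(r0 + 1, c0 + 1) * fr * fc
}

# Inverse-mapping rotation about the image centre (degrees, counterclockwise
# in (row, col) pixel coordinates).
rotate_image <- function(img, angle_deg, fill = 0) {
  h <- nrow(img)
  w <- ncol(img)
  th <- angle_deg * pi / 180
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  dr <- outer(seq_len(h) - ctr[1], rep(1, w))
  dc <- outer(rep(1, h), seq_len(w) - ctr[2])
  src_r <- ctr[1] + cos(th) * dr - sin(th) * dc
  src_c <- ctr[2] + sin(th) * dr + cos(th) * dc
  warp_bilinear(img, src_r, src_c, fill)
}

rotate_point <- function(pt, angle_deg, h, w) {
  th <- angle_deg * pi / 180
  ctr <- c((h + 1) / 2, (w + 1) / 2)
  d <- pt - ctr
  # forward map is the inverse of the sampling map above
  ctr + c(cos(th) * d[1] + sin(th) * d[2],
          -sin(th) * d[1] + cos(th) * d[2])
}

# Smooth random displacement field for elastic deformation: Gaussian noise
# blurred at `sigma`, scaled to a maximum displacement of `alpha` pixels.
elastic_field <- function(h, w, alpha, sigma) {
  f <- EBImage::gblur(matrix(stats::rnorm(h * w), h, w), sigma = sigma)
  f / max(abs(f), 1e-12) * alpha
}

#' Offline dataset augmentation
#'
#' Enlarges a frame set to `factor` times its size. The first copy of every
#' frame is the identity; each further copy applies a seeded random
#' combination of horizontal flip (p = 0.5), rotation within +/-15 degrees,
#' intensity scaling within +/-20%, and a small elastic deformation
#' (p = 0.5, max 3 px displacement, 8 px smoothness). Image and mask receive
#' the identical geometric transform (bilinear for the image, re-binarized
#' for the mask); intensity scaling touches the image only. The stored
#' `tip_pixel` is transformed alongside (approximately so under elastic
#' deformation).
#'
#' @param frames An `echo_sequence` or list of `echo_frame`s.
#' @param factor Integer >= 1.
#' @param seed Integer seed.
#' @param ops Character subset of `c("flip", "rotate", "intensity",
#'   "elastic")`: which operations may be applied.
#' @return A list of `echo_frame`s of length `factor * length(frames)`.
#' @export
augment_dataset <- function(frames, factor = 10, seed = 1L,
                            ops = c("flip", "rotate", "intensity",
                                    "elastic")) {
  stopifnot(factor >= 1)
  ops <- match.arg(ops, several.ok = TRUE)
  set.seed(seed)
  out <- vector("list", factor * length(frames))
  k <- 0
  for (fr in frames) {
    k <- k + 1
    out[[k]] <- fr
  }
  for (cp in seq_len(factor - 1)) {
    for (fr in frames) {
      k <- k + 1
      out[[k]] <- augment_frame(fr, ops)
    }
  }
  out
}

augment_frame <- function(fr, ops) {
  img <- fr$image
  msk <- fr$mask
  tip <- fr$tip_pixel
  h <- nrow(img)
  w <- ncol(img)
  if ("flip" %in% ops && stats::runif(1) < 0.5) {
    img <- img[, w:1, drop = FALSE]
    msk <- msk[, w:1, drop = FALSE]
    tip[2] <- w + 1 - tip[2]
  }
  if ("rotate" %in% ops) {
    ang <- stats::runif(1, -15, 15)
    img <- rotate_image(img, ang)
    mskf <- rotate_image(msk * 1.0, ang)
    msk <- matrix(as.integer(mskf > 0.5), h, w)
    tip <- rotate_point(tip, ang, h, w)
  }
  if ("elastic" %in% ops && stats::runif(1) < 0.5) {
    dr <- elastic_field(h, w, alpha = 3, sigma = 8)
    dc <- elastic_field(h, w, alpha = 3, sigma = 8)
    rr <- outer(seq_len(h), rep(1, w)) + dr
    cc <- outer(rep(1, h), seq_len(w)) + dc
    img <- warp_bilinear(img, rr, cc)
    mskf <- warp_bilinear(msk * 1.0, rr, cc)
    msk <- matrix(as.integer(mskf > 0.5), h, w)
    ti <- pmin(pmax(round(tip), 1), c(h, w))
    tip <- tip - c(dr[ti[1], ti[2]], dc[ti[1], ti[2]])
  }
  if ("intensity" %in% ops) {
    img <- pmin(pmax(img * stats::runif(1, 0.8, 1.2), 0), 1)
  }
  structure(list(image = img, mask = msk, geometry = fr$geometry,
                 tip_pixel = tip, tip_angle = fr$tip_angle,
                 frame_index = fr$frame_index),
            class = "echo_frame")
}
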