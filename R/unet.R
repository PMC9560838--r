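# 2-D UNet on the package's CPU convnet primitives (src/convnet.cpp).
# Tensors are (H, W, C) arrays; parameters live in a flat named list so the
# Adam state and gradient accumulators can mirror it 1:1.

he_init <- function(c_out, c_in, k) {
  fan_in <- c_in * k * k
  list(W = matrix(stats::rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)),
                  nrow = c_out),
       b = rep(0, c_out))
}

#' Build an untrained patch-based 2-D UNet
#'
#' Encoder-decoder with skip connections: at each of `unet_depth` resolution
#' levels two 3x3 same-padding convolutions with ReLU, channel count doubling
#' per level from `base_filters`; 2x2 max pooling between encoder levels;
#' nearest-neighbour upsampling followed by a channel-halving convolution and
#' skip concatenation in the decoder; dropout at the configured rate before
#' the final 1x1 convolution with sigmoid output. Weight initialization is
#' seeded from `config$seed`, so building twice gives identical weights.
#'
#' @param config A [train_config()].
#' @return An object of class `unet_model`: list with `params` (named list
#'   of `W`/`b` pairs), `depth`, `base_filters`, `config`.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "train_config"))
  set.seed(config$seed)
  d <- config$unet_depth
  f <- config$base_filters
  ch <- f * 2^(seq_len(d) - 1)
  p <- list()
  c_in <- 1
  for (l in seq_len(d - 1)) {
    p[[paste0("enc", l, "_c1")]] <- he_init(ch[l], c_in, 3)
    p[[paste0("enc", l, "_c2")]] <- he_init(ch[l], ch[l], 3)
    c_in <- ch[l]
  }
  p[["bot_c1"]] <- he_init(ch[d], c_in, 3)
  p[["bot_c2"]] <- he_init(ch[d], ch[d], 3)
  for (l in rev(seq_len(d - 1))) {
    p[[paste0("up", l)]] <- he_init(ch[l], ch[l + 1], 3)
    p[[paste0("dec", l, "_c1")]] <- he_init(ch[l], 2 * ch[l], 3)
    p[[paste0("dec", l, "_c2")]] <- he_init(ch[l], ch[l], 3)
  }
  p[["out"]] <- he_init(1, ch[1], 1)
  structure(list(params = p, depth = d, base_filters = f, config = config),
            class = "unet_model")
}

as_chw <- function(x) {
  if (length(dim(x)) == 2) array(x, c(nrow(x), ncol(x), 1)) else x
}

conv_relu_fw <- function(par, x, k = 3L) {
  y <- conv2d_forward(x, par$W, par$b, k, (k - 1L) %/% 2L)
  list(y = y, a = pmax(y, 0))
}

# Forward pass; with training = TRUE applies inverted dropout before the
# output layer (consumes RNG). Returns the probability map plus all caches
# needed for the backward pass.
unet_forward <- function(model, x, training = FALSE) {
  p <- model$params
  d <- model$depth
  rate <- model$config$dropout_rate_last_layer
  h <- as_chw(x)
  enc <- vector("list", max(0, d - 1))
  for (l in seq_len(d - 1)) {
    r1 <- conv_relu_fw(p[[paste0("enc", l, "_c1")]], h)
    r2 <- conv_relu_fw(p[[paste0("enc", l, "_c2")]], r1$a)
    mp <- maxpool2_forward(r2$a)
    enc[[l]] <- list(x_in = h, y1 = r1$y, a1 = r1$a, y2 = r2$y, a2 = r2$a,
                     idx = mp$idx, dim = dim(r2$a))
    h <- mp$y
  }
  b1 <- conv_relu_fw(p[["bot_c1"]], h)
  b2 <- conv_relu_fw(p[["bot_c2"]], b1$a)
  bot <- list(x_in = h, y1 = b1$y, a1 = b1$a, y2 = b2$y, a2 = b2$a)
  h <- b2$a
  dec <- vector("list", max(0, d - 1))
  for (l in rev(seq_len(d - 1))) {
    u <- upsample2_forward(h)
    ru <- conv_relu_fw(p[[paste0("up", l)]], u)
    skip <- enc[[l]]$a2
    n_skip <- dim(skip)[3]
    cat_in <- array(c(skip, ru$a),
                    dim = c(dim(skip)[1], dim(skip)[2],
                            n_skip + dim(ru$a)[3]))
    r1 <- conv_relu_fw(p[[paste0("dec", l, "_c1")]], cat_in)
    r2 <- conv_relu_fw(p[[paste0("dec", l, "_c2")]], r1$a)
    dec[[l]] <- list(u_in = u, yu = ru$y, au = ru$a, cat_in = cat_in,
                     n_skip = n_skip, y1 = r1$y, a1 = r1$a,
                     y2 = r2$y, a2 = r2$a)
    h <- r2$a
  }
  drop_mask <- NULL
  if (training && rate > 0) {
    drop_mask <- array((stats::runif(length(h)) >= rate) / (1 - rate), dim(h))
    h <- h * drop_mask
  }
  logits <- conv2d_forward(h, p[["out"]]$W, p[["out"]]$b, 1L, 0L)
  prob <- 1 / (1 + exp(-logits))
  list(prob = prob[, , 1], enc = enc, bot = bot, dec = dec,
       head_in = h, drop_mask = drop_mask, logits = logits)
}

# Backward pass from dL/dprob; returns gradients keyed like model$params.
unet_backward <- function(model, fw, gprob) {
  p <- model$params
  d <- model$depth
  g <- list()
  prob <- fw$prob
  glogit <- array(gprob * prob * (1 - prob), dim(fw$logits))
  bwo <- conv2d_backward(fw$head_in, p[["out"]]$W, glogit, 1L, 0L)
  g[["out"]] <- list(W = bwo$gw, b = as.numeric(bwo$gb))
  gh <- bwo$gx
  if (!is.null(fw$drop_mask)) gh <- gh * fw$drop_mask
  gskip <- vector("list", max(0, d - 1))
  for (l in seq_len(d - 1)) {          # decoders, innermost applied last
    dc <- fw$dec[[l]]
    gy2 <- gh * (dc$y2 > 0)
    bw2 <- conv2d_backward(dc$a1, p[[paste0("dec", l, "_c2")]]$W, gy2, 3L, 1L)
    g[[paste0("dec", l, "_c2")]] <- list(W = bw2$gw, b = as.numeric(bw2$gb))
    gy1 <- bw2$gx * (dc$y1 > 0)
    bw1 <- conv2d_backward(dc$cat_in, p[[paste0("dec", l, "_c1")]]$W,
                           gy1, 3L, 1L)
    g[[paste0("dec", l, "_c1")]] <- list(W = bw1$gw, b = as.numeric(bw1$gb))
    gcat <- bw1$gx
    ns <- dc$n_skip
    gskip[[l]] <- gcat[, , seq_len(ns), drop = FALSE]
    gau <- gcat[, , (ns + 1):dim(gcat)[3], drop = FALSE]
    gyu <- gau * (dc$yu > 0)
    bwu <- conv2d_backward(dc$u_in, p[[paste0("up", l)]]$W, gyu, 3L, 1L)
    g[[paste0("up", l)]] <- list(W = bwu$gw, b = as.numeric(bwu$gb))
    gh <- upsample2_backward(bwu$gx)
  }
  bt <- fw$bot
  gy2 <- gh * (bt$y2 > 0)
  bw2 <- conv2d_backward(bt$a1, p[["bot_c2"]]$W, gy2, 3L, 1L)
  g[["bot_c2"]] <- list(W = bw2$gw, b = as.numeric(bw2$gb))
  gy1 <- bw2$gx * (bt$y1 > 0)
  bw1 <- conv2d_backward(bt$x_in, p[["bot_c1"]]$W, gy1, 3L, 1L)
  g[["bot_c1"]] <- list(W = bw1$gw, b = as.numeric(bw1$gb))
  gh <- bw1$gx
  for (l in rev(seq_len(d - 1))) {     # encoders, outermost applied first
    ec <- fw$enc[[l]]
    ga2 <- maxpool2_backward(gh, ec$idx, ec$dim[1], ec$dim[2]) + gskip[[l]]
    gy2 <- ga2 * (ec$y2 > 0)
    bw2 <- conv2d_backward(ec$a1, p[[paste0("enc", l, "_c2")]]$W, gy2, 3L, 1L)
    g[[paste0("enc", l, "_c2")]] <- list(W = bw2$gw, b = as.numeric(bw2$gb))
    gy1 <- bw2$gx * (ec$y1 > 0)
    bw1 <- conv2d_backward(ec$x_in, p[[paste0("enc", l, "_c1")]]$W,
                           gy1, 3L, 1L)
    g[[paste0("enc", l, "_c1")]] <- list(W = bw1$gw, b = as.numeric(bw1$gb))
    gh <- bw1$gx
  }
  g
}

# Probability map for an arbitrary image: pad to the divisibility the depth
# requires; when the image exceeds the patch size, run tiled inference with
# half-patch stride and average overlapping probabilities.
unet_prob_map <- function(model, image) {
  cfg <- model$config
  ph <- cfg$patch_shape[2]
  pw <- cfg$patch_shape[3]
  h <- nrow(image)
  w <- ncol(image)
  if (h <= ph && w <= pw) {
    div <- 2^(model$depth - 1)
    hp <- div * ceiling(h / div)
    wp <- div * ceiling(w / div)
    xp <- matrix(0, hp, wp)
    xp[seq_len(h), seq_len(w)] <- image
    prob <- unet_forward(model, xp, training = FALSE)$prob
    return(prob[seq_len(h), seq_len(w)])
  }
  acc <- matrix(0, h, w)
  wt <- matrix(0, h, w)
  r_starts <- unique(pmin(seq(1, max(1, h - ph + 1), by = ph %/% 2),
                          max(1, h - ph + 1)))
  c_starts <- unique(pmin(seq(1, max(1, w - pw + 1), by = pw %/% 2),
                          max(1, w - pw + 1)))
  if (h > ph) r_starts <- unique(c(r_starts, h - ph + 1))
  if (w > pw) c_starts <- unique(c(c_starts, w - pw + 1))
  for (r0 in r_starts) {
    for (c0 in c_starts) {
      rr <- r0:min(h, r0 + ph - 1)
      cc <- c0:min(w, c0 + pw - 1)
      tile <- matrix(0, ph, pw)
      tile[seq_along(rr), seq_along(cc)] <- image[rr, cc]
      pt <- unet_forward(model, tile, training = FALSE)$prob
      acc[rr, cc] <- acc[rr, cc] + pt[seq_along(rr), seq_along(cc)]
      wt[rr, cc] <- wt[rr, cc] + 1
    }
  }
  acc / pmax(wt, 1)
}

#' Predict a catheter mask for an image or frame
#'
#' Runs the network over the full image (tiled with overlap-averaging when
#' the image exceeds the training patch size) and thresholds the sigmoid
#' probability map at the configured binarization threshold.
#'
#' @param object A `unet_model` (or see [predict.unet_fit()]).
#' @param frame An `echo_frame` or a numeric image matrix in [0, 1].
#' @param type `"mask"` (default) for the thresholded binary mask or
#'   `"prob"` for the probability map.
#' @param threshold Overrides the config's binarization threshold.
#' @param ... Unused.
#' @return Integer 0/1 matrix (or probability matrix) of the input shape.
#' @export
predict.unet_model <- function(object, frame, type = c("mask", "prob"),
                               threshold = NULL, ...) {
  type <- match.arg(type)
  image <- if (inherits(frame, "echo_frame")) frame$image else frame
  stopifnot(is.matrix(image))
  prob <- unet_prob_map(object, image)
  if (type == "prob") return(prob)
  thr <- threshold %||% object$config$binarization_threshold
  matrix(as.integer(prob > thr), nrow(prob), ncol(prob))
}

#' @export
print.unet_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) length(p$W) + length(p$b),
                      numeric(1)))
  cat(sprintf("<unet_model depth %d, %d base filters, %d parameters>\n",
              x$depth, x$base_filters, n_par))
  invisible(x)
}
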