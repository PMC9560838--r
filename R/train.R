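#' Train the patch-based UNet with smoothed Dice loss
#'
#' Implements the patch-based training loop: at every iteration a batch of
#' patches is drawn from random training frames at the configured
#' positive-patch rate, the network is run with dropout, and the batch-mean
#' smoothed Dice loss is minimised with Adam. A fixed, seeded validation
#' patch set is evaluated every `validation_interval` iterations; training
#' stops early once the best validation loss has not improved for
#' `early_stopping_patience` iterations, and the returned model carries the
#' weights from the best validation iteration. All randomness (weight
#' initialization, patch draws, dropout) derives from `config$seed`, so a
#' repeated run reproduces the loss history exactly.
#'
#' @param config A [train_config()] (see [desk_config()] for a profile that
#'   trains in minutes).
#' @param train_frames,val_frames Lists of `echo_frame`s (typically the
#'   output of [augment_dataset()] for training and raw frames for
#'   validation).
#' @param verbose Print progress every validation interval.
#' @return An object of class `unet_fit`: list with `model` (best-iteration
#'   `unet_model`), `history` (tibble: `iteration`, `split`, `dice_loss`),
#'   `stopped_at`, `best_iteration`, `best_val_loss`, `config`.
#' @examples
#' \donttest{
#' geo <- sector_geometry()
#' frames <- lapply(1:8, function(i)
#'   render_frame(scene_config(seed = i), geo,
#'                tip_position = c(90 + 3 * i, 60 + 2 * i)))
#' fit <- train_unet(desk_config(max_iterations = 30), frames[1:6],
#'                   frames[7:8])
#' glance(fit)
#' }
#' @export
train_unet <- function(config, train_frames, val_frames, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (length(train_frames) == 0 || length(val_frames) == 0) {
    stop("training and validation sets must be non-empty", call. = FALSE)
  }
  model <- build_unet(config)   # seeds the RNG from config$seed

  # fixed validation patch set, drawn once from a dedicated substream
  set.seed(config$seed + 1L)
  val_set <- purrr::map(seq_len(config$validation_patches), function(i) {
    fr <- val_frames[[sample.int(length(val_frames), 1)]]
    sample_patch(fr, config)
  })

  set.seed(config$seed + 2L)    # training stream
  opt <- adam_init(model$params, config$learning_rate)
  hist_iter <- integer(0)
  hist_split <- character(0)
  hist_loss <- numeric(0)
  best_val <- Inf
  best_iter <- 0L
  best_params <- model$params
  stopped_at <- config$max_iterations

  val_loss <- function() {
    mean(vapply(val_set, function(s) {
      fw <- unet_forward(model, s$image_patch, training = FALSE)
      dice_loss(fw$prob, s$mask_patch, config$smoothing_constant)
    }, numeric(1)))
  }

  for (iter in seq_len(config$max_iterations)) {
    gacc <- NULL
    batch_loss <- 0
    for (b in seq_len(config$batch_size)) {
      fr <- train_frames[[sample.int(length(train_frames), 1)]]
      s <- sample_patch(fr, config)
      fw <- unet_forward(model, s$image_patch, training = TRUE)
      l <- dice_loss(fw$prob, s$mask_patch, config$smoothing_constant)
      batch_loss <- batch_loss + l
      gprob <- dice_loss_grad(fw$prob, s$mask_patch,
                              config$smoothing_constant)
      g <- unet_backward(model, fw, gprob)
      gacc <- if (is.null(gacc)) g else accumulate_grads(gacc, g)
    }
    batch_loss <- batch_loss / config$batch_size
    if (!is.finite(batch_loss)) {
      stop(sprintf(
        "training diverged at iteration %d (non-finite Dice loss); lower the learning rate",
        iter), call. = FALSE)
    }
    model$params <- adam_step(opt, model$params, gacc, config$batch_size)
    hist_iter <- c(hist_iter, iter)
    hist_split <- c(hist_split, "train")
    hist_loss <- c(hist_loss, batch_loss)

    if (iter %% config$validation_interval == 0) {
      vl <- val_loss()
      hist_iter <- c(hist_iter, iter)
      hist_split <- c(hist_split, "validation")
      hist_loss <- c(hist_loss, vl)
      if (verbose) {
        message(sprintf("iter %5d  train %.4f  val %.4f", iter, batch_loss,
                        vl))
      }
      if (vl < best_val) {
        best_val <- vl
        best_iter <- iter
        best_params <- model$params
      } else if (iter - best_iter >= config$early_stopping_patience) {
        stopped_at <- iter
        break
      }
      stopped_at <- iter
    }
  }

  model$params <- best_params
  history <- tibble::tibble(iteration = hist_iter, split = hist_split,
                            dice_loss = hist_loss)
  structure(list(model = model, history = history,
                 stopped_at = stopped_at,
                 best_iteration = best_iter,
                 best_val_loss = best_val,
                 config = config),
            class = "unet_fit")
}

accumulate_grads <- function(a, b) {
  for (nm in names(a)) {
    a[[nm]]$W <- a[[nm]]$W + b[[nm]]$W
    a[[nm]]$b <- a[[nm]]$b + b[[nm]]$b
  }
  a
}

# Adam optimiser state kept in an environment so adam_step can update
# moments in place.
adam_init <- function(params, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$b1 <- beta1; e$b2 <- beta2; e$eps <- eps; e$t <- 0
  e$m <- lapply(params, function(p) list(W = p$W * 0, b = p$b * 0))
  e$v <- e$m
  e
}

adam_step <- function(opt, params, grads, batch_size) {
  opt$t <- opt$t + 1
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (nm in names(params)) {
    for (slot in c("W", "b")) {
      gr <- grads[[nm]][[slot]] / batch_size
      opt$m[[nm]][[slot]] <- opt$b1 * opt$m[[nm]][[slot]] + (1 - opt$b1) * gr
      opt$v[[nm]][[slot]] <- opt$b2 * opt$v[[nm]][[slot]] +
        (1 - opt$b2) * gr^2
      params[[nm]][[slot]] <- params[[nm]][[slot]] -
        opt$lr * (opt$m[[nm]][[slot]] / bc1) /
        (sqrt(opt$v[[nm]][[slot]] / bc2) + opt$eps)
    }
  }
  params
}

#' @export
predict.unet_fit <- function(object, frame, ...) {
  predict(object$model, frame, ...)
}

#' @export
print.unet_fit <- function(x, ...) {
  cat(sprintf(
    "<unet_fit: stopped at iteration %d, best validation Dice loss %.4f at iteration %d>\n",
    x$stopped_at, x$best_val_loss, x$best_iteration))
  invisible(x)
}

#' Per-iteration loss history of a UNet fit
#' @param x A `unet_fit`.
#' @param ... Unused.
#' @return Tibble with `iteration`, `split` (`train`/`validation`),
#'   `dice_loss`.
#' @export
tidy.unet_fit <- function(x, ...) {
  x$history
}

#' One-row summary of a UNet fit
#' @param x A `unet_fit`.
#' @param ... Unused.
#' @return Tibble with `stopped_at`, `best_iteration`, `best_val_loss`,
#'   `final_train_loss`.
#' @export
glance.unet_fit <- function(x, ...) {
  tr <- dplyr::filter(x$history, .data$split == "train")
  tibble::tibble(stopped_at = x$stopped_at,
                 best_iteration = x$best_iteration,
                 best_val_loss = x$best_val_loss,
                 final_train_loss = tr$dice_loss[nrow(tr)])
}

#' Export a loss history as CSV
#'
#' Columns `iteration, split, dice_loss`, one row per logged value.
#'
#' @param fit A `unet_fit`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_loss_history <- function(fit, path) {
  stopifnot(inherits(fit, "unet_fit"))
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a JSON file embedding the configuration and all weights
#' (plain text, so checkpoints survive text-only transports).
#'
#' @param fit A `unet_fit` or `unet_model`.
#' @param path Checkpoint path.
#' @return `write_checkpoint()` returns `path` invisibly;
#'   `read_checkpoint()` returns a `unet_model`.
#' @export
write_checkpoint <- function(fit, path) {
  model <- if (inherits(fit, "unet_fit")) fit$model else fit
  stopifnot(inherits(model, "unet_model"))
  payload <- list(
    config = unclass(model$config),
    depth = model$depth,
    base_filters = model$base_filters,
    params = lapply(model$params, function(p)
      list(W = as.numeric(p$W), dim = dim(p$W), b = p$b))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg_args <- j$config
  cfg_args$patch_shape <- as.numeric(cfg_args$patch_shape)
  cfg <- do.call(train_config, cfg_args)
  params <- lapply(j$params, function(p)
    list(W = matrix(as.numeric(p$W), p$dim[1], p$dim[2]),
         b = as.numeric(p$b)))
  structure(list(params = params, depth = j$depth,
                 base_filters = j$base_filters, config = cfg),
            class = "unet_model")
}
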