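#' Training configuration for the patch-based UNet
#'
#' Holds the full hyperparameter set of the segmentation pipeline. The
#' defaults are the reference operating point: single-channel 448x448
#' patches, batch size 4, up to 30000 batch iterations with early stopping
#' at a patience of 6000 iterations, UNet depth 5, dropout 0.5 at the last
#' layer, positive-patch sampling rate 0.95, offline augmentation factor 10,
#' smoothed Dice loss with additive constant 1, ReLU activations, and a 0.5
#' binarization threshold. Optimiser settings (Adam, learning rate 1e-3) and
#' the validation interval are exposed because they must be pinned for
#' reproducibility.
#'
#' @param patch_shape `(channels, height, width)` of a training patch.
#' @param batch_size Patches per iteration.
#' @param max_iterations Maximum number of batch iterations.
#' @param unet_depth Number of resolution levels (>= 1).
#' @param base_filters Channels at the first level (doubled per level).
#' @param dropout_rate_last_layer Dropout before the final 1x1 layer.
#' @param positive_rate Probability a sampled patch contains the target.
#' @param augmentation_factor Offline dataset enlargement factor.
#' @param early_stopping_patience Iterations without validation improvement
#'   before training stops.
#' @param smoothing_constant Additive smoothing of the Dice loss (>= 0).
#' @param binarization_threshold Probability threshold for predicted masks.
#' @param learning_rate Adam step size.
#' @param validation_interval Iterations between validation evaluations.
#' @param validation_patches Size of the fixed seeded validation patch set.
#' @param seed Integer seed controlling all training randomness.
#' @return An object of class `train_config`.
#' @seealso [desk_config()] for the small-scale profile used in examples
#'   and tests.
#' @export
train_config <- function(patch_shape = c(1, 448, 448),
                         batch_size = 4,
                         max_iterations = 30000,
                         unet_depth = 5,
                         base_filters = 16,
                         dropout_rate_last_layer = 0.5,
                         positive_rate = 0.95,
                         augmentation_factor = 10,
                         early_stopping_patience = 6000,
                         smoothing_constant = 1,
                         binarization_threshold = 0.5,
                         learning_rate = 1e-3,
                         validation_interval = 100,
                         validation_patches = 16,
                         seed = 1L) {
  stopifnot(length(patch_shape) == 3, patch_shape[1] == 1,
            positive_rate >= 0, positive_rate <= 1,
            unet_depth >= 1, smoothing_constant >= 0,
            batch_size >= 1, max_iterations >= 1)
  div <- 2^(unet_depth - 1)
  if (patch_shape[2] %% div != 0 || patch_shape[3] %% div != 0) {
    stop(sprintf(
      "patch height/width must be divisible by 2^(depth-1) = %d; pad to %dx%d",
      div, div * ceiling(patch_shape[2] / div),
      div * ceiling(patch_shape[3] / div)), call. = FALSE)
  }
  structure(list(patch_shape = patch_shape, batch_size = batch_size,
                 max_iterations = max_iterations, unet_depth = unet_depth,
                 base_filters = base_filters,
                 dropout_rate_last_layer = dropout_rate_last_layer,
                 positive_rate = positive_rate,
                 augmentation_factor = augmentation_factor,
                 early_stopping_patience = early_stopping_patience,
                 smoothing_constant = smoothing_constant,
                 binarization_threshold = binarization_threshold,
                 learning_rate = learning_rate,
                 validation_interval = validation_interval,
                 validation_patches = validation_patches,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Desk-scale training profile
#'
#' A small configuration that trains in minutes on one CPU while exercising
#' the identical pipeline: depth-3 UNet with 8 base filters, 64x64 patches,
#' up to 600 iterations, validation every 50 iterations with a patience of
#' 300, augmentation factor 4. Used throughout examples and tests on
#' synthetic frames.
#'
#' @param ... Overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
desk_config <- function(...) {
  args <- list(patch_shape = c(1, 64, 64), batch_size = 4,
               max_iterations = 600, unet_depth = 3, base_filters = 8,
               augmentation_factor = 4, early_stopping_patience = 300,
               validation_interval = 50, validation_patches = 12,
               seed = 1L)
  over <- list(...)
  args[names(over)] <- over
  do.call(train_config, args)
}

#' Read / write a training configuration as YAML
#'
#' Field names in the YAML mirror the arguments of [train_config()].
#'
#' @param path YAML file path.
#' @param config A `train_config`.
#' @return `read_train_config()` returns a `train_config`;
#'   `write_train_config()` returns `path` invisibly.
#' @export
read_train_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(train_config))
  bad <- setdiff(names(y), known)
  if (length(bad) > 0) {
    stop("unknown training config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(y$patch_shape)) y$patch_shape <- as.numeric(y$patch_shape)
  do.call(train_config, y)
}

#' @rdname read_train_config
#' @export
write_train_config <- function(config, path) {
  stopifnot(inherits(config, "train_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
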