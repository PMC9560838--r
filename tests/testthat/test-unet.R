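tiny_config <- function(...) {
  train_config(patch_shape = c(1, 8, 8), unet_depth = 2, base_filters = 2,
               dropout_rate_last_layer = 0, max_iterations = 5,
               validation_interval = 2, validation_patches = 2,
               early_stopping_patience = 10, seed = 1L, ...)
}

test_that("network output is a sigmoid probability map of the input shape", {
  m <- build_unet(tiny_config())
  x <- matrix(runif(64), 8, 8)
  fw <- cathtrack:::unet_forward(m, x)
  expect_equal(dim(fw$prob), c(8, 8))
  expect_true(all(fw$prob > 0 & fw$prob < 1))
  # depth 1: a plain convolutional stack, no resolution change
  m1 <- build_unet(train_config(patch_shape = c(1, 7, 5), unet_depth = 1,
                                base_filters = 3))
  fw1 <- cathtrack:::unet_forward(m1, matrix(runif(35), 7, 5))
  expect_equal(dim(fw1$prob), c(7, 5))
})

test_that("depth-5 bottleneck halves 448 four times to 28", {
  cfg <- train_config()     # reference profile: depth 5, 448x448 patches
  m <- build_unet(cfg)
  # channel plan doubles per level from base_filters
  expect_equal(nrow(m$params$bot_c1$W), cfg$base_filters * 2^4)
  expect_equal(448 / 2^(cfg$unet_depth - 1), 28)
  expect_error(train_config(patch_shape = c(1, 450, 450)), "divisible")
})

test_that("weight initialization is reproducible from the config seed", {
  a <- build_unet(tiny_config())
  b <- build_unet(tiny_config())
  expect_identical(a$params, b$params)
})

test_that("backpropagated gradients match finite differences", {
  cfg <- tiny_config()
  m <- build_unet(cfg)
  set.seed(4)
  # nudge biases off zero so no pre-activation sits exactly on the ReLU
  # kink (where the loss is one-sidedly differentiable by construction)
  for (nm in names(m$params)) {
    m$params[[nm]]$b <- rnorm(length(m$params[[nm]]$b), sd = 0.1)
  }
  x <- matrix(runif(64), 8, 8)
  y <- matrix(rbinom(64, 1, 0.3), 8, 8)
  loss_at <- function(model) {
    fw <- cathtrack:::unet_forward(model, x)
    dice_loss(fw$prob, y, smoothing = 1)
  }
  fw <- cathtrack:::unet_forward(m, x)
  g <- cathtrack:::unet_backward(
    m, fw, cathtrack:::dice_loss_grad(fw$prob, y, 1))
  eps <- 1e-6
  for (nm in c("enc1_c1", "enc1_c2", "bot_c2", "up1", "dec1_c1", "out")) {
    k <- sample(length(m$params[[nm]]$W), 1)
    mp <- m; mp$params[[nm]]$W[k] <- mp$params[[nm]]$W[k] + eps
    mm <- m; mm$params[[nm]]$W[k] <- mm$params[[nm]]$W[k] - eps
    num <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    expect_equal(g[[nm]]$W[k], num, tolerance = 1e-4)
    kb <- sample(length(m$params[[nm]]$b), 1)
    bp <- m; bp$params[[nm]]$b[kb] <- bp$params[[nm]]$b[kb] + eps
    bm <- m; bm$params[[nm]]$b[kb] <- bm$params[[nm]]$b[kb] - eps
    numb <- (loss_at(bp) - loss_at(bm)) / (2 * eps)
    expect_equal(g[[nm]]$b[kb], numb, tolerance = 1e-4)
  }
})

test_that("binarization threshold extremes give empty and full masks", {
  m <- build_unet(tiny_config())
  x <- matrix(runif(64), 8, 8)
  expect_equal(sum(predict(m, x, threshold = 1)), 0)
  expect_equal(sum(predict(m, x, threshold = 0)), 64)
  pr <- predict(m, x, type = "prob")
  expect_true(all(pr > 0 & pr < 1))
})

test_that("tiled inference covers frames larger than the patch", {
  m <- build_unet(tiny_config())
  big <- matrix(runif(20 * 26), 20, 26)
  pr <- predict(m, big, type = "prob")
  expect_equal(dim(pr), c(20, 26))
  expect_true(all(is.finite(pr)))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("checkpoints round-trip weights and config through JSON", {
  m <- build_unet(tiny_config())
  f <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(m, f)
  back <- read_checkpoint(f)
  expect_equal(back$params, m$params)
  expect_equal(back$config$patch_shape, m$config$patch_shape)
  x <- matrix(runif(64), 8, 8)
  expect_equal(predict(back, x, type = "prob"), predict(m, x, type = "prob"))
})
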