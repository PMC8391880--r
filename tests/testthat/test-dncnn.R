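tiny_patches <- function(seed = 2, count = 8, size = 12) {
  st <- simulate_bscan_stack(tiny_scene(fov = 64L),
                             speckle_model(looks = 4, seed = seed), 11)
  extract_patches(compound(st, 5), count = count, size = size, seed = seed)
}

test_that("the device-scale configuration matches the published recipe", {
  cfg <- dncnn_config()
  expect_equal(cfg$depth, 20L)
  expect_equal(cfg$filters, 64L)
  expect_equal(cfg$momentum, 0.9)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$batch_size, 128L)
  expect_equal(cfg$epochs, 50L)
  expect_error(dncnn_config(depth = 2), "depth")
})

test_that("the network has batch-norm on all but the first and last layer", {
  net <- dncnn_network(dncnn_config(depth = 20, filters = 4))
  expect_length(net$layers, 20L)
  has_bn <- vapply(net$layers, function(l) !is.null(l$gamma), logical(1))
  expect_equal(sum(has_bn), 18L)
  expect_false(has_bn[1]); expect_false(has_bn[20])
  # spatial size is preserved through the stack
  out <- octmelanin:::dncnn_forward(net, array(runif(50 * 50), c(50, 50, 1)))
  expect_equal(dim(out), c(50, 50, 1))
})

test_that("zero conv weights predict a zero residual for any input", {
  net <- dncnn_network(dncnn_config(depth = 5, filters = 3))
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W[] <- 0
    net$layers[[l]]$b[] <- 0
  }
  img <- matrix(sample(0:255, 30 * 30, TRUE), 30, 30)
  expect_true(all(predict(net, img) == 0))
})

test_that("analytic gradients match finite differences", {
  cfg <- dncnn_config(depth = 4, filters = 3, epochs = 1, batch_size = 2,
                      seed = 9)
  net <- dncnn_network(cfg)
  net$layers[[cfg$depth]]$W[] <- stats::rnorm(length(net$layers[[cfg$depth]]$W),
                                              0, 0.1)
  set.seed(2)
  X <- array(stats::runif(6 * 6 * 2), c(6, 6, 2))
  Y <- array(stats::runif(6 * 6 * 2) * 0.1, c(6, 6, 2))
  loss_at <- function(m) mean((octmelanin:::dncnn_forward(m, X, "train")$out - Y)^2)
  fw <- octmelanin:::dncnn_forward(net, X, mode = "train")
  gr <- octmelanin:::dncnn_backward(net, fw$cache,
                                    2 * (fw$out - Y) / length(Y), 6, 6, 2)
  eps <- 1e-6
  for (l in c(1, 2, 3, 4)) for (pn in names(gr[[l]])) {
    i <- 1L
    net2 <- net
    net2$layers[[l]][[pn]][i] <- net$layers[[l]][[pn]][i] + eps
    lp <- loss_at(net2)
    net2$layers[[l]][[pn]][i] <- net$layers[[l]][[pn]][i] - eps
    lm <- loss_at(net2)
    num <- (lp - lm) / (2 * eps)
    ana <- gr[[l]][[pn]][i]
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-4), 1e-2)
  }
})

test_that("training reduces the MSE loss on synthetic patches", {
  ps <- tiny_patches(seed = 4, count = 24, size = 16)
  fit <- dncnn(ps, dncnn_config(depth = 4, filters = 6, epochs = 4,
                                batch_size = 8, learning_rate = 0.05,
                                seed = 1, desk_scale = TRUE))
  lg <- fit$training_log
  expect_equal(nrow(lg), 4L)
  expect_lt(lg$loss[4], lg$loss[1])
  # determinism under the config seed
  fit2 <- dncnn(ps, fit$config)
  expect_identical(fit$training_log, fit2$training_log)
  expect_error(dncnn_train(dncnn_network(), structure(
    list(noisy = array(0, c(4, 4, 0)), residual = array(0, c(4, 4, 0)),
         size = 4L), class = "patch_set")), "empty")
})

test_that("zero-residual data is a fixed point of training", {
  ps <- tiny_patches(seed = 5, count = 12, size = 12)
  ps$residual[] <- 0
  fit <- dncnn(ps, dncnn_config(depth = 3, filters = 4, epochs = 3,
                                batch_size = 6, seed = 2, desk_scale = TRUE))
  expect_lt(utils::tail(fit$training_log$loss, 1), 1e-8)
})

test_that("an untrained model denoises to the identity, clipped 8-bit", {
  net <- dncnn_network(dncnn_config(depth = 5, filters = 4))
  img <- oct_image(matrix(sample(0:255, 40 * 40, TRUE), 40, 40), 0.5)
  dn <- denoise(net, img)
  expect_lt(mean(abs(as.numeric(dn) - as.numeric(img))), 1)
  expect_true(min(dn) >= 0 && max(dn) <= 255)
  expect_error(denoise(net, array(0, c(4, 4, 2))), "single-channel")
})

test_that("the stack fallback equals the compound clean image", {
  st <- simulate_bscan_stack(tiny_scene(fov = 64L),
                             speckle_model(looks = 4, seed = 7), 11)
  fb <- denoise_fallback(st)
  pr <- compound(st, 5)
  expect_equal(unclass(fb), pmin(pmax(round(pr$clean), 0), 255),
               ignore_attr = TRUE)
})

test_that("the single-image fallback smooths flat regions, keeps constants", {
  cimg <- oct_image(matrix(120L, 48, 48), 0.5)
  expect_equal(unclass(denoise_fallback(cimg)), unclass(cimg),
               ignore_attr = TRUE)
  sim <- simulate_escan(tiny_scene(fov = 96L, grain_rate = 0,
                                   confetti_parent_rate = 0),
                        speckle_model(looks = 4, seed = 13))
  dn <- denoise_fallback(sim$image)
  centre <- 20:76
  expect_lt(stats::var(as.numeric(unclass(dn)[centre, centre])),
            stats::var(as.numeric(unclass(sim$image)[centre, centre])))
})

test_that("checkpoints round-trip weights, config and predictions", {
  ps <- tiny_patches(seed = 6, count = 8, size = 12)
  fit <- dncnn(ps, dncnn_config(depth = 3, filters = 3, epochs = 2,
                                batch_size = 4, seed = 3, desk_scale = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  save_dncnn(fit, path)
  back <- load_dncnn(path)
  img <- matrix(sample(0:255, 20 * 20, TRUE), 20, 20)
  expect_equal(predict(back, img), predict(fit, img), tolerance = 1e-12)
  expect_equal(back$config$depth, fit$config$depth)
})
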