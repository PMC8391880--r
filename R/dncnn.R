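#' Configuration of the residual-learning speckle denoiser
#'
#' The network is a VGG-style stack of 3 x 3 convolutions: layer 1 is
#' conv + ReLU, layers 2 .. depth-1 are conv + batch-norm + ReLU, and the
#' last layer is a single linear 3 x 3 convolution that reconstructs the
#' residual (noise map). Training minimizes the mean squared error between
#' the predicted and true residual with SGD plus momentum. The device-scale
#' defaults are depth 20, 64 filters, momentum 0.9, learning rate 0.001,
#' mini-batch 128 and 50 epochs; `desk_scale = TRUE` switches any argument
#' you did not set explicitly to a small CPU preset (depth 7, 16 filters,
#' 5 epochs, batch 32, learning rate 0.01) that trains in minutes.
#'
#' @param depth number of convolutional layers (>= 3).
#' @param filters feature maps per hidden layer.
#' @param kernel convolution kernel side (only 3 is implemented).
#' @param momentum SGD momentum coefficient.
#' @param learning_rate SGD step size.
#' @param batch_size mini-batch size.
#' @param epochs training epochs.
#' @param seed integer seed for weight initialization and batch shuffling.
#' @param desk_scale logical; apply the small-CPU preset.
#' @return a `dncnn_config` object.
#' @export
dncnn_config <- function(depth = 20L, filters = 64L, kernel = 3L,
                         momentum = 0.9, learning_rate = 0.001,
                         batch_size = 128L, epochs = 50L, seed = 1L,
                         desk_scale = FALSE) {
  if (desk_scale) {
    if (missing(depth)) depth <- 7L
    if (missing(filters)) filters <- 16L
    if (missing(epochs)) epochs <- 5L
    if (missing(batch_size)) batch_size <- 32L
    if (missing(learning_rate)) learning_rate <- 0.01
  }
  if (depth < 3) stop("`depth` must be >= 3", call. = FALSE)
  if (kernel != 3L) stop("only 3 x 3 kernels are implemented", call. = FALSE)
  if (any(c(filters, momentum, learning_rate, batch_size, epochs) <= 0) &&
      momentum != 0)
    stop("hyperparameters must be positive", call. = FALSE)
  structure(list(depth = as.integer(depth), filters = as.integer(filters),
                 kernel = 3L, optimizer = "sgd_momentum",
                 momentum = momentum, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 desk_scale = isTRUE(desk_scale)),
            class = "dncnn_config")
}

BN_EPS <- 1e-5
BN_RUN_MOMENTUM <- 0.9

# ---- im2col machinery -------------------------------------------------
# Activations move through the network as matrices of shape
# (h*w*n_samples) x channels, rows ordered row-fastest, then column, then
# sample. im2col unfolds the 3x3 zero-padded neighbourhood of every pixel
# into a (h*w*n) x (9*channels) matrix so each convolution is one GEMM.

im2col3 <- function(A, h, w, n, C) {
  P <- array(0, c(h + 2L, w + 2L, n, C))
  P[2:(h + 1L), 2:(w + 1L), , ] <- A
  M <- matrix(0, h * w * n, 9L * C)
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    M[, ((k - 1L) * C + 1L):(k * C)] <-
      P[(1:h) + 1L + di, (1:w) + 1L + dj, , ]
  }
  M
}

col2im3 <- function(dM, h, w, n, C) {
  dP <- array(0, c(h + 2L, w + 2L, n, C))
  k <- 0L
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    blk <- dM[, ((k - 1L) * C + 1L):(k * C)]
    dim(blk) <- c(h, w, n, C)
    ri <- (1:h) + 1L + di; cj <- (1:w) + 1L + dj
    dP[ri, cj, , ] <- dP[ri, cj, , ] + blk
  }
  dA <- dP[2:(h + 1L), 2:(w + 1L), , , drop = FALSE]
  dim(dA) <- c(h * w * n, C)
  dA
}

# ---- parameter initialization -----------------------------------------

dncnn_init_params <- function(config) {
  D <- config$depth; Fh <- config$filters
  c_in <- c(1L, rep(Fh, D - 1L))
  c_out <- c(rep(Fh, D - 1L), 1L)
  layers <- vector("list", D)
  for (l in seq_len(D)) {
    fan_in <- 9L * c_in[l]
    # the reconstruction layer starts at zero so the untrained network is
    # the zero-residual predictor and training can only improve on it
    W <- if (l == D) matrix(0, fan_in, c_out[l])
         else matrix(stats::rnorm(fan_in * c_out[l], 0, sqrt(2 / fan_in)),
                     fan_in, c_out[l])
    layers[[l]] <- list(W = W, b = numeric(c_out[l]))
    if (l > 1L && l < D) {
      layers[[l]]$gamma <- rep(1, c_out[l])
      layers[[l]]$beta <- numeric(c_out[l])
      layers[[l]]$run_mean <- numeric(c_out[l])
      layers[[l]]$run_var <- rep(1, c_out[l])
    }
  }
  layers
}

#' Build an untrained denoiser network
#'
#' Weights are He-initialized under `config$seed`; batch-norm scale/offset
#' start at 1/0 and the running statistics at 0/1, so the untrained network
#' is already a valid (if useless) residual predictor.
#'
#' @param config a [dncnn_config()].
#' @return an object of class `dncnn` with empty training log.
#' @export
dncnn_network <- function(config = dncnn_config()) {
  stopifnot(inherits(config, "dncnn_config"))
  layers <- with_seed(config$seed, dncnn_init_params(config))
  structure(list(layers = layers, config = config,
                 training_log = data.frame(epoch = integer(0),
                                           loss = numeric(0))),
            class = "dncnn")
}

# forward pass; batch X: array (h, w, n) in [0,1]
# mode "train" caches intermediates and uses batch statistics
dncnn_forward <- function(model, X, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  h <- dim(X)[1]; w <- dim(X)[2]
  n <- if (length(dim(X)) == 3L) dim(X)[3] else 1L
  D <- model$config$depth
  A <- matrix(as.numeric(X), h * w * n, 1L)
  cache <- if (mode == "train") vector("list", D)
  layers <- model$layers
  for (l in seq_len(D)) {
    C_in <- ncol(A)
    dim(A) <- c(h, w, n, C_in)
    M <- im2col3(A, h, w, n, C_in)
    Z <- M %*% layers[[l]]$W
    Z <- sweep(Z, 2L, layers[[l]]$b, `+`)
    st <- list(C_in = C_in)
    if (mode == "train") st$M <- M
    if (l > 1L && l < D) {                     # batch norm
      if (mode == "train") {
        mu <- colMeans(Z)
        xc <- sweep(Z, 2L, mu, `-`)
        v <- colMeans(xc^2)
        invstd <- 1 / sqrt(v + BN_EPS)
        xhat <- sweep(xc, 2L, invstd, `*`)
        st$bn <- list(mu = mu, var = v, invstd = invstd, xhat = xhat)
      } else {
        invstd <- 1 / sqrt(layers[[l]]$run_var + BN_EPS)
        xhat <- sweep(sweep(Z, 2L, layers[[l]]$run_mean, `-`),
                      2L, invstd, `*`)
      }
      Z <- sweep(sweep(xhat, 2L, layers[[l]]$gamma, `*`),
                 2L, layers[[l]]$beta, `+`)
    }
    if (l < D) {                               # ReLU (all but last layer)
      relu_mask <- Z > 0
      Z <- Z * relu_mask
      if (mode == "train") st$relu <- relu_mask
    }
    if (mode == "train") cache[[l]] <- st
    A <- Z
  }
  out <- array(A, c(h, w, n))
  if (mode == "train") list(out = out, cache = cache) else out
}

# backward pass; dOut: array (h, w, n); returns gradients per layer
dncnn_backward <- function(model, cache, dOut, h, w, n) {
  D <- model$config$depth
  layers <- model$layers
  grads <- vector("list", D)
  dA <- matrix(as.numeric(dOut), h * w * n, 1L)
  for (l in rev(seq_len(D))) {
    st <- cache[[l]]
    if (l < D) dA <- dA * st$relu
    if (l > 1L && l < D) {
      bn <- st$bn
      Nb <- nrow(dA)
      dgamma <- colSums(dA * bn$xhat)
      dbeta <- colSums(dA)
      dxhat <- sweep(dA, 2L, layers[[l]]$gamma, `*`)
      # dx = invstd/N * (N*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
      s1 <- colSums(dxhat)
      s2 <- colSums(dxhat * bn$xhat)
      dA <- sweep(dxhat * Nb, 2L, s1, `-`)
      dA <- dA - sweep(bn$xhat, 2L, s2, `*`)
      dA <- sweep(dA, 2L, bn$invstd / Nb, `*`)
      grads[[l]] <- list(W = crossprod(st$M, dA), b = colSums(dA),
                         gamma = dgamma, beta = dbeta)
    } else {
      grads[[l]] <- list(W = crossprod(st$M, dA), b = colSums(dA))
    }
    if (l > 1L) {
      dM <- dA %*% t(layers[[l]]$W)
      dA <- col2im3(dM, h, w, n, st$C_in)
    }
  }
  grads
}

#' Train the residual-learning denoiser
#'
#' Minimizes the MSE between the network output and the true residual
#' (noise map) over the patch set, with SGD + momentum. Inputs are scaled
#' to \[0, 1\] internally; per-epoch losses are appended to the training
#' log. Deterministic under `config$seed`.
#'
#' @param model an untrained or previously trained [dncnn_network()].
#' @param patches a `patch_set` (see [extract_patches()] and
#'   [c_patch_sets]); gray-level units.
#' @param config optional [dncnn_config()] overriding the model's.
#' @param verbose print per-epoch losses.
#' @return the trained `dncnn` model.
#' @export
dncnn_train <- function(model, patches, config = model$config,
                        verbose = FALSE) {
  stopifnot(inherits(model, "dncnn"), inherits(patches, "patch_set"))
  n_all <- dim(patches$noisy)[3]
  if (is.null(n_all) || n_all < 1)
    stop("patch set is empty", call. = FALSE)
  h <- dim(patches$noisy)[1]; w <- dim(patches$noisy)[2]
  X <- patches$noisy / 255
  Yres <- patches$residual / 255
  layers <- model$layers
  D <- config$depth
  vel <- lapply(layers, function(lay) lapply(lay[intersect(
    names(lay), c("W", "b", "gamma", "beta"))], function(p) p * 0))
  log_rows <- model$training_log
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n_all)
      losses <- numeric(0)
      for (start in seq(1L, n_all, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n_all)]
        nb <- length(idx)
        Xb <- X[, , idx, drop = FALSE]
        Yb <- Yres[, , idx, drop = FALSE]
        mtmp <- list(layers = layers, config = config)
        class(mtmp) <- "dncnn"
        fw <- dncnn_forward(mtmp, Xb, mode = "train")
        err <- fw$out - Yb
        losses <- c(losses, mean(err^2))
        dOut <- 2 * err / length(err)
        grads <- dncnn_backward(mtmp, fw$cache, dOut, h, w, nb)
        for (l in seq_len(D)) {
          for (p in names(vel[[l]])) {
            vel[[l]][[p]] <- config$momentum * vel[[l]][[p]] -
              config$learning_rate * grads[[l]][[p]]
            layers[[l]][[p]] <- layers[[l]][[p]] + vel[[l]][[p]]
          }
          if (l > 1L && l < D) {   # running statistics for inference
            bn <- fw$cache[[l]]$bn
            layers[[l]]$run_mean <- BN_RUN_MOMENTUM * layers[[l]]$run_mean +
              (1 - BN_RUN_MOMENTUM) * bn$mu
            layers[[l]]$run_var <- BN_RUN_MOMENTUM * layers[[l]]$run_var +
              (1 - BN_RUN_MOMENTUM) * bn$var
          }
        }
      }
      log_rows <- rbind(log_rows,
                        data.frame(epoch = nrow(log_rows) + 1L,
                                   loss = mean(losses)))
      if (verbose)
        message(sprintf("epoch %d: loss %.3g", ep, mean(losses)))
    }
  })
  model$layers <- layers
  model$config <- config
  model$training_log <- log_rows
  model
}

#' Fit a speckle denoiser to compounding patches
#'
#' Convenience wrapper: builds the network from `config` and trains it on
#' `patches`. This is the modelling entry point; the returned object has
#' `print`, `plot` (loss curve) and `predict` (residual map) methods, and
#' [denoise()] applies it to an image.
#'
#' @inheritParams dncnn_train
#' @param config a [dncnn_config()].
#' @return a fitted `dncnn` object.
#' @export
#' @examples
#' \donttest{
#' stack <- simulate_bscan_stack(melanin_scene(fov_px = c(96, 96)),
#'                               speckle_model(looks = 4, seed = 7))
#' pair <- compound(stack, n_lines = 5)
#' patches <- extract_patches(pair, count = 32, size = 40, seed = 1)
#' fit <- dncnn(patches, dncnn_config(desk_scale = TRUE, depth = 4,
#'                                    filters = 4, epochs = 2))
#' fit
#' }
dncnn <- function(patches, config = dncnn_config(desk_scale = TRUE)) {
  dncnn_train(dncnn_network(config), patches, config)
}

#' @export
print.dncnn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<dncnn> %d conv layers (%d with batch-norm), %d filters\n",
              cfg$depth, max(cfg$depth - 2L, 0L), cfg$filters))
  if (nrow(x$training_log))
    cat(sprintf("  trained %d epochs; loss %.4g -> %.4g\n",
                nrow(x$training_log), x$training_log$loss[1],
                utils::tail(x$training_log$loss, 1)))
  else cat("  untrained\n")
  invisible(x)
}

#' @export
plot.dncnn <- function(x, ...) {
  if (!nrow(x$training_log)) stop("model is untrained", call. = FALSE)
  plot(x$training_log$epoch, x$training_log$loss, type = "b",
       xlab = "epoch", ylab = "MSE loss", main = "denoiser training", ...)
  invisible(x)
}

#' Predict the residual (noise map) of an image
#'
#' @param object a fitted `dncnn`.
#' @param image an [oct_image] or numeric matrix in gray levels.
#' @param ... unused.
#' @return double matrix of predicted residual, gray-level units.
#' @export
predict.dncnn <- function(object, image, ...) {
  m <- as.numeric(image) / 255
  dim(m) <- c(dim(image)[1], dim(image)[2], 1L)
  res <- dncnn_forward(object, m, mode = "infer")
  matrix(res, dim(image)[1], dim(image)[2]) * 255
}

#' Denoise an 8-bit image with a trained residual-learning model
#'
#' Residual learning: the network predicts the noise map, and
#' `clip(input - residual, 0, 255)` is the denoised image. The whole image
#' is passed through the network in one shot (the convolutions are
#' zero-padded internally), so there are no tiling seams.
#'
#' @param model a fitted `dncnn`.
#' @param image a single-channel 8-bit [oct_image] (or integer matrix).
#' @return the denoised [oct_image], same shape and labels.
#' @export
denoise <- function(model, image) {
  stopifnot(inherits(model, "dncnn"))
  if (!is.matrix(image))
    stop("`image` must be a single-channel matrix", call. = FALSE)
  res <- predict(model, image)
  out <- unclass(image) - res
  dim(out) <- dim(image)
  as_oct_image(out,
               scale_um_per_px = attr(image, "scale_um_per_px") %||% 0.5,
               condition = attr(image, "condition"),
               layer = attr(image, "layer"))
}

#' Learning-free denoising fallback
#'
#' Lets the pipeline run without a trained model. For a B-scan stack the
#' fallback is exactly the full-stack compound mean (the clean-image
#' definition of spatial compounding). For a single image it is a 3 x 3
#' median filter — an edge-preserving step that suppresses the heavy tail
#' of multiplicative speckle without shifting object boundaries — followed
#' by a light Gaussian (sigma 0.6 px) that regularizes the remaining
#' single-pixel noise.
#'
#' @param x a `bscan_stack` or a single [oct_image]/matrix.
#' @return an [oct_image].
#' @export
denoise_fallback <- function(x) {
  if (inherits(x, "bscan_stack")) {
    pair_clean <- Reduce(`+`, lapply(x$slices, function(s) {
      m <- as.numeric(s); dim(m) <- dim(s); m
    })) / length(x$slices)
    return(as_oct_image(pair_clean, x$scale_um_per_px))
  }
  if (!is.matrix(x)) stop("input must be a stack or a matrix", call. = FALSE)
  med <- median3x3(unclass(x))
  med <- gauss_blur(med, sigma = 0.6)
  as_oct_image(med,
               scale_um_per_px = attr(x, "scale_um_per_px") %||% 0.5,
               condition = attr(x, "condition"), layer = attr(x, "layer"))
}

#' Save / load a denoiser checkpoint
#'
#' Single-file JSON checkpoint with the configuration, all weights and the
#' training log embedded, so [denoise()] is reproducible from one artifact.
#'
#' @param model a `dncnn`.
#' @param path checkpoint path (`.json`).
#' @return `load_dncnn` returns the restored model.
#' @export
save_dncnn <- function(model, path) {
  stopifnot(inherits(model, "dncnn"))
  payload <- list(
    config = unclass(model$config),
    training_log = model$training_log,
    layers = lapply(model$layers, function(lay) {
      lay$W_dim <- dim(lay$W)
      lay$W <- as.numeric(lay$W)
      lay
    }))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_dncnn
#' @export
load_dncnn <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- p$config
  config <- dncnn_config(depth = cfg$depth, filters = cfg$filters,
                         momentum = cfg$momentum,
                         learning_rate = cfg$learning_rate,
                         batch_size = cfg$batch_size, epochs = cfg$epochs,
                         seed = cfg$seed, desk_scale = isTRUE(cfg$desk_scale))
  num <- function(x) as.numeric(unlist(x))
  layers <- lapply(p$layers, function(lay) {
    out <- list(W = matrix(num(lay$W), lay$W_dim[[1]], lay$W_dim[[2]]),
                b = num(lay$b))
    for (f in c("gamma", "beta", "run_mean", "run_var"))
      if (!is.null(lay[[f]])) out[[f]] <- num(lay[[f]])
    out
  })
  log <- data.frame(
    epoch = vapply(p$training_log, function(r) as.integer(r$epoch), 1L),
    loss = vapply(p$training_log, function(r) as.numeric(r$loss), 1.0))
  structure(list(layers = layers, config = config, training_log = log),
            class = "dncnn")
}
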