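#' Spatial compounding of adjacent B-scan slices
#'
#' Averaging many partially de-correlated adjacent slices suppresses
#' multiplicative speckle; the full-stack average serves as the clean
#' (low-speckle) reference, while the average of `n_lines` slices taken
#' symmetrically outward from the centre slice is the matched noisy image.
#' The signed difference `noisy - clean` is the residual (noise map) a
#' residual-learning denoiser is trained to predict.
#'
#' All means are computed in floating point; nothing is re-quantized to
#' 8 bits inside the residual computation, so `clean + residual` reproduces
#' `noisy` exactly.
#'
#' @param stack a [simulate_bscan_stack()] result, or any list with a
#'   `slices` element containing equally sized matrices.
#' @param n_lines odd number of centre-out slices averaged into the noisy
#'   image; must satisfy `1 <= n_lines < length(slices)`.
#' @return a list of class `compounding_pair`: `clean`, `noisy`, `residual`
#'   (double matrices), `n_lines`, `scale_um_per_px`.
#' @export
compound <- function(stack, n_lines = 5L) {
  slices <- if (is.list(stack) && !is.null(stack$slices)) stack$slices
            else stack
  S <- length(slices)
  if (S < 2) stop("stack must contain at least 2 slices", call. = FALSE)
  if (!is.numeric(n_lines) || n_lines < 1 || n_lines >= S)
    stop(sprintf("`n_lines` must satisfy 1 <= n_lines < %d (stack size)", S),
         call. = FALSE)
  n_lines <- as.integer(n_lines)
  if (n_lines %% 2L == 0L)
    stop("`n_lines` must be odd (centre-out symmetric selection)",
         call. = FALSE)
  centre <- (S + 1L) %/% 2L
  half <- (n_lines - 1L) %/% 2L
  sel <- (centre - half):(centre + half)
  if (sel[1] < 1L || sel[n_lines] > S)
    stop("centre-out window exceeds the stack", call. = FALSE)
  acc_all <- Reduce(`+`, lapply(slices, function(s) {
    m <- as.numeric(s); dim(m) <- dim(s); m
  }))
  clean <- acc_all / S
  acc_sel <- Reduce(`+`, lapply(slices[sel], function(s) {
    m <- as.numeric(s); dim(m) <- dim(s); m
  }))
  noisy <- acc_sel / n_lines
  structure(list(clean = clean, noisy = noisy, residual = noisy - clean,
                 n_lines = n_lines,
                 scale_um_per_px = stack$scale_um_per_px %||% NA_real_),
            class = "compounding_pair")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.compounding_pair <- function(x, ...) {
  cat(sprintf("<compounding_pair> %d x %d px, noisy = %d-line compound\n",
              nrow(x$clean), ncol(x$clean), x$n_lines))
  cat(sprintf("  residual range [%.2f, %.2f] gray\n",
              min(x$residual), max(x$residual)))
  invisible(x)
}

#' Randomly crop co-located noisy/residual training patches
#'
#' Uniform-random top-left corners, fully inside the image; the noisy patch
#' and its residual (noise-map) patch always cover the same window.
#'
#' @param pair a [compound()] result.
#' @param count number of patch pairs (device-scale default 512 per image
#'   pair).
#' @param size square patch side in pixels (default 50).
#' @param seed integer seed for the crop positions.
#' @return a list of class `patch_set`: `noisy` and `residual` arrays of
#'   dimension `size x size x count`, plus `corners` (top-left row/col) and
#'   `size`.
#' @export
extract_patches <- function(pair, count = 512L, size = 50L, seed = 1L) {
  stopifnot(inherits(pair, "compounding_pair"))
  nr <- nrow(pair$noisy); nc <- ncol(pair$noisy)
  if (count < 1) stop("`count` must be >= 1", call. = FALSE)
  if (size > nr || size > nc)
    stop("`size` exceeds the image dimensions", call. = FALSE)
  count <- as.integer(count); size <- as.integer(size)
  corners <- with_seed(seed, cbind(
    row = sample.int(nr - size + 1L, count, replace = TRUE),
    col = sample.int(nc - size + 1L, count, replace = TRUE)))
  noisy <- array(0, c(size, size, count))
  residual <- array(0, c(size, size, count))
  for (k in seq_len(count)) {
    ri <- corners[k, 1L]:(corners[k, 1L] + size - 1L)
    ci <- corners[k, 2L]:(corners[k, 2L] + size - 1L)
    noisy[, , k] <- pair$noisy[ri, ci]
    residual[, , k] <- pair$residual[ri, ci]
  }
  structure(list(noisy = noisy, residual = residual, corners = corners,
                 size = size),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d co-located noisy/residual pairs of %d x %d px\n",
              dim(x$noisy)[3], x$size, x$size))
  invisible(x)
}

#' Concatenate patch sets
#'
#' Pools the patches of several image pairs into one training set.
#'
#' @param ... `patch_set` objects (or a single list of them) with a common
#'   patch size.
#' @return a combined `patch_set`.
#' @export
c_patch_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "patch_set")) sets <- sets[[1]]
  stopifnot(all(vapply(sets, inherits, logical(1), "patch_set")))
  size <- sets[[1]]$size
  noisy <- array(unlist(lapply(sets, `[[`, "noisy")), c(size, size,
               sum(vapply(sets, function(s) dim(s$noisy)[3], numeric(1)))))
  residual <- array(unlist(lapply(sets, `[[`, "residual")), dim(noisy))
  structure(list(noisy = noisy, residual = residual,
                 corners = do.call(rbind, lapply(sets, `[[`, "corners")),
                 size = size),
            class = "patch_set")
}

#' Write a compounding pair to disk
#'
#' `clean` and `noisy` are quantized to 8-bit PNG only on export; the signed
#' residual is stored as a 16-bit TIFF with a +128 gray-level offset (value
#' stored = `(residual + 128) / 256` of full scale, saturated at the ends),
#' so typical residuals round-trip to within the 16-bit quantization step.
#'
#' @param pair a [compound()] result.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the three file paths.
#' @export
save_compounding_pair <- function(pair, dir, prefix = "pair") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_clean <- file.path(dir, paste0(prefix, "_clean.png"))
  p_noisy <- file.path(dir, paste0(prefix, "_noisy.png"))
  p_res <- file.path(dir, paste0(prefix, "_residual.tif"))
  png::writePNG(pmin(pmax(round(pair$clean), 0), 255) / 255, p_clean)
  png::writePNG(pmin(pmax(round(pair$noisy), 0), 255) / 255, p_noisy)
  tiff::writeTIFF(pmin(pmax((pair$residual + 128) / 256, 0), 1), p_res,
                  bits.per.sample = 16L)
  invisible(c(clean = p_clean, noisy = p_noisy, residual = p_res))
}
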