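#' 8-bit OCT image container
#'
#' An `oct_image` is an integer matrix of gray levels in \[0, 255\] (rows =
#' image rows, columns = image columns) carrying the physical pixel pitch in
#' micrometres and optional cohort labels. It is the unit every pipeline
#' stage consumes and produces.
#'
#' @param pixels numeric or integer matrix; values must lie in \[0, 255\].
#' @param scale_um_per_px positive pixel pitch in micrometres per pixel.
#' @param condition optional condition label, `"lesion"` or `"perilesional"`.
#' @param layer optional skin-layer label: `"stratum_spinosum"`, `"DEJ"` or
#'   `"papillary_dermis"`.
#'
#' @return An `oct_image` object (integer matrix with attributes
#'   `scale_um_per_px`, `condition`, `layer`).
#' @export
#' @examples
#' img <- oct_image(matrix(128L, 32, 32), scale_um_per_px = 0.5)
#' img
oct_image <- function(pixels, scale_um_per_px = 0.5, condition = NULL,
                      layer = NULL) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (!is.numeric(scale_um_per_px) || length(scale_um_per_px) != 1L ||
      !is.finite(scale_um_per_px) || scale_um_per_px <= 0)
    stop("`scale_um_per_px` must be a single positive number", call. = FALSE)
  px <- round(pixels)
  if (anyNA(px) || min(px) < 0 || max(px) > 255)
    stop("pixel values must lie in [0, 255]", call. = FALSE)
  storage.mode(px) <- "integer"
  if (!is.null(condition))
    condition <- match.arg(condition, c("lesion", "perilesional"))
  if (!is.null(layer))
    layer <- match.arg(layer, c("stratum_spinosum", "DEJ", "papillary_dermis"))
  structure(px,
            scale_um_per_px = scale_um_per_px,
            condition = condition, layer = layer,
            class = c("oct_image", "matrix", "array"))
}

#' @export
print.oct_image <- function(x, ...) {
  cat(sprintf("<oct_image> %d x %d px, %.3g um/px (%.0f x %.0f um)\n",
              nrow(x), ncol(x), oct_scale(x),
              nrow(x) * oct_scale(x), ncol(x) * oct_scale(x)))
  lab <- c(attr(x, "condition"), attr(x, "layer"))
  if (length(lab)) cat("  labels:", paste(lab, collapse = " / "), "\n")
  cat(sprintf("  gray range [%d, %d], mean %.1f\n",
              min(x), max(x), mean(x)))
  invisible(x)
}

#' @rdname oct_image
#' @param x object to test or query.
#' @export
is_oct_image <- function(x) inherits(x, "oct_image")

#' @rdname oct_image
#' @export
oct_scale <- function(x) {
  s <- attr(x, "scale_um_per_px")
  if (is.null(s)) stop("object carries no um/px scale", call. = FALSE)
  s
}

# internal: numeric matrix in [0,255] -> oct_image, clipping + rounding
as_oct_image <- function(m, scale_um_per_px, condition = NULL, layer = NULL) {
  m <- pmin(pmax(round(m), 0), 255)
  oct_image(m, scale_um_per_px = scale_um_per_px,
            condition = condition, layer = layer)
}

#' Read and write 8-bit grayscale OCT images
#'
#' PNG and TIFF are supported. Images are stored with 8-bit pixel depth;
#' multi-channel input is rejected, and deeper bit depths are only accepted
#' with `coerce = TRUE`, which linearly rescales to \[0, 255\].
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param scale_um_per_px pixel pitch attached to the loaded image.
#' @param coerce logical; linearly rescale non-8-bit input instead of failing.
#' @param condition,layer optional labels attached to the loaded image.
#' @return `load_oct_image` returns an [oct_image]; `save_oct_image`
#'   invisibly returns `path`.
#' @export
load_oct_image <- function(path, scale_um_per_px = 0.5, coerce = FALSE,
                           condition = NULL, layer = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(raw)) == 3L) {
    nch <- dim(raw)[3L]
    if (!coerce)
      stop(sprintf("expected a single-channel image, got %d channels", nch),
           call. = FALSE)
    raw <- raw[, , 1L]
  }
  # readPNG/readTIFF return [0,1]; 8-bit images hit exact k/255 grid points
  g <- raw * 255
  if (!coerce && max(abs(g - round(g))) > 1e-6)
    stop("image is not 8-bit; pass coerce = TRUE to rescale", call. = FALSE)
  if (coerce && max(g) > 0) g <- g / max(g) * 255
  as_oct_image(g, scale_um_per_px, condition = condition, layer = layer)
}

#' @rdname load_oct_image
#' @param image an [oct_image] or integer matrix in \[0, 255\].
#' @export
save_oct_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  m <- unclass(image) / 255
  attributes(m) <- list(dim = dim(image))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}

#' Save a binary mask as an 8-bit {0,255} PNG
#'
#' @param mask logical or 0/1 matrix.
#' @param path output `.png` path.
#' @export
save_mask <- function(mask, path) {
  m <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  png::writePNG(m, path)
  invisible(path)
}

#' Peak signal-to-noise ratio between two 8-bit images
#'
#' Standard definition on the \[0, 255\] scale:
#' `PSNR = 10 log10(255^2 / MSE)`.
#'
#' @param x,ref images or numeric matrices of identical size.
#' @return PSNR in decibels (`Inf` for identical images).
#' @export
psnr <- function(x, ref) {
  if (!all(dim(x) == dim(ref))) stop("dimension mismatch", call. = FALSE)
  mse <- mean((as.numeric(x) - as.numeric(ref))^2)
  if (mse == 0) return(Inf)
  10 * log10(255^2 / mse)
}
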