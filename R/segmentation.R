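#' Parameters of the melanin detection chain
#'
#' Defaults follow the detection recipe: CLAHE over a 40 x 40 tile grid with
#' an exponential target distribution (rate 0.1) and contrast-limiting
#' factor 0.001; melanin candidates are enhanced pixels strictly above the
#' 0.6 normalized threshold (gray level 153); tissue is strictly above gray
#' 38 in the enhanced image; grain objects must exceed 0.5 um equivalent
#' diameter after a 2 x 2 opening; confetti objects must exceed 8.42 square
#' micrometres (an equivalent circle of about 3.3 um diameter) after a
#' radius-1 closing. All three thresholds are strict inequalities.
#'
#' @param clahe_tiles integer 2-vector, tile grid (rows, cols), or `NULL`
#'   (default) to size the grid from the image so each tile covers about
#'   `clahe_tile_um` micrometres — the physical tile the 40 x 40 grid
#'   realizes on a 897 x 899 px device field of view.
#' @param clahe_tile_um target physical tile side when `clahe_tiles` is
#'   `NULL`.
#' @param clahe_lambda rate of the exponential target distribution.
#' @param clahe_clip contrast-limiting factor (see [enhance_contrast()]).
#' @param clahe_bins histogram bins per tile.
#' @param melanin_threshold normalized brightness threshold in (0, 1).
#' @param tissue_threshold_gray tissue gray-level threshold (8-bit).
#' @param grain_min_diameter_um minimum grain equivalent diameter.
#' @param confetti_min_area_um2 minimum confetti area.
#' @param confetti_close_se structuring element of the confetti aggregation
#'   step (see [binary_close()]).
#' @param connectivity component connectivity, 8 (default) or 4.
#' @return a `segmentation_params` object.
#' @export
segmentation_params <- function(clahe_tiles = NULL,
                                clahe_tile_um = 12.5,
                                clahe_lambda = 0.1,
                                clahe_clip = 0.001,
                                clahe_bins = 256L,
                                melanin_threshold = 0.6,
                                tissue_threshold_gray = 38L,
                                grain_min_diameter_um = 0.5,
                                confetti_min_area_um2 = 8.42,
                                confetti_close_se = "box3",
                                connectivity = 8) {
  if (melanin_threshold <= 0 || melanin_threshold >= 1)
    stop("`melanin_threshold` must lie in (0, 1)", call. = FALSE)
  gray <- round(melanin_threshold * 255)
  if (gray <= tissue_threshold_gray || gray > 255)
    stop("melanin threshold must exceed the tissue threshold", call. = FALSE)
  if (confetti_min_area_um2 <= pi * (grain_min_diameter_um / 2)^2)
    stop("confetti area gate must exceed the grain diameter gate",
         call. = FALSE)
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  if (!is.null(clahe_tiles)) {
    clahe_tiles <- as.integer(clahe_tiles)
    if (any(clahe_tiles < 1)) stop("`clahe_tiles` must be >= 1", call. = FALSE)
  }
  structure(list(clahe_tiles = clahe_tiles,
                 clahe_tile_um = clahe_tile_um,
                 clahe_lambda = clahe_lambda, clahe_clip = clahe_clip,
                 clahe_bins = as.integer(clahe_bins),
                 melanin_threshold = melanin_threshold,
                 melanin_threshold_gray = as.integer(gray),
                 tissue_threshold_gray = as.integer(tissue_threshold_gray),
                 grain_min_diameter_um = grain_min_diameter_um,
                 confetti_min_area_um2 = confetti_min_area_um2,
                 confetti_close_se = confetti_close_se,
                 connectivity = as.integer(connectivity)),
            class = "segmentation_params")
}

# clip a tile histogram and redistribute the excess over under-cap bins;
# real-valued counts, iterated to convergence so no bin ends above the cap
clip_histogram <- function(h, cap) {
  for (it in 1:100) {
    over <- pmax(h - cap, 0)
    tot <- sum(over)
    if (tot < 1e-9) break
    h <- pmin(h, cap)
    under <- h < cap
    if (!any(under)) break
    h[under] <- h[under] + tot / sum(under)
  }
  h
}

# per-tile clip limit in counts: the minimum is the flat-histogram level
# ceil(npix/nbins); the limiting factor adds that fraction of the headroom
# up to the full tile count
clahe_clip_limit <- function(npix, nbins, clip) {
  minc <- ceiling(npix / nbins)
  minc + max(0, floor(clip * (npix - minc)))
}

# mapping for one tile histogram: clipped CDF pushed through the inverse
# CDF of an exponential (rate lambda) truncated to [0, 1]
clahe_tile_mapping <- function(hist_counts, cap, lambda) {
  h <- clip_histogram(hist_counts, cap)
  P <- cumsum(h) / sum(h)
  g <- -log(1 - P * (1 - exp(-lambda))) / lambda
  as.integer(round(pmin(pmax(g, 0), 1) * 255))
}

#' Exponential contrast-limited adaptive histogram equalization
#'
#' The image is divided into `clahe_tiles` tiles; each tile's 256-bin
#' histogram is clipped at the contrast limit (excess redistributed over the
#' remaining bins) and its cumulative distribution is pushed through the
#' inverse CDF of an exponential target distribution with rate
#' `clahe_lambda`, truncated to the unit interval. Every pixel is remapped
#' by bilinear interpolation between the mappings of the four surrounding
#' tile centres, and the result is quantized back to 8 bits so downstream
#' gray-level thresholds are exact.
#'
#' The contrast limit is expressed in counts as
#' `ceil(npix/nbins) + floor(clahe_clip * (npix - ceil(npix/nbins)))`: the
#' floor is the flat-histogram level, `clahe_clip = 1` disables clipping,
#' and the default 0.001 is a very strong limit under which the mapping
#' stays close to the identity.
#'
#' @param image an [oct_image] or integer matrix in \[0, 255\].
#' @param params a [segmentation_params()].
#' @return integer matrix of enhanced gray levels in \[0, 255\].
#' @export
enhance_contrast <- function(image, params = segmentation_params()) {
  nr <- nrow(image); nc <- ncol(image)
  tiles <- params$clahe_tiles
  if (is.null(tiles)) {
    scale <- attr(image, "scale_um_per_px") %||% 0.5
    tiles <- pmax(2L, as.integer(round(c(nr, nc) * scale /
                                         params$clahe_tile_um)))
  }
  ntr <- tiles[1]; ntc <- tiles[2]
  if (ntr > nr || ntc > nc)
    stop("tile grid larger than the image", call. = FALSE)
  nbins <- params$clahe_bins
  img <- unclass(image)
  r_edges <- round(seq(0, nr, length.out = ntr + 1))
  c_edges <- round(seq(0, nc, length.out = ntc + 1))
  maps <- array(0L, c(ntr, ntc, nbins))
  for (tr in seq_len(ntr)) for (tc in seq_len(ntc)) {
    sub <- img[(r_edges[tr] + 1L):r_edges[tr + 1L],
               (c_edges[tc] + 1L):c_edges[tc + 1L]]
    h <- tabulate(sub + 1L, nbins)
    cap <- clahe_clip_limit(length(sub), nbins, params$clahe_clip)
    maps[tr, tc, ] <- clahe_tile_mapping(h, cap, params$clahe_lambda)
  }
  # bilinear interpolation between the four surrounding tile centres
  centres_r <- (r_edges[-(ntr + 1)] + r_edges[-1] + 1) / 2
  centres_c <- (c_edges[-(ntc + 1)] + c_edges[-1] + 1) / 2
  interp_axis <- function(coords, centres) {
    lo <- findInterval(coords, centres)
    lo <- pmin(pmax(lo, 1L), length(centres) - 1L)
    if (length(centres) == 1L) return(list(lo = rep(1L, length(coords)),
                                           w = rep(1, length(coords))))
    hi <- lo + 1L
    w <- (centres[hi] - coords) / (centres[hi] - centres[lo])
    w <- pmin(pmax(w, 0), 1)
    list(lo = lo, w = w)
  }
  ax_r <- interp_axis(seq_len(nr), centres_r)
  ax_c <- interp_axis(seq_len(nc), centres_c)
  lo_r <- matrix(ax_r$lo, nr, nc); w_r <- matrix(ax_r$w, nr, nc)
  lo_c <- matrix(ax_c$lo, nr, nc, byrow = TRUE)
  w_c <- matrix(ax_c$w, nr, nc, byrow = TRUE)
  hi_r <- pmin(lo_r + 1L, ntr); hi_c <- pmin(lo_c + 1L, ntc)
  look <- function(tr, tc) maps[cbind(as.vector(tr), as.vector(tc),
                                      as.vector(img) + 1L)]
  out <- w_r * w_c * look(lo_r, lo_c) +
    (1 - w_r) * w_c * look(hi_r, lo_c) +
    w_r * (1 - w_c) * look(lo_r, hi_c) +
    (1 - w_r) * (1 - w_c) * look(hi_r, hi_c)
  matrix(as.integer(round(out)), nr, nc)
}

#' Threshold enhanced pixels into melanin candidates
#'
#' Strictly greater than `round(melanin_threshold * 255)` — with the default
#' 0.6 the cut sits at gray level 153, so a 153 pixel is excluded and a 154
#' pixel is a candidate.
#'
#' @param enhanced 8-bit enhanced image from [enhance_contrast()].
#' @inheritParams enhance_contrast
#' @return logical candidate mask.
#' @export
threshold_candidates <- function(enhanced, params = segmentation_params()) {
  unclass(enhanced) > params$melanin_threshold_gray
}

#' Extract grain melanin objects
#'
#' A 2 x 2 binary opening removes single-pixel speckle survivors, then
#' connected components (8-connectivity by default) with an equivalent-circle
#' diameter `2*sqrt(area/pi)` strictly greater than the 0.5 um gate are
#' retained as grain melanin.
#'
#' @param binary candidate mask from [threshold_candidates()].
#' @inheritParams enhance_contrast
#' @param scale_um_per_px pixel pitch.
#' @param image optional gray image for per-object intensity statistics.
#' @return list with `grain_mask` (logical) and `grain_objects`
#'   (a [component_table()] data frame).
#' @export
extract_grain <- function(binary, params = segmentation_params(),
                          scale_um_per_px = 0.5, image = NULL) {
  opened <- binary_open(binary, "square2")
  labels <- label_components(opened, params$connectivity)
  tab <- component_table(labels, scale_um_per_px, image)
  keep <- tab$eq_diameter_um > params$grain_min_diameter_um
  mask <- matrix(FALSE, nrow(binary), ncol(binary))
  if (any(keep)) mask[labels %in% tab$id[keep]] <- TRUE
  tab <- tab[keep, , drop = FALSE]
  tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(grain_mask = mask, grain_objects = tab)
}

#' Extract confetti melanin objects
#'
#' A binary closing with the 1-px-radius pixel disk (the 3 x 3
#' 8-neighbourhood) merges grain detections separated by single-pixel gaps
#' into aggregates; closed components whose grain-pixel area strictly exceeds the
#' 8.42 square-micrometre gate become confetti objects. The confetti mask is
#' the retained components intersected with the grain mask, so confetti is
#' always a subset of grain, and object areas count only real grain pixels
#' (never the gap pixels bridged by the closing).
#'
#' @param grain_mask logical mask from [extract_grain()].
#' @inheritParams extract_grain
#' @return list with `confetti_mask` and `confetti_objects`.
#' @export
extract_confetti <- function(grain_mask, params = segmentation_params(),
                             scale_um_per_px = 0.5, image = NULL) {
  closed <- binary_close(grain_mask, params$confetti_close_se)
  labels <- label_components(closed, params$connectivity)
  labels[!grain_mask] <- 0L          # measure grain pixels only
  tab <- component_table(labels, scale_um_per_px, image)
  keep <- tab$area_um2 > params$confetti_min_area_um2
  mask <- matrix(FALSE, nrow(grain_mask), ncol(grain_mask))
  if (any(keep)) mask[labels %in% tab$id[keep]] <- TRUE
  tab <- tab[keep, , drop = FALSE]
  tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(confetti_mask = mask, confetti_objects = tab)
}

#' Tissue mask of an enhanced image
#'
#' Tissue is every enhanced pixel strictly above the tissue gray threshold
#' (default 38); it is the denominator of the grain-density feature.
#'
#' @inheritParams threshold_candidates
#' @return logical tissue mask.
#' @export
tissue_mask <- function(enhanced, params = segmentation_params()) {
  unclass(enhanced) > params$tissue_threshold_gray
}

#' Run the full melanin segmentation chain on one image
#'
#' Contrast enhancement, candidate thresholding, grain extraction
#' (opening + diameter gate) and confetti extraction (closing + area gate),
#' plus the tissue mask. Per-object gray statistics are measured on the
#' input (typically denoised) image.
#'
#' @param image a denoised [oct_image] (or 8-bit matrix).
#' @inheritParams enhance_contrast
#' @param scale_um_per_px pixel pitch; taken from the image when available.
#' @return an object of class `melanin_segmentation` with elements
#'   `enhanced`, `binary_candidates`, `grain_mask`, `grain_objects`,
#'   `confetti_mask`, `confetti_objects`, `tissue_mask`, `params`,
#'   `scale_um_per_px`, `image`.
#' @export
segment_melanin <- function(image, params = segmentation_params(),
                            scale_um_per_px = NULL) {
  if (is.null(scale_um_per_px))
    scale_um_per_px <- attr(image, "scale_um_per_px") %||% 0.5
  enhanced <- enhance_contrast(image, params)
  binary <- threshold_candidates(enhanced, params)
  g <- extract_grain(binary, params, scale_um_per_px, image = unclass(image))
  cf <- extract_confetti(g$grain_mask, params, scale_um_per_px,
                         image = unclass(image))
  structure(list(enhanced = enhanced, binary_candidates = binary,
                 grain_mask = g$grain_mask, grain_objects = g$grain_objects,
                 confetti_mask = cf$confetti_mask,
                 confetti_objects = cf$confetti_objects,
                 tissue_mask = tissue_mask(enhanced, params),
                 params = params, scale_um_per_px = scale_um_per_px,
                 image = unclass(image)),
            class = "melanin_segmentation")
}

#' @export
print.melanin_segmentation <- function(x, ...) {
  cat(sprintf("<melanin_segmentation> %d x %d px at %.3g um/px\n",
              nrow(x$image), ncol(x$image), x$scale_um_per_px))
  cat(sprintf("  %d grain objects (%.1f um2), %d confetti (%.1f um2), tissue %.1f%%\n",
              nrow(x$grain_objects), sum(x$grain_objects$area_um2),
              nrow(x$confetti_objects), sum(x$confetti_objects$area_um2),
              100 * mean(x$tissue_mask)))
  invisible(x)
}

#' Overlay detected melanin on the image
#'
#' Renders the image with grain melanin in red and confetti melanin in
#' yellow (confetti drawn on top, since it is a subset of grain).
#'
#' @param x a `melanin_segmentation`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the RGB raster array.
#' @export
plot.melanin_segmentation <- function(x, ...) {
  g <- x$image / 255
  rgb <- array(rep(g, 3), c(nrow(g), ncol(g), 3))
  r <- rgb[, , 1]; gg <- rgb[, , 2]; b <- rgb[, , 3]
  r[x$grain_mask] <- 1; gg[x$grain_mask] <- 0; b[x$grain_mask] <- 0
  r[x$confetti_mask] <- 1; gg[x$confetti_mask] <- 1; b[x$confetti_mask] <- 0
  rgb[, , 1] <- r; rgb[, , 2] <- gg; rgb[, , 3] <- b
  plot(grDevices::as.raster(rgb), ...)
  invisible(rgb)
}

#' Write segmentation artifacts to disk
#'
#' Masks as 8-bit 0/255 PNG, object tables as CSV with the standard columns.
#'
#' @param seg a `melanin_segmentation`.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @export
save_segmentation <- function(seg, dir, prefix = "image") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  save_mask(seg$grain_mask, file.path(dir, paste0(prefix, "_grain.png")))
  save_mask(seg$confetti_mask,
            file.path(dir, paste0(prefix, "_confetti.png")))
  obj <- rbind(cbind(class = rep("grain", nrow(seg$grain_objects)),
                     seg$grain_objects),
               cbind(class = rep("confetti", nrow(seg$confetti_objects)),
                     seg$confetti_objects))
  utils::write.csv(obj, file.path(dir, paste0(prefix, "_objects.csv")),
                   row.names = FALSE)
  invisible(dir)
}
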