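# The 18 per-image morphometric features, split into area, distribution,
# shape and brightness groups. Undefined features (for example distance
# features with fewer than two confetti objects) propagate as NA, never as
# zero, so cohort statistics are not biased by empty images. All SD-type
# features use the population convention (divide by n).

FEATURE_NAMES <- c(
  "G_area", "G_density",
  "G_intensity_min", "G_intensity_max", "G_intensity_mean", "G_intensity_SD",
  "C_area", "C_distance_mean", "C_distance_SD", "C_roundness",
  "C_size_min", "C_size_max", "C_size_mean", "C_size_SD",
  "C_intensity_min", "C_intensity_max", "C_intensity_mean", "C_intensity_SD")

#' Area and density features
#'
#' `G_area` and `C_area` are the summed grain and confetti areas in square
#' micrometres; `G_density` is the grain pixel count as a percentage of the
#' tissue pixel count. With an empty tissue mask the density is undefined
#' (`NA`).
#'
#' @param seg a [segment_melanin()] result.
#' @return named list with `G_area`, `C_area`, `G_density`.
#' @export
compute_area_features <- function(seg) {
  n_tissue <- sum(seg$tissue_mask)
  list(G_area = sum(seg$grain_objects$area_um2),
       C_area = sum(seg$confetti_objects$area_um2),
       G_density = if (n_tissue == 0L) NA_real_
                   else 100 * sum(seg$grain_mask) / n_tissue)
}

#' Confetti centroid distance features
#'
#' Euclidean distances between all unordered pairs of confetti centroids,
#' in micrometres; returns their mean and population SD. Undefined (`NA`)
#' with fewer than two confetti objects.
#'
#' @inheritParams compute_area_features
#' @param scale_um_per_px pixel pitch.
#' @return named list with `C_distance_mean`, `C_distance_SD`.
#' @export
compute_distance_features <- function(seg,
                                      scale_um_per_px = seg$scale_um_per_px) {
  tab <- seg$confetti_objects
  if (nrow(tab) < 2L)
    return(list(C_distance_mean = NA_real_, C_distance_SD = NA_real_))
  d <- as.numeric(stats::dist(cbind(tab$centroid_x_px, tab$centroid_y_px)))
  d <- d * scale_um_per_px
  list(C_distance_mean = mean(d), C_distance_SD = sd_pop(d))
}

#' Confetti shape features
#'
#' Per-object roundness is `4*pi*area_px / perimeter_px^2` with the
#' perimeter counted as object pixels 8-adjacent to background; this
#' pixel-count convention does not bound roundness by 1 for thin objects.
#' `C_roundness` is the mean over confetti objects; the size features
#' summarize per-object areas in square micrometres.
#'
#' @inheritParams compute_area_features
#' @return named list with `C_roundness`, `C_size_min/max/mean/SD`.
#' @export
compute_shape_features <- function(seg) {
  tab <- seg$confetti_objects
  if (nrow(tab) == 0L)
    return(list(C_roundness = NA_real_, C_size_min = NA_real_,
                C_size_max = NA_real_, C_size_mean = NA_real_,
                C_size_SD = NA_real_))
  roundness <- 4 * pi * tab$n_px / tab$perimeter_px^2
  list(C_roundness = mean(roundness),
       C_size_min = min(tab$area_um2), C_size_max = max(tab$area_um2),
       C_size_mean = mean(tab$area_um2), C_size_SD = sd_pop(tab$area_um2))
}

#' Grain and confetti brightness features
#'
#' Gray-level statistics of the pixels under the grain and confetti masks,
#' measured on the selected source image: the denoised image by default
#' (enhancement is a detection aid, not a measurement surface), or the
#' enhanced image for sensitivity analysis. Note that confetti intensity on
#' the denoised image is not guaranteed to exceed the 153 candidate
#' threshold, which was applied to the enhanced image.
#'
#' @inheritParams compute_area_features
#' @param image gray image co-registered with the masks (defaults to the
#'   image the segmentation was run on).
#' @param source `"denoised"` or `"enhanced"`.
#' @return named list with the eight `G_`/`C_intensity_*` features.
#' @export
compute_intensity_features <- function(seg, image = seg$image,
                                       source = c("denoised", "enhanced")) {
  source <- match.arg(source)
  src <- if (source == "enhanced") seg$enhanced else unclass(image)
  if (!all(dim(src) == dim(seg$grain_mask)))
    stop("image is not co-registered with the masks", call. = FALSE)
  stats_of <- function(mask) {
    v <- as.numeric(src[mask])
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    c(min(v), max(v), mean(v), sd_pop(v))
  }
  g <- stats_of(seg$grain_mask); cf <- stats_of(seg$confetti_mask)
  list(G_intensity_min = g[1], G_intensity_max = g[2],
       G_intensity_mean = g[3], G_intensity_SD = g[4],
       C_intensity_min = cf[1], C_intensity_max = cf[2],
       C_intensity_mean = cf[3], C_intensity_SD = cf[4])
}

#' Compute all 18 features of one segmented image
#'
#' @inheritParams compute_intensity_features
#' @return one-row `data.frame` of class `melanin_features` with the 18
#'   feature columns plus `n_grain` and `n_confetti`.
#' @export
melanin_features <- function(seg, image = seg$image,
                             source = c("denoised", "enhanced")) {
  stopifnot(inherits(seg, "melanin_segmentation"))
  vals <- c(compute_area_features(seg),
            compute_distance_features(seg),
            compute_shape_features(seg),
            compute_intensity_features(seg, image, source))
  out <- as.data.frame(vals)[, FEATURE_NAMES[FEATURE_NAMES %in% names(vals)]]
  out <- out[, FEATURE_NAMES]
  out$n_grain <- nrow(seg$grain_objects)
  out$n_confetti <- nrow(seg$confetti_objects)
  class(out) <- c("melanin_features", "data.frame")
  out
}

#' Featurize every image of a manifest
#'
#' Loads (or takes from memory) each manifest image, denoises it, runs the
#' segmentation chain and computes the 18 features, carrying the condition
#' and layer labels through. A failing image is recorded and skipped; the
#' run continues.
#'
#' @param manifest manifest `data.frame` (see [simulate_cohort()] /
#'   [read_manifest()]).
#' @param params a [segmentation_params()].
#' @param denoiser `"fallback"` (median filter), `"none"`, or a fitted
#'   [dncnn] model.
#' @param source intensity source, `"denoised"` or `"enhanced"`.
#' @return `data.frame` with `image_id`, `condition`, `layer`, the 18
#'   features, `n_grain`, `n_confetti`; attribute `"failures"` lists
#'   per-image errors.
#' @export
featurize_manifest <- function(manifest, params = segmentation_params(),
                               denoiser = "fallback",
                               source = c("denoised", "enhanced")) {
  source <- match.arg(source)
  images <- attr(manifest, "images")
  rows <- list(); failures <- list()
  for (k in seq_len(nrow(manifest))) {
    id <- manifest$image_id[k]
    res <- tryCatch({
      img <- if (!is.null(images)) images[[id]]
             else load_oct_image(manifest$path[k],
                                 manifest$scale_um_per_px[k])
      dn <- if (inherits(denoiser, "dncnn")) denoise(denoiser, img)
            else if (identical(denoiser, "none")) img
            else denoise_fallback(img)
      attr(dn, "scale_um_per_px") <- manifest$scale_um_per_px[k]
      seg <- segment_melanin(dn, params,
                             scale_um_per_px = manifest$scale_um_per_px[k])
      fv <- melanin_features(seg, source = source)
      cbind(data.frame(image_id = id, condition = manifest$condition[k],
                       layer = manifest$layer[k], stringsAsFactors = FALSE),
            as.data.frame(fv))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
      warning(sprintf("image '%s' failed: %s", id, conditionMessage(res)),
              call. = FALSE)
    } else rows[[id]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}
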