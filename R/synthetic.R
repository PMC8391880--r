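#' Multiplicative speckle model
#'
#' Speckle in coherent imaging multiplies the tissue reflectivity rather than
#' adding to it. The simulator draws pixelwise i.i.d. Gamma noise with unit
#' mean and shape `looks` (the effective number of incoherent averages), the
#' standard surrogate for incoherent speckle: variance of the noise factor is
#' `1/looks`, and `looks = Inf` is the noiseless limit.
#'
#' @param looks effective number of looks, >= 1 (may be `Inf`).
#' @param seed integer seed controlling every random draw of a simulation.
#' @return a `speckle_model` object.
#' @export
speckle_model <- function(looks = 4, seed = 1L) {
  if (!is.numeric(looks) || length(looks) != 1L || is.na(looks) || looks < 1)
    stop("`looks` must be a single number >= 1", call. = FALSE)
  structure(list(looks = looks, distribution = "gamma_multiplicative",
                 seed = as.integer(seed)),
            class = "speckle_model")
}

# unit-mean Gamma(looks) multiplicative field
speckle_field <- function(n, looks) {
  if (is.infinite(looks)) return(rep(1, n))
  stats::rgamma(n, shape = looks, rate = looks)
}

#' Synthetic melanin scene description
#'
#' Describes an FF-OCT-like field of view: a smooth tissue reflectivity
#' background, bright sub-resolution "grain" melanin disks, and clustered
#' multi-disk aggregates ("confetti") whose true area always exceeds the
#' 8.42 square-micrometre confetti gate by construction. `lesion_like`
#' scenes place confetti aggregates with a Thomas (parent-offspring) cluster
#' process; `perilesional_like` scenes place the same expected number of
#' aggregates homogeneously (matched intensity
#' `confetti_parent_rate * confetti_offspring_mean`).
#'
#' @param condition `"perilesional_like"` (homogeneous placement) or
#'   `"lesion_like"` (clustered placement).
#' @param fov_px image height and width in pixels.
#' @param scale_um_per_px pixel pitch in micrometres (> 0).
#' @param grain_rate isolated grain objects per square millimetre.
#' @param confetti_parent_rate cluster parents per square millimetre.
#' @param confetti_offspring_mean expected aggregates per parent.
#' @param confetti_sigma_um Gaussian scatter (micrometres) of aggregates
#'   about their parent.
#' @param grain_diameter_um 2-vector, uniform range of grain diameters; must
#'   lie within \[0.5, 3\] so that no isolated grain can reach the confetti
#'   area gate.
#' @param melanin_gray 2-vector within \[154, 255\]: painted melanin gray.
#' @param tissue_gray_mean mean tissue gray in \[39, 150\].
#' @param border_px width of a dark (non-tissue) frame around the field.
#' @return a `melanin_scene` object.
#' @export
melanin_scene <- function(condition = c("perilesional_like", "lesion_like"),
                          fov_px = c(256L, 256L),
                          scale_um_per_px = 0.5,
                          grain_rate = 1500,
                          confetti_parent_rate = 250,
                          confetti_offspring_mean = 4.8,
                          confetti_sigma_um = 10,
                          grain_diameter_um = c(2, 3),
                          melanin_gray = c(200L, 255L),
                          tissue_gray_mean = 90L,
                          border_px = 0L) {
  condition <- match.arg(condition)
  if (scale_um_per_px <= 0)
    stop("`scale_um_per_px` must be positive", call. = FALSE)
  if (any(fov_px < 8)) stop("`fov_px` must be at least 8 x 8", call. = FALSE)
  if (grain_rate < 0 || confetti_parent_rate < 0 || confetti_offspring_mean < 0)
    stop("rates must be non-negative", call. = FALSE)
  if (grain_diameter_um[1] < 0.5 || grain_diameter_um[2] > 3)
    stop("`grain_diameter_um` must lie within [0.5, 3]", call. = FALSE)
  if (melanin_gray[1] < 154 || melanin_gray[2] > 255)
    stop("`melanin_gray` must lie within [154, 255]", call. = FALSE)
  if (tissue_gray_mean < 39 || tissue_gray_mean > 150)
    stop("`tissue_gray_mean` must lie in [39, 150]", call. = FALSE)
  structure(list(condition = condition,
                 fov_px = as.integer(fov_px),
                 scale_um_per_px = scale_um_per_px,
                 grain_rate = grain_rate,
                 confetti_parent_rate = confetti_parent_rate,
                 confetti_offspring_mean = confetti_offspring_mean,
                 confetti_sigma_um = confetti_sigma_um,
                 grain_diameter_um = grain_diameter_um,
                 melanin_gray = as.integer(melanin_gray),
                 tissue_gray_mean = as.integer(tissue_gray_mean),
                 border_px = as.integer(border_px)),
            class = "melanin_scene")
}

# confetti aggregate geometry: a core disk plus two satellites, connected by
# construction; the core alone rasterizes above the 8.42 um^2 gate
CONFETTI_CORE_D_UM <- 3.6
CONFETTI_SAT_D_UM <- 2.4
CONFETTI_SAT_OFF_UM <- 1.5

#' Sample the melanin objects of a scene (ground-truth point process)
#'
#' Draws the object placements only — no rasterization, no speckle — which
#' is all the spatial statistics of a scene need. Consumes the current RNG
#' stream.
#'
#' @param scene a [melanin_scene()].
#' @return `data.frame` with columns `class` ("grain"/"confetti"), `x_um`,
#'   `y_um` (object centre) and `diameter_um` (grains only, `NA` for
#'   confetti aggregates).
#' @export
sample_melanin_objects <- function(scene) {
  h_um <- scene$fov_px[1] * scene$scale_um_per_px
  w_um <- scene$fov_px[2] * scene$scale_um_per_px
  area_mm2 <- h_um * w_um / 1e6
  n_grain <- stats::rpois(1, scene$grain_rate * area_mm2)
  gx <- stats::runif(n_grain, 0, w_um)
  gy <- stats::runif(n_grain, 0, h_um)
  gd <- stats::runif(n_grain, scene$grain_diameter_um[1],
                     scene$grain_diameter_um[2])
  if (scene$condition == "lesion_like") {
    n_par <- stats::rpois(1, scene$confetti_parent_rate * area_mm2)
    px <- stats::runif(n_par, 0, w_um)
    py <- stats::runif(n_par, 0, h_um)
    noff <- stats::rpois(n_par, scene$confetti_offspring_mean)
    cx <- rep(px, noff) + stats::rnorm(sum(noff), 0, scene$confetti_sigma_um)
    cy <- rep(py, noff) + stats::rnorm(sum(noff), 0, scene$confetti_sigma_um)
    keep <- cx >= 0 & cx <= w_um & cy >= 0 & cy <= h_um
    cx <- cx[keep]; cy <- cy[keep]
  } else {
    n_conf <- stats::rpois(1, scene$confetti_parent_rate *
                                scene$confetti_offspring_mean * area_mm2)
    cx <- stats::runif(n_conf, 0, w_um)
    cy <- stats::runif(n_conf, 0, h_um)
  }
  data.frame(
    class = rep(c("grain", "confetti"), c(n_grain, length(cx))),
    x_um = c(gx, cx), y_um = c(gy, cy),
    diameter_um = c(gd, rep(NA_real_, length(cx))))
}

# linear pixel indices of a disk (centre/radius in um) under center-in-disk
# inclusion; pixel (i,j) centre at ((i-0.5)s, (j-0.5)s)
disk_pixels <- function(cx, cy, r_um, nr, nc, s) {
  i0 <- max(1L, floor((cy - r_um) / s))
  i1 <- min(nr, ceiling((cy + r_um) / s) + 1L)
  j0 <- max(1L, floor((cx - r_um) / s))
  j1 <- min(nc, ceiling((cx + r_um) / s) + 1L)
  if (i0 > i1 || j0 > j1) return(integer(0))
  ii <- i0:i1; jj <- j0:j1
  inside <- outer(((ii - 0.5) * s - cy)^2, ((jj - 0.5) * s - cx)^2,
                  `+`) <= r_um^2
  (rep(jj, each = length(ii))[inside] - 1L) * nr +
    rep(ii, length(jj))[inside]
}

# rasterize sampled objects onto a tissue structure field; returns the
# structure (double matrix, melanin painted) and the melanin mask
rasterize_objects <- function(objects, structure_field, scene) {
  s <- scene$scale_um_per_px
  nr <- nrow(structure_field); nc <- ncol(structure_field)
  mask <- matrix(FALSE, nr, nc)
  img <- structure_field
  if (nrow(objects)) {
    grays <- sample(scene$melanin_gray[1]:scene$melanin_gray[2],
                    nrow(objects), replace = TRUE)
    for (k in seq_len(nrow(objects))) {
      x <- objects$x_um[k]; y <- objects$y_um[k]
      if (objects$class[k] == "grain") {
        idx <- disk_pixels(x, y, objects$diameter_um[k] / 2, nr, nc, s)
      } else {
        idx <- disk_pixels(x, y, CONFETTI_CORE_D_UM / 2, nr, nc, s)
        ang <- stats::runif(2, 0, 2 * pi)
        for (a in ang)
          idx <- c(idx, disk_pixels(x + CONFETTI_SAT_OFF_UM * cos(a),
                                    y + CONFETTI_SAT_OFF_UM * sin(a),
                                    CONFETTI_SAT_D_UM / 2, nr, nc, s))
        idx <- unique(idx)
      }
      img[idx] <- pmax(img[idx], grays[k])
      mask[idx] <- TRUE
    }
  }
  list(structure = img, mask = mask)
}

# smooth unit-mean tissue reflectivity field scaled to the tissue gray
tissue_field <- function(scene) {
  nr <- scene$fov_px[1]; nc <- scene$fov_px[2]
  w <- matrix(stats::rnorm(nr * nc), nr, nc)
  sm <- gauss_blur(w, sigma = 8)
  sm <- (sm - mean(sm)) / stats::sd(sm)
  f <- scene$tissue_gray_mean * pmin(pmax(1 + 0.10 * sm, 0.6), 1.4)
  b <- scene$border_px
  if (b > 0) {
    f[c(seq_len(b), nr - seq_len(b) + 1L), ] <- 5
    f[, c(seq_len(b), nc - seq_len(b) + 1L)] <- 5
  }
  f
}

# build structure field + ground truth for a scene (consumes RNG)
build_scene <- function(scene) {
  tf <- tissue_field(scene)
  objects <- sample_melanin_objects(scene)
  ras <- rasterize_objects(objects, tf, scene)
  truth <- ground_truth(ras$mask, scene$scale_um_per_px)
  list(structure = ras$structure, truth = truth, objects = objects)
}

# ground truth from the painted melanin raster: components under
# 8-connectivity; area > 8.42 um^2 => confetti (a subset of grain)
ground_truth <- function(melanin_mask, scale_um_per_px,
                         confetti_min_area_um2 = 8.42) {
  labels <- label_components(melanin_mask, connectivity = 8)
  tab <- component_table(labels, scale_um_per_px)
  cls <- ifelse(tab$area_um2 > confetti_min_area_um2, "confetti", "grain")
  confetti_mask <- matrix(FALSE, nrow(melanin_mask), ncol(melanin_mask))
  if (any(cls == "confetti"))
    confetti_mask[labels %in% tab$id[cls == "confetti"]] <- TRUE
  structure(list(grain_mask = melanin_mask,
                 confetti_mask = confetti_mask,
                 object_table = cbind(tab, class = cls)),
            class = "melanin_truth")
}

#' Simulate one en-face (E-scan) OCT image with known ground truth
#'
#' Builds a smooth tissue reflectivity field, paints grain and confetti
#' melanin disks at high gray levels, multiplies pixelwise unit-mean Gamma
#' speckle onto the structure and quantizes to 8 bits. Bit-identical under a
#' fixed `noise$seed`.
#'
#' @param scene a [melanin_scene()].
#' @param noise a [speckle_model()].
#' @return a list of class `oct_simulation` with elements `image`
#'   ([oct_image]), `structure` (noise-free double matrix) and `truth`
#'   (ground-truth masks and object table).
#' @export
simulate_escan <- function(scene, noise = speckle_model()) {
  stopifnot(inherits(scene, "melanin_scene"), inherits(noise, "speckle_model"))
  with_seed(noise$seed, {
    sc <- build_scene(scene)
    n <- length(sc$structure)
    img <- sc$structure * matrix(speckle_field(n, noise$looks),
                                 nrow(sc$structure))
    condition <- if (scene$condition == "lesion_like") "lesion"
                 else "perilesional"
    structure(list(
      image = as_oct_image(img, scene$scale_um_per_px, condition = condition),
      structure = sc$structure,
      truth = sc$truth),
      class = "oct_simulation")
  })
}

#' Simulate a stack of adjacent B-scan slices
#'
#' All slices share one structure field (adjacent FF-OCT slices are acquired
#' co-registered); each slice receives an independent speckle draw, which is
#' what makes spatial compounding informative.
#'
#' @inheritParams simulate_escan
#' @param n_slices number of adjacent slices (>= 2; the device default is 11).
#' @return a list of class `bscan_stack`: `slices` (list of [oct_image]),
#'   `structure`, `truth`, `scale_um_per_px`.
#' @export
simulate_bscan_stack <- function(scene, noise = speckle_model(),
                                 n_slices = 11L) {
  stopifnot(inherits(scene, "melanin_scene"), inherits(noise, "speckle_model"))
  if (!is.numeric(n_slices) || n_slices < 2)
    stop("`n_slices` must be at least 2", call. = FALSE)
  n_slices <- as.integer(n_slices)
  with_seed(noise$seed, {
    sc <- build_scene(scene)
    n <- length(sc$structure)
    slices <- lapply(seq_len(n_slices), function(i)
      as_oct_image(sc$structure * matrix(speckle_field(n, noise$looks),
                                         nrow(sc$structure)),
                   scene$scale_um_per_px))
    structure(list(slices = slices, structure = sc$structure,
                   truth = sc$truth,
                   scale_um_per_px = scene$scale_um_per_px),
              class = "bscan_stack")
  })
}

#' @export
print.bscan_stack <- function(x, ...) {
  cat(sprintf("<bscan_stack> %d slices of %d x %d px, %.3g um/px\n",
              length(x$slices), nrow(x$slices[[1]]), ncol(x$slices[[1]]),
              x$scale_um_per_px))
  invisible(x)
}

#' Simulate a labeled lesion/perilesional cohort
#'
#' Generates `n_per_group` lesion-like (clustered confetti) and
#' `n_per_group` perilesional-like (homogeneous confetti) E-scan images,
#' writes them as 8-bit PNG and returns the manifest. Regenerating with the
#' same seed reproduces manifests and images exactly.
#'
#' @param n_per_group images per condition (>= 2).
#' @param layer skin-layer label for the whole cohort.
#' @param seed integer master seed; per-image seeds are drawn from it.
#' @param dir output directory (created if missing). `NULL` keeps the images
#'   in memory only (attribute `"images"` on the manifest).
#' @param lesion_scene,perilesional_scene scene presets; defaults are the
#'   package's study conditions.
#' @param looks speckle looks applied to every image.
#' @return `data.frame` manifest with columns `image_id`, `path`,
#'   `condition`, `layer`, `seed`, `scale_um_per_px`; attributes `"truth"`
#'   (per-image ground-truth object tables) and, when `dir` is `NULL`,
#'   `"images"`.
#' @export
simulate_cohort <- function(n_per_group, layer = "stratum_spinosum",
                            seed = 1L, dir = NULL,
                            lesion_scene = melanin_scene("lesion_like"),
                            perilesional_scene = melanin_scene("perilesional_like"),
                            looks = 4) {
  if (n_per_group < 2) stop("`n_per_group` must be >= 2", call. = FALSE)
  layer <- match.arg(layer, c("stratum_spinosum", "DEJ", "papillary_dermis"))
  if (!is.null(dir) && !dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  conditions <- rep(c("lesion", "perilesional"), each = n_per_group)
  img_seeds <- with_seed(as.integer(seed),
                         sample.int(.Machine$integer.max - 1L,
                                    2L * n_per_group))
  images <- vector("list", 2L * n_per_group)
  truths <- vector("list", 2L * n_per_group)
  rows <- vector("list", 2L * n_per_group)
  for (k in seq_along(conditions)) {
    scene <- if (conditions[k] == "lesion") lesion_scene else perilesional_scene
    sim <- simulate_escan(scene, speckle_model(looks = looks,
                                               seed = img_seeds[k]))
    id <- sprintf("%s_%03d", conditions[k],
                  ((k - 1L) %% n_per_group) + 1L)
    path <- NA_character_
    if (!is.null(dir)) {
      path <- file.path(dir, paste0(id, ".png"))
      save_oct_image(sim$image, path)
    } else {
      images[[k]] <- sim$image
    }
    truths[[k]] <- sim$truth$object_table
    rows[[k]] <- data.frame(image_id = id, path = path,
                            condition = conditions[k], layer = layer,
                            seed = img_seeds[k],
                            scale_um_per_px = scene$scale_um_per_px,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  names(truths) <- manifest$image_id
  attr(manifest, "truth") <- truths
  if (is.null(dir)) {
    names(images) <- manifest$image_id
    attr(manifest, "images") <- images
  }
  manifest
}

#' Match detected objects to ground-truth objects by centroid distance
#'
#' A detected object is a true positive when a ground-truth centroid of the
#' same class lies within `tol_um`; a truth object is recalled when at least
#' one detection lies within `tol_um`. Object splits caused by speckle
#' therefore do not count against precision as long as the fragments stay on
#' the true object.
#'
#' @param detected,truth object tables with `centroid_x_px`, `centroid_y_px`.
#' @param scale_um_per_px pixel pitch.
#' @param tol_um matching tolerance in micrometres.
#' @return list with `n_detected`, `n_truth`, `recall`, `precision`.
#' @export
match_objects <- function(detected, truth, scale_um_per_px, tol_um = 2) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L || nt == 0L)
    return(list(n_detected = nd, n_truth = nt,
                recall = if (nt == 0L) NA_real_ else 0,
                precision = if (nd == 0L) NA_real_ else 0))
  dx <- outer(detected$centroid_x_px, truth$centroid_x_px, `-`)
  dy <- outer(detected$centroid_y_px, truth$centroid_y_px, `-`)
  d_um <- sqrt(dx^2 + dy^2) * scale_um_per_px
  hit <- d_um <= tol_um
  list(n_detected = nd, n_truth = nt,
       recall = mean(apply(hit, 2, any)),
       precision = mean(apply(hit, 1, any)))
}
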