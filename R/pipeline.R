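#' Read and write cohort manifests
#'
#' A manifest is a CSV with one row per image: `image_id`, `path`,
#' `condition` (lesion/perilesional), `layer` (stratum_spinosum, DEJ,
#' papillary_dermis), `scale_um_per_px` and optionally `seed` and
#' `patient_id`. Ids must be unique, scales positive, and paths resolvable
#' (relative paths are resolved against the manifest's directory).
#'
#' @param path CSV path.
#' @param check_paths verify that every image file exists.
#' @return manifest `data.frame`.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "path", "condition", "layer", "scale_um_per_px")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(m$image_id))
    stop("duplicate image_id in manifest", call. = FALSE)
  if (any(m$scale_um_per_px <= 0))
    stop("manifest scales must be positive", call. = FALSE)
  bad <- setdiff(m$condition, c("lesion", "perilesional"))
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  rel <- !file.exists(m$path) & file.exists(file.path(dirname(path), m$path))
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  if (check_paths && !all(file.exists(m$path)))
    stop("missing image file(s): ",
         paste(m$path[!file.exists(m$path)], collapse = ", "), call. = FALSE)
  m
}

#' @rdname read_manifest
#' @param manifest manifest `data.frame`.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Bundles everything a full run needs: segmentation parameters, the
#' denoiser choice, the intensity source for brightness features, the
#' statistics options and the seed. Serializes losslessly to JSON
#' (`load_run_config(save_run_config(c)) == c`).
#'
#' @param params a [segmentation_params()].
#' @param denoiser `"fallback"`, `"none"` or `"dncnn"`.
#' @param checkpoint checkpoint path, required when `denoiser = "dncnn"`.
#' @param intensity_source `"denoised"` or `"enhanced"`.
#' @param welch,lilliefors,adjust statistics options, see
#'   [stratified_report()].
#' @param seed integer seed recorded with every artifact.
#' @return a `run_config` object.
#' @export
run_config <- function(params = segmentation_params(),
                       denoiser = c("fallback", "none", "dncnn"),
                       checkpoint = NULL,
                       intensity_source = c("denoised", "enhanced"),
                       welch = FALSE, lilliefors = FALSE,
                       adjust = "none", seed = 1L) {
  denoiser <- match.arg(denoiser)
  intensity_source <- match.arg(intensity_source)
  structure(list(params = params, denoiser = denoiser,
                 checkpoint = checkpoint,
                 intensity_source = intensity_source,
                 welch = isTRUE(welch), lilliefors = isTRUE(lilliefors),
                 adjust = adjust, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON path.
#' @export
save_run_config <- function(config, path) {
  payload <- unclass(config)
  payload$params <- unclass(payload$params)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname run_config
#' @export
load_run_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- p$params
  params <- segmentation_params(
    clahe_tiles = sp$clahe_tiles, clahe_tile_um = sp$clahe_tile_um,
    clahe_lambda = sp$clahe_lambda,
    clahe_clip = sp$clahe_clip, clahe_bins = sp$clahe_bins,
    melanin_threshold = sp$melanin_threshold,
    tissue_threshold_gray = sp$tissue_threshold_gray,
    grain_min_diameter_um = sp$grain_min_diameter_um,
    confetti_min_area_um2 = sp$confetti_min_area_um2,
    confetti_close_se = sp$confetti_close_se,
    connectivity = sp$connectivity)
  run_config(params = params, denoiser = p$denoiser,
             checkpoint = p$checkpoint,
             intensity_source = p$intensity_source,
             welch = p$welch, lilliefors = p$lilliefors,
             adjust = p$adjust, seed = p$seed)
}

# stable hash of a run configuration (md5 of its canonical JSON)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full detection pipeline over a manifest
#'
#' Denoise, segment, featurize and compare, writing every artifact into
#' `out_dir`: denoised images, grain/confetti masks, per-image object
#' tables, `features.csv`, `report.csv` and a run log. Every CSV artifact
#' is stamped with the configuration hash and seed. Per-image failures are
#' logged and isolated; the run continues.
#'
#' @param manifest manifest `data.frame` (or path to a manifest CSV).
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param features_before optional feature table for the before/after
#'   denoising contrast in the report.
#' @return invisibly, a list with `features`, `report`, `out_dir`,
#'   `config_hash`.
#' @export
run_pipeline <- function(manifest, config = run_config(),
                         out_dir = tempfile("cade_run_"),
                         features_before = NULL) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (config$denoiser == "dncnn" &&
      (is.null(config$checkpoint) || !file.exists(config$checkpoint)))
    stop("denoiser = 'dncnn' needs an existing `checkpoint`", call. = FALSE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- config_hash(config)
  logf <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = logf, append = TRUE)
  cat(sprintf("run %s seed %d, %d images\n", hash, config$seed,
              nrow(manifest)), file = logf)
  model <- if (config$denoiser == "dncnn") load_dncnn(config$checkpoint)
  images <- attr(manifest, "images")
  for (k in seq_len(nrow(manifest))) {
    id <- manifest$image_id[k]
    t0 <- proc.time()[3]
    ok <- tryCatch({
      img <- if (!is.null(images)) images[[id]]
             else load_oct_image(manifest$path[k],
                                 manifest$scale_um_per_px[k])
      dn <- switch(config$denoiser,
                   none = img,
                   fallback = denoise_fallback(img),
                   dncnn = denoise(model, img))
      save_oct_image(dn, file.path(out_dir, paste0(id, "_denoised.png")))
      seg <- segment_melanin(dn, config$params,
                             manifest$scale_um_per_px[k])
      save_segmentation(seg, out_dir, prefix = id)
      TRUE
    }, error = function(e) {
      log_line("ERROR %s: %s", id, conditionMessage(e)); FALSE
    })
    if (ok) log_line("image %s done in %.2fs", id, proc.time()[3] - t0)
  }
  denoiser_arg <- switch(config$denoiser, none = "none",
                         fallback = "fallback", dncnn = model)
  features <- featurize_manifest(manifest, config$params,
                                 denoiser = denoiser_arg,
                                 source = config$intensity_source)
  report <- stratified_report(features, features_before = features_before,
                              adjust = config$adjust, welch = config$welch,
                              lilliefors = config$lilliefors)
  stamp <- sprintf("# config_hash=%s seed=%d", hash, config$seed)
  fpath <- file.path(out_dir, "features.csv")
  writeLines(stamp, fpath)
  suppressWarnings(utils::write.table(features, fpath, sep = ",",
                                      row.names = FALSE, append = TRUE,
                                      qmethod = "double"))
  rpath <- file.path(out_dir, "report.csv")
  writeLines(stamp, rpath)
  suppressWarnings(utils::write.table(report, rpath, sep = ",",
                                      row.names = FALSE, append = TRUE,
                                      qmethod = "double"))
  save_run_config(config, file.path(out_dir, "config.json"))
  log_line("wrote features.csv and report.csv")
  invisible(list(features = features, report = report, out_dir = out_dir,
                 config_hash = hash))
}
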