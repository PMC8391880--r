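# build a minimal melanin_segmentation object from explicit masks so the
# feature layer can be exercised against hand-computed values
mock_seg <- function(grain_mask, confetti_mask, tissue, image, scale = 0.5,
                     enhanced = image) {
  structure(list(
    enhanced = enhanced, binary_candidates = grain_mask,
    grain_mask = grain_mask,
    grain_objects = component_table(label_components(grain_mask), scale,
                                    image),
    confetti_mask = confetti_mask,
    confetti_objects = component_table(label_components(confetti_mask),
                                       scale, image),
    tissue_mask = tissue, params = segmentation_params(),
    scale_um_per_px = scale, image = image),
    class = "melanin_segmentation")
}

blank <- function(n = 40) matrix(FALSE, n, n)

test_that("area features reduce to pixel ratios", {
  g <- blank(); g[1:10, 1:10] <- TRUE          # 100 grain px
  tissue <- blank(); tissue[1:25, 1:40] <- TRUE  # 1000 tissue px
  img <- matrix(200L, 40, 40)
  seg <- mock_seg(g, blank(), tissue, img, scale = 0.5)
  a <- compute_area_features(seg)
  expect_equal(a$G_density, 10)
  expect_equal(a$G_area, 100 * 0.25)
  expect_equal(a$C_area, 0)
  # empty scene: zero areas and density, not NA (tissue present)
  seg0 <- mock_seg(blank(), blank(), tissue, img)
  expect_equal(compute_area_features(seg0)$G_area, 0)
  # empty tissue: density undefined
  segNA <- mock_seg(g, blank(), blank(), img)
  expect_true(is.na(compute_area_features(segNA)$G_density))
})

test_that("distance features enumerate centroid pairs in micrometres", {
  m <- blank(120)
  m[10, 10] <- TRUE; m[10, 110] <- TRUE        # 100 px apart
  seg <- mock_seg(m, m, m | TRUE, matrix(200L, 120, 120), scale = 0.5)
  d <- compute_distance_features(seg)
  expect_equal(d$C_distance_mean, 50)
  expect_equal(d$C_distance_SD, 0)
  # three collinear centroids at 0, 30, 60 um: pairs {30, 30, 60}
  m2 <- blank(140)
  m2[10, c(10, 70, 130)] <- TRUE               # 60 px = 30 um spacing
  seg2 <- mock_seg(m2, m2, m2 | TRUE, matrix(200L, 140, 140), scale = 0.5)
  d2 <- compute_distance_features(seg2)
  expect_equal(d2$C_distance_mean, 40)
  expect_equal(d2$C_distance_SD, sqrt(mean((c(30, 30, 60) - 40)^2)))
  expect_equal(round(d2$C_distance_SD, 3), 14.142)
  # single confetti object: undefined
  m3 <- blank(); m3[5, 5] <- TRUE
  seg3 <- mock_seg(m3, m3, m3 | TRUE, matrix(200L, 40, 40))
  expect_true(is.na(compute_distance_features(seg3)$C_distance_mean))
})

test_that("roundness follows the contour-pixel convention", {
  line <- blank(); line[10, 11:15] <- TRUE     # 1x5 line: all 5 px contour
  seg <- mock_seg(line, line, line | TRUE, matrix(200L, 40, 40))
  s <- compute_shape_features(seg)
  expect_equal(s$C_roundness, 4 * pi * 5 / 25)
  expect_gt(s$C_roundness, 1)   # pixel-count perimeter does not bound by 1
  sq <- blank(); sq[20:22, 20:22] <- TRUE      # 3x3 square: 8 contour px
  seg2 <- mock_seg(sq, sq, sq | TRUE, matrix(200L, 40, 40))
  expect_equal(compute_shape_features(seg2)$C_roundness, 4 * pi * 9 / 64)
  expect_equal(round(4 * pi * 9 / 64, 3), 1.767)
})

test_that("disk roundness decreases monotonically with elongation", {
  vals <- vapply(c(1, 1.5, 2, 3, 4), function(ar) {
    m <- blank(80)
    for (i in 1:80) for (j in 1:80)
      if (((i - 40) / (10 / sqrt(ar)))^2 + ((j - 40) / (10 * sqrt(ar)))^2 <= 1)
        m[i, j] <- TRUE
    seg <- mock_seg(m, m, m | TRUE, matrix(200L, 80, 80))
    compute_shape_features(seg)$C_roundness
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("intensity features are plain mask statistics, population SD", {
  img <- matrix(200L, 40, 40)
  m <- blank(); m[3:4, 3:4] <- TRUE
  seg <- mock_seg(m, m, m | TRUE, img)
  f <- compute_intensity_features(seg)
  expect_equal(f$G_intensity_min, 200)
  expect_equal(f$G_intensity_max, 200)
  expect_equal(f$G_intensity_SD, 0)
  img2 <- img; img2[3, 3] <- 150L; img2[3, 4] <- 250L
  m2 <- blank(); m2[3, 3:4] <- TRUE
  seg2 <- mock_seg(m2, m2, m2 | TRUE, img2)
  f2 <- compute_intensity_features(seg2)
  expect_equal(f2$G_intensity_mean, 200)
  expect_equal(f2$G_intensity_SD, 50)
  # empty masks are flagged undefined
  seg3 <- mock_seg(blank(), blank(), m2, img2)
  expect_true(is.na(compute_intensity_features(seg3)$C_intensity_mean))
  # the enhanced source is selectable
  seg4 <- mock_seg(m2, m2, m2 | TRUE, img2,
                   enhanced = matrix(10L, 40, 40))
  expect_equal(compute_intensity_features(seg4,
                                          source = "enhanced")$G_intensity_mean,
               10)
})

test_that("denoised-source confetti intensity can sit below the 153 cut", {
  # enhancement lifts a sub-153 pixel above threshold while the denoised
  # value stays below: the documented non-invariant
  img <- matrix(60L, 30, 30)
  img[10:12, 10:12] <- 140L
  seg <- segment_melanin(oct_image(img, 0.5),
                         segmentation_params(clahe_tiles = c(1, 1),
                                             clahe_clip = 0.9))
  expect_gte(nrow(seg$grain_objects), 1L)
  f <- compute_intensity_features(seg, source = "denoised")
  expect_lt(f$G_intensity_mean, 153)
})

test_that("all 18 feature names are present with exact spelling", {
  sim <- simulate_escan(tiny_scene("lesion_like"), speckle_model(4, 2))
  seg <- segment_melanin(denoise_fallback(sim$image))
  fv <- melanin_features(seg)
  expect_identical(names(fv)[1:18], c(
    "G_area", "G_density",
    "G_intensity_min", "G_intensity_max", "G_intensity_mean",
    "G_intensity_SD",
    "C_area", "C_distance_mean", "C_distance_SD", "C_roundness",
    "C_size_min", "C_size_max", "C_size_mean", "C_size_SD",
    "C_intensity_min", "C_intensity_max", "C_intensity_mean",
    "C_intensity_SD"))
  expect_true(all(c("n_grain", "n_confetti") %in% names(fv)))
  expect_true(fv$C_size_min <= fv$C_size_mean &&
                fv$C_size_mean <= fv$C_size_max)
  expect_lte(fv$C_area, fv$G_area)
  expect_true(fv$G_density >= 0 && fv$G_density <= 100)
})

test_that("features are scale-equivariant", {
  set.seed(40)
  checked <- 0L
  for (k in 1:6) {
    sim <- simulate_escan(melanin_scene("lesion_like"),
                          speckle_model(4, seed = 50 + k))
    seg <- segment_melanin(denoise_fallback(sim$image))
    if (nrow(seg$confetti_objects) < 2) next
    # same masks re-measured at twice the pixel pitch
    seg2 <- seg
    seg2$scale_um_per_px <- 2 * seg$scale_um_per_px
    for (tb in c("grain_objects", "confetti_objects")) {
      seg2[[tb]]$area_um2 <- seg[[tb]]$area_um2 * 4
      seg2[[tb]]$eq_diameter_um <- seg[[tb]]$eq_diameter_um * 2
    }
    f1 <- melanin_features(seg)
    f2 <- melanin_features(seg2)
    expect_equal(f2$G_area, 4 * f1$G_area)
    expect_equal(f2$C_area, 4 * f1$C_area)
    expect_equal(f2$C_size_mean, 4 * f1$C_size_mean)
    expect_equal(f2$C_distance_mean, 2 * f1$C_distance_mean)
    expect_equal(f2$C_distance_SD, 2 * f1$C_distance_SD)
    expect_equal(f2$C_roundness, f1$C_roundness)
    expect_equal(f2$G_density, f1$G_density)
    expect_equal(f2$G_intensity_mean, f1$G_intensity_mean)
    checked <- checked + 1L
  }
  expect_gte(checked, 4L)
})

test_that("featurize_manifest carries labels, is deterministic, isolates failures", {
  dir <- withr::local_tempdir()
  man <- simulate_cohort(2, seed = 19, dir = dir)
  ft <- featurize_manifest(man)
  expect_equal(nrow(ft), 4L)
  expect_true(all(c("image_id", "condition", "layer") %in% names(ft)))
  expect_equal(sum(ft$condition == "lesion"), 2L)
  ft2 <- featurize_manifest(man)
  expect_identical(ft, ft2)
  # corrupt one file: three valid rows plus one recorded failure
  writeLines("not a png", man$path[2])
  expect_warning(ft3 <- featurize_manifest(man), "failed")
  expect_equal(nrow(ft3), 3L)
  expect_length(attr(ft3, "failures"), 1L)
})
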