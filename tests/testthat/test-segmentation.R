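test_that("the normalized melanin threshold maps to gray level 153", {
  p <- segmentation_params()
  expect_identical(p$melanin_threshold_gray, 153L)
  enh <- matrix(c(153L, 154L, 0L, 255L), 2, 2)
  m <- threshold_candidates(enh, p)
  expect_identical(as.vector(m), c(FALSE, TRUE, FALSE, TRUE))
  expect_false(any(threshold_candidates(matrix(0L, 4, 4), p)))
})

test_that("parameter invariants are enforced", {
  expect_error(segmentation_params(melanin_threshold = 0.1,
                                   tissue_threshold_gray = 38), "exceed")
  expect_error(segmentation_params(confetti_min_area_um2 = 0.1,
                                   grain_min_diameter_um = 0.5), "gate")
  expect_error(segmentation_params(connectivity = 6), "4 or 8")
})

test_that("a constant image is a fixed point of contrast enhancement", {
  img <- oct_image(matrix(90L, 64, 64), 0.5)
  enh <- enhance_contrast(img, segmentation_params(clahe_tiles = c(4, 4)))
  expect_equal(length(unique(as.vector(enh))), 1L)
})

test_that("tile mappings match the hand-computed exponential CLAHE oracle", {
  p <- segmentation_params(clahe_tiles = c(1, 1))
  set.seed(8)
  img <- matrix(sample(40:140, 24 * 24, TRUE), 24, 24)
  img[5, 5] <- 200L
  enh <- enhance_contrast(oct_image(img, 0.5), p)
  counts <- tabulate(img + 1L, 256L)
  map <- oracle_clahe_map(counts, length(img), p$clahe_lambda, p$clahe_clip)
  expect_identical(as.vector(enh), map[as.vector(img) + 1L])
  # a bright outlier lands at the top of the local mapping
  expect_equal(enh[5, 5], max(enh))
})

test_that("a dim isolated spot is enhanced by the oracle-computed amount", {
  # gray-140 spot on a gray-60 tile; frozen expectation computed with
  # oracle_clahe_map under the strong default contrast limit
  img <- matrix(60L, 22, 22)
  img[11, 11] <- 140L
  p <- segmentation_params(clahe_tiles = c(1, 1))
  enh <- enhance_contrast(oct_image(img, 0.5), p)
  map <- oracle_clahe_map(tabulate(img + 1L, 256L), length(img),
                          p$clahe_lambda, p$clahe_clip)
  expect_identical(enh[11, 11], map[141L])
  expect_gt(enh[11, 11], max(enh[img == 60L]))  # stays the local maximum
})

test_that("opening removes single pixels and keeps 2x2-solid objects", {
  p <- segmentation_params()
  m <- matrix(FALSE, 10, 10)
  m[2, 2] <- TRUE                       # isolated pixel: removed by opening
  m[5:7, 5:7] <- TRUE                   # 3x3 square: survives
  g <- extract_grain(m, p, scale_um_per_px = 0.53)
  expect_equal(nrow(g$grain_objects), 1L)
  expect_equal(g$grain_objects$n_px, 9L)
  expect_equal(g$grain_objects$area_um2, 9 * 0.53^2)
  expect_gt(g$grain_objects$eq_diameter_um, 0.5)
  g0 <- extract_grain(matrix(FALSE, 6, 6), p, 0.5)
  expect_equal(nrow(g0$grain_objects), 0L)
})

test_that("the confetti area gate is strict and counts only grain pixels", {
  p <- segmentation_params()
  # a 2x2 block is one closed component; choose scales so its area sits
  # just below, then above, the 8.42 um^2 gate
  m <- matrix(FALSE, 8, 8); m[3:4, 3:4] <- TRUE
  below <- extract_confetti(m, p, scale_um_per_px = 1.45)  # 8.41 um^2
  expect_equal(nrow(below$confetti_objects), 0L)
  above <- extract_confetti(m, p, scale_um_per_px = 1.46)  # 8.53 um^2
  expect_equal(nrow(above$confetti_objects), 1L)
  # the gate corresponds to an equivalent circle of ~3.3 um
  expect_equal(round(2 * sqrt(8.42 / pi), 1), 3.3)
})

test_that("closing merges blobs across a 1-px gap without counting the gap", {
  p <- segmentation_params()
  m <- matrix(FALSE, 12, 16)
  m[4:5, 3:7] <- TRUE                   # 10 px
  m[4:5, 9:13] <- TRUE                  # 10 px, 1-column gap at column 8
  cf <- extract_confetti(m, p, scale_um_per_px = 1)
  expect_equal(nrow(cf$confetti_objects), 1L)
  expect_equal(cf$confetti_objects$n_px, 20L)
  expect_equal(cf$confetti_objects$area_um2, 20)
  expect_true(all(m[cf$confetti_mask]))
})

test_that("the tissue mask is a strict 38 gray-level cut", {
  p <- segmentation_params()
  enh <- matrix(c(0L, 38L, 39L, 255L), 2, 2)
  expect_identical(as.vector(tissue_mask(enh, p)),
                   c(FALSE, FALSE, TRUE, TRUE))
  expect_false(any(tissue_mask(matrix(0L, 3, 3), p)))
})

test_that("tissue fraction tracks the generator's painted tissue", {
  sc <- tiny_scene(fov = 160L, tissue_gray_mean = 80L, border_px = 12L,
                   grain_rate = 0, confetti_parent_rate = 0)
  sim <- simulate_escan(sc, speckle_model(looks = 4, seed = 17))
  seg <- segment_melanin(denoise_fallback(sim$image))
  true_frac <- mean(sim$structure > 38)
  expect_lt(abs(mean(seg$tissue_mask) - true_frac), 0.05)
})

test_that("masks nest: confetti within grain within candidates", {
  for (seed in c(3, 14)) {
    sim <- simulate_escan(tiny_scene("lesion_like"), speckle_model(4, seed))
    seg <- segment_melanin(denoise_fallback(sim$image))
    expect_true(all(seg$binary_candidates[seg$grain_mask]))
    expect_true(all(seg$grain_mask[seg$confetti_mask]))
    expect_true(all(seg$confetti_objects$area_um2 > 8.42))
    expect_true(all(seg$grain_objects$eq_diameter_um > 0.5))
  }
})

test_that("raising the melanin threshold never increases grain area", {
  sim <- simulate_escan(tiny_scene("lesion_like"), speckle_model(4, 23))
  dn <- denoise_fallback(sim$image)
  areas <- vapply(c(0.55, 0.6, 0.7, 0.8), function(th) {
    seg <- segment_melanin(dn, segmentation_params(melanin_threshold = th))
    sum(seg$grain_objects$area_um2)
  }, 0)
  expect_true(all(diff(areas) <= 0))
})

test_that("grain and confetti tables match the flood-fill oracle exactly", {
  set.seed(31)
  p <- segmentation_params()
  for (k in 1:20) {
    nr <- sample(8:32, 1); nc <- sample(8:32, 1)
    m <- matrix(stats::runif(nr * nc) < 0.35, nr, nc)
    g <- extract_grain(m, p, 0.5)
    og <- oracle_grain(m, 0.5)
    expect_identical(g$grain_mask, og$mask)
    expect_equal(nrow(g$grain_objects), nrow(og$tab))
    if (nrow(og$tab)) {
      ord <- order(og$tab$centroid_x_px, og$tab$centroid_y_px)
      ord2 <- order(g$grain_objects$centroid_x_px,
                    g$grain_objects$centroid_y_px)
      expect_equal(g$grain_objects[ord2, c("n_px", "area_um2",
                                           "centroid_x_px", "centroid_y_px",
                                           "perimeter_px")],
                   og$tab[ord, ], ignore_attr = TRUE)
    }
    cf <- extract_confetti(g$grain_mask, p, 0.5)
    ocf <- oracle_confetti(og$mask, 0.5)
    expect_identical(cf$confetti_mask, ocf$mask)
    expect_equal(nrow(cf$confetti_objects), nrow(ocf$tab))
  }
})

test_that("labeling honours the connectivity parameter", {
  m <- matrix(0, 4, 4); m[1, 1] <- 1; m[2, 2] <- 1
  expect_equal(max(label_components(m, 8)), 1L)
  expect_equal(max(label_components(m, 4)), 2L)
  expect_identical(label_components(m, 8), oracle_label(m, 8))
  expect_identical(label_components(m, 4), oracle_label(m, 4))
})

test_that("detection recovers synthetic ground truth at 2 um tolerance", {
  # pooled over four scenes under the bright-melanin, looks-4 conditions
  tp_d <- 0; nd <- 0; tp_t <- 0; nt <- 0
  for (seed in 1:4) {
    cond <- if (seed %% 2) "perilesional_like" else "lesion_like"
    sim <- simulate_escan(melanin_scene(cond), speckle_model(4, seed))
    seg <- segment_melanin(denoise_fallback(sim$image))
    m <- match_objects(seg$grain_objects, sim$truth$object_table, 0.5, 2)
    nd <- nd + m$n_detected; nt <- nt + m$n_truth
    tp_d <- tp_d + m$precision * m$n_detected
    tp_t <- tp_t + m$recall * m$n_truth
  }
  expect_gte(tp_t / nt, 0.9)   # recall
  expect_gte(tp_d / nd, 0.8)   # precision
})
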