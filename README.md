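# octmelanin

Melanin morphometry for cellular-resolution full-field optical coherence
tomography (FF-OCT) skin images.

Pigmentary disorders such as melasma are monitored by how much melanin the
epidermis holds and how it is distributed, but reading FF-OCT stacks by eye
is slow and subjective. `octmelanin` implements a computer-aided detection
pipeline for dermatology imaging groups: it suppresses multiplicative
speckle, segments hyper-reflective melanin into **grain** (any object with
equivalent diameter > 0.5 µm) and **confetti** (aggregates with area
> 8.42 µm², a subset of grain) classes, extracts 18 morphometric features
per image, and tests every feature between lesion and perilesional cohorts,
stratified by skin layer (stratum spinosum, dermal–epidermal junction,
papillary dermis). A seeded synthetic FF-OCT simulator with exact ground
truth makes the whole chain testable without clinical data.

## The method

* **Spatial compounding.** Eleven adjacent B-scan slices share structure
  but carry independent speckle. Their mean is a low-speckle *clean* image;
  the mean of 5 centre-out slices is a matched *noisy* image; the signed
  difference is the *residual* (noise map). These triplets are free
  training data measured from the imaging process itself.
* **SC-DnCNN.** A residual-learning convolutional denoiser (conv 3×3 →
  [conv+batch-norm+ReLU]×(depth−2) → linear conv) predicts the residual,
  which is subtracted from the input: `x_denoised = clip(x − f(x), 0, 255)`.
  Trained with SGD (momentum 0.9) on the MSE to the true residual; implemented
  in base R with BLAS matrix kernels, with a seeded, CPU-scale `desk_scale`
  preset and a learning-free fallback (11-slice compound for stacks, median +
  light Gaussian for single images).
* **Detection.** Exponential-target CLAHE (λ = 0.1, ~12.5 µm tiles, clip
  0.001) → candidates at enhanced gray > 153 (0.6 normalized) → 2×2 opening
  and diameter gate (grain) → 3×3 closing and strict 8.42 µm² area gate
  (confetti). Tissue = enhanced gray > 38.
* **Features and statistics.** Areas, grain density (% of tissue), pairwise
  confetti centroid distances (mean/SD, µm), roundness
  `4π·area/perimeter²`, size and brightness summaries; per feature and
  layer, a Kolmogorov–Smirnov normality gate chooses Student's t-test
  (mean ± SD) or Mann–Whitney U (median), two-sided, α = 0.05.

## Worked example

```r
library(octmelanin)

# a clustered "lesion-like" scene with multiplicative speckle (4 looks)
sim <- simulate_escan(melanin_scene("lesion_like"),
                      speckle_model(looks = 4, seed = 1))
seg <- segment_melanin(denoise_fallback(sim$image))
seg
#> <melanin_segmentation> 256 x 256 px at 0.5 um/px
#>   26 grain objects (121.5 um2), 4 confetti (43.5 um2), tissue 99.9%

melanin_features(seg)[, c("G_area", "G_density", "C_area",
                          "C_distance_mean", "C_roundness")]
#>   G_area G_density C_area C_distance_mean C_roundness
#> 1  121.5 0.7422454   43.5        55.14727   0.6551278
```

121.5 µm² of melanin was detected, covering 0.74 % of the tissue; the four
confetti aggregates lie on average 55 µm apart — the clustered placement
pulls this below the ~67 µm expected for uniformly scattered aggregates in
a 128 µm field. A full cohort comparison:

```r
man   <- simulate_cohort(24, seed = 1, dir = NULL)   # 24 images per condition
feats <- featurize_manifest(man)
rep   <- stratified_report(feats)
subset(as.data.frame(rep), feature == "C_distance_mean" & layer == "all",
       select = c(feature, test_used, p_value, significant))
#>           feature test_used      p_value significant
#> 8 C_distance_mean    t_test 1.362478e-05        TRUE
```

The lesion-like cohort's confetti spacing is significantly smaller — the
clustered-vs-uniform contrast the pipeline exists to detect. A thin CLI over
the same functions ships in `inst/cli/octmelanin`
(`simulate | denoise | detect | features | compare | run`).

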