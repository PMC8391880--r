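#' Normality gate for a feature sample
#'
#' One-sample Kolmogorov-Smirnov test of the values against a normal
#' distribution with the sample mean and SD; the sample passes (is treated
#' as normal) when the KS p-value is at least `alpha`. Because the
#' reference parameters are estimated from the same sample, the plain KS
#' critical values are anti-conservative (the Lilliefors caveat);
#' `lilliefors = TRUE` switches to the Lilliefors-corrected test. Degenerate
#' samples — fewer than 4 values, or zero spread — fail by convention.
#'
#' @param values numeric vector (NAs dropped).
#' @param alpha significance level of the gate.
#' @param lilliefors use the Lilliefors correction.
#' @return `TRUE` (treat as normal) or `FALSE`.
#' @export
test_normality <- function(values, alpha = 0.05, lilliefors = FALSE) {
  x <- values[is.finite(values)]
  if (length(x) < 4L) return(FALSE)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(FALSE)
  p <- if (lilliefors) nortest::lillie.test(x)$p.value
       else suppressWarnings(
         stats::ks.test(x, "pnorm", mean = mean(x), sd = s)$p.value)
  p >= alpha
}

#' Two-sample comparison of a feature between cohorts
#'
#' When both groups pass the normality gate the feature is compared with a
#' two-sided Student's t-test (equal variances unless `welch = TRUE`) and
#' summarized as mean and SD; otherwise with a two-sided Mann-Whitney U
#' test and summarized by the median. Missing values are dropped and the
#' remaining counts reported.
#'
#' @param lesion,perilesional numeric feature values per group.
#' @param feature,layer labels carried into the output row.
#' @param alpha significance level.
#' @param normality `"auto"` (KS gate), or force `"normal"`/`"nonnormal"`.
#' @param welch use the Welch t-test instead of Student's.
#' @param lilliefors Lilliefors correction in the normality gate.
#' @return one-row `data.frame` of class `group_comparison`: group sizes,
#'   normality decisions, `test_used`, group summaries (mean, SD, median
#'   each), `p_value` and `significant`. When a group has fewer than two
#'   defined values the comparison is skipped and `note` says why.
#' @export
compare_groups <- function(lesion, perilesional, feature = "feature",
                           layer = "all", alpha = 0.05,
                           normality = c("auto", "normal", "nonnormal"),
                           welch = FALSE, lilliefors = FALSE) {
  normality <- match.arg(normality)
  x <- lesion[is.finite(lesion)]
  y <- perilesional[is.finite(perilesional)]
  row <- data.frame(
    feature = feature, layer = layer,
    n_lesion = length(x), n_perilesional = length(y),
    normal_lesion = NA, normal_perilesional = NA,
    test_used = NA_character_,
    mean_lesion = if (length(x)) mean(x) else NA_real_,
    sd_lesion = if (length(x) > 1) stats::sd(x) else NA_real_,
    median_lesion = if (length(x)) stats::median(x) else NA_real_,
    mean_perilesional = if (length(y)) mean(y) else NA_real_,
    sd_perilesional = if (length(y) > 1) stats::sd(y) else NA_real_,
    median_perilesional = if (length(y)) stats::median(y) else NA_real_,
    p_value = NA_real_, significant = NA, note = "",
    stringsAsFactors = FALSE)
  class(row) <- c("group_comparison", "data.frame")
  if (length(x) < 2L || length(y) < 2L) {
    row$note <- "skipped: fewer than 2 defined values in a group"
    return(row)
  }
  norm_x <- switch(normality, auto = test_normality(x, alpha, lilliefors),
                   normal = TRUE, nonnormal = FALSE)
  norm_y <- switch(normality, auto = test_normality(y, alpha, lilliefors),
                   normal = TRUE, nonnormal = FALSE)
  row$normal_lesion <- norm_x
  row$normal_perilesional <- norm_y
  if (norm_x && norm_y) {
    row$test_used <- "t_test"
    row$p_value <- stats::t.test(x, y, var.equal = !welch,
                                 alternative = "two.sided")$p.value
  } else {
    row$test_used <- "mann_whitney_u"
    row$p_value <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided")$p.value)
  }
  row$significant <- row$p_value < alpha
  row
}

#' Layer-stratified comparison report over a feature table
#'
#' Runs [compare_groups()] for every feature, pooled and within each skin
#' layer present, optionally for a second ("before denoising") feature
#' table so the with/without-denoiser contrast appears as paired
#' Before/After rows. Features undefined in more than half of a group are
#' flagged `low_n`.
#'
#' @param features feature table from [featurize_manifest()].
#' @param features_before optional second table (same schema), reported as
#'   `denoising = "before"` rows.
#' @param by_layer stratify by the `layer` column (pooled-only with a
#'   warning when layer labels are missing).
#' @param alpha significance level.
#' @param adjust `"none"` (default, each feature tested at `alpha`) or
#'   `"BH"` for Benjamini-Hochberg adjusted p-values (added as `p_adjusted`).
#' @param ... passed to [compare_groups()] (`normality`, `welch`,
#'   `lilliefors`).
#' @return `data.frame` of class `melanin_report`, one row per
#'   feature x stratum (x denoising state).
#' @export
stratified_report <- function(features, features_before = NULL,
                              by_layer = TRUE, alpha = 0.05,
                              adjust = c("none", "BH"), ...) {
  adjust <- match.arg(adjust)
  feat_cols <- intersect(FEATURE_NAMES, names(features))
  if (!length(feat_cols)) stop("no feature columns found", call. = FALSE)
  strata <- "all"
  if (by_layer) {
    if (is.null(features$layer) || all(is.na(features$layer))) {
      warning("no layer labels; pooled-only report", call. = FALSE)
    } else strata <- c("all", unique(stats::na.omit(features$layer)))
  }
  one_table <- function(tab, label) {
    rows <- list()
    for (st in strata) {
      sub <- if (st == "all") tab else tab[tab$layer == st, , drop = FALSE]
      les <- sub[sub$condition == "lesion", , drop = FALSE]
      per <- sub[sub$condition == "perilesional", , drop = FALSE]
      for (f in feat_cols) {
        cmp <- compare_groups(les[[f]], per[[f]], feature = f, layer = st,
                              alpha = alpha, ...)
        cmp$denoising <- label
        cmp$low_n <- (cmp$n_lesion < nrow(les) / 2) ||
          (cmp$n_perilesional < nrow(per) / 2)
        rows[[paste(label, st, f)]] <- cmp
      }
    }
    do.call(rbind, rows)
  }
  out <- one_table(features, "after")
  if (!is.null(features_before))
    out <- rbind(one_table(features_before, "before"), out)
  if (adjust == "BH")
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  class(out) <- c("melanin_report", "data.frame")
  out
}

#' @export
print.melanin_report <- function(x, digits = 4, max_rows = 20L, ...) {
  cat(sprintf("<melanin_report> %d comparisons (%d significant at p < 0.05)\n",
              nrow(x), sum(x$significant, na.rm = TRUE)))
  show <- x[order(x$p_value), c("feature", "layer", "denoising", "test_used",
                                "n_lesion", "n_perilesional", "p_value",
                                "significant")]
  print.data.frame(utils::head(show, max_rows), digits = digits,
                   row.names = FALSE)
  if (nrow(x) > max_rows) cat("...", nrow(x) - max_rows, "more rows\n")
  invisible(x)
}
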