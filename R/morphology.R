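# Binary morphology on logical matrices, with exactly defined structuring
# elements, plus connected-component labeling and per-object tables.
#
# The structuring elements the detection chain needs (2x2 square for the
# opening, radius-1 disk for the closing) are implemented as vectorized
# shift-and-combine operations: opening/closing are anchor-invariant, and an
# explicit offset set keeps the result bit-reproducible by the brute-force
# oracles used in the tests. Pixels outside the image count as background.

# shift a matrix by (di, dj): out[i, j] = m[i + di, j + dj], `fill` outside
shift_mat <- function(m, di, dj, fill = FALSE) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  ri <- max(1, 1 - di):min(nr, nr - di)
  cj <- max(1, 1 - dj):min(nc, nc - dj)
  if (length(ri) && length(cj)) out[ri, cj] <- m[ri + di, cj + dj]
  out
}

# offsets (di, dj) of the supported structuring elements
se_offsets <- function(se = c("square2", "disk1", "box3")) {
  se <- match.arg(se)
  switch(se,
    square2 = cbind(di = c(0, 1, 0, 1), dj = c(0, 0, 1, 1)),
    disk1   = cbind(di = c(0, -1, 1, 0, 0), dj = c(0, 0, 0, -1, 1)),
    box3    = as.matrix(expand.grid(di = -1:1, dj = -1:1)))
}

binary_erode <- function(mask, se = "square2") {
  off <- se_offsets(se)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off)))
    out <- out & shift_mat(mask, off[k, 1L], off[k, 2L], fill = FALSE)
  out
}

binary_dilate <- function(mask, se = "square2") {
  off <- se_offsets(se)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off)))   # reflected offsets
    out <- out | shift_mat(mask, -off[k, 1L], -off[k, 2L], fill = FALSE)
  out
}

#' Binary opening and closing
#'
#' `binary_open` removes structures smaller than the structuring element
#' (erosion followed by dilation); `binary_close` bridges gaps narrower than
#' the element (dilation followed by erosion). Supported elements:
#' `"square2"` (2 x 2 square), `"disk1"` (the plus-shaped 4-neighbourhood)
#' and `"box3"` (3 x 3 square, the pixel disk of radius 1 under the
#' chessboard metric). Outside the image is background.
#'
#' @param mask logical matrix.
#' @param se structuring element name.
#' @return logical matrix of the same size.
#' @export
binary_open <- function(mask, se = "square2") {
  mask <- mask != 0
  binary_dilate(binary_erode(mask, se), se)
}

#' @rdname binary_open
#' @export
binary_close <- function(mask, se = "box3") {
  mask <- mask != 0
  binary_erode(binary_dilate(mask, se), se)
}

#' Label connected foreground components
#'
#' Components of a binary mask under 8- or 4-connectivity. Labels are
#' assigned in raster (column-major) order of each component's first pixel,
#' so the labeling is deterministic.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 8 (default; diagonal neighbours connect) or 4.
#' @return integer matrix; 0 is background, components are numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  n <- length(fg)
  if (n == 0L) return(labels)
  id <- integer(nr * nc)           # linear index -> vertex id
  id[fg] <- seq_len(n)
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  from <- integer(0); to <- integer(0)
  ri <- (fg - 1L) %% nr + 1L
  ci <- (fg - 1L) %/% nr + 1L
  for (o in offs) {
    r2 <- ri + o[1L]; c2 <- ci + o[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 <= nc
    lin2 <- r2[ok] + (c2[ok] - 1L) * nr
    hit <- mask[lin2]
    from <- c(from, id[fg[ok]][hit])
    to <- c(to, id[lin2[hit]])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  memb <- igraph::components(g)$membership
  # renumber by first (smallest linear index) pixel of each component
  first <- vapply(split(fg, memb), min, numeric(1))
  renum <- integer(length(first))
  renum[order(first)] <- seq_along(first)
  labels[fg] <- renum[memb]
  labels
}

# contour pixels: foreground pixels 8-adjacent to background (image border
# counts as background)
contour_mask <- function(mask) {
  mask <- mask != 0
  mask & !binary_erode(mask, "box3")
}

#' Per-component object table
#'
#' Measures every labeled component: pixel count, physical area, unweighted
#' pixel centroid, contour-pixel perimeter and (optionally) gray-level
#' statistics under the component from a co-registered image. The perimeter
#' is the number of object pixels 8-adjacent to background, matching the
#' pixel-count convention of the roundness metric.
#'
#' @param labels integer label matrix from [label_components()].
#' @param scale_um_per_px pixel pitch, for areas in square micrometres.
#' @param image optional co-registered gray-level matrix.
#' @return a `data.frame` with one row per component: `id`, `n_px`,
#'   `area_um2`, `centroid_x_px`, `centroid_y_px`, `perimeter_px`,
#'   `eq_diameter_um`, and `gray_min`/`gray_max`/`gray_mean`/`gray_sd` when
#'   `image` is given (population SD).
#' @export
component_table <- function(labels, scale_um_per_px, image = NULL) {
  idx <- which(labels > 0L)
  empty <- data.frame(id = integer(0), n_px = integer(0),
                      area_um2 = numeric(0), centroid_x_px = numeric(0),
                      centroid_y_px = numeric(0), perimeter_px = integer(0),
                      eq_diameter_um = numeric(0))
  if (!is.null(image))
    empty <- cbind(empty, gray_min = numeric(0), gray_max = numeric(0),
                   gray_mean = numeric(0), gray_sd = numeric(0))
  if (!length(idx)) return(empty)
  lab <- labels[idx]
  nr <- nrow(labels)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  ids <- sort(unique(lab))
  f <- factor(lab, levels = ids)
  n_px <- as.integer(tabulate(f))
  ctm <- contour_mask(labels > 0L)
  per <- as.integer(tabulate(factor(labels[which(ctm)], levels = ids)))
  area <- n_px * scale_um_per_px^2
  out <- data.frame(
    id = seq_along(ids),
    n_px = n_px,
    area_um2 = area,
    centroid_x_px = as.numeric(tapply(cc, f, mean)),
    centroid_y_px = as.numeric(tapply(r, f, mean)),
    perimeter_px = per,
    eq_diameter_um = 2 * sqrt(area / pi))
  if (!is.null(image)) {
    v <- as.numeric(image[idx])
    out$gray_min <- as.numeric(tapply(v, f, min))
    out$gray_max <- as.numeric(tapply(v, f, max))
    out$gray_mean <- as.numeric(tapply(v, f, mean))
    out$gray_sd <- as.numeric(tapply(v, f, function(z)
      sqrt(mean((z - mean(z))^2))))
  }
  rownames(out) <- NULL
  out
}
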