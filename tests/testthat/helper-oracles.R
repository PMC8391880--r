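# Independent brute-force oracles used to cross-check the vectorized
# implementations. Everything here is written as plain loops over pixels or
# exhaustive enumeration, deliberately sharing no code with the package.

# flood-fill connected-component labeling (stack-based, per pixel)
oracle_label <- function(mask, connectivity = 8) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8)
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  lab <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || labels[i, j] > 0L) next
    lab <- lab + 1L
    stack <- list(c(i, j))
    labels[i, j] <- lab
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        q <- p + o
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            mask[q[1], q[2]] && labels[q[1], q[2]] == 0L) {
          labels[q[1], q[2]] <- lab
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  labels
}

# per-component measurements by explicit pixel counting
oracle_table <- function(labels, scale) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids))
    return(data.frame(n_px = integer(0), area_um2 = numeric(0),
                      centroid_x_px = numeric(0), centroid_y_px = numeric(0),
                      perimeter_px = integer(0)))
  nr <- nrow(labels); nc <- ncol(labels)
  rows <- lapply(ids, function(id) {
    px <- which(labels == id, arr.ind = TRUE)
    per <- 0L
    for (k in seq_len(nrow(px))) {
      i <- px[k, 1]; j <- px[k, 2]
      edge <- FALSE
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > nr || jj < 1 || jj > nc || labels[ii, jj] == 0)
          edge <- TRUE
      }
      if (edge) per <- per + 1L
    }
    data.frame(n_px = nrow(px), area_um2 = nrow(px) * scale^2,
               centroid_x_px = mean(px[, 2]), centroid_y_px = mean(px[, 1]),
               perimeter_px = per)
  })
  do.call(rbind, rows)
}

# binary erosion/dilation/opening/closing by explicit window loops
oracle_open2x2 <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  er <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (di in 0:1) for (dj in 0:1) {
      ii <- i + di; jj <- j + dj
      if (ii > nr || jj > nc || !mask[ii, jj]) ok <- FALSE
    }
    er[i, j] <- ok
  }
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    hit <- FALSE
    for (di in 0:1) for (dj in 0:1) {
      ii <- i - di; jj <- j - dj
      if (ii >= 1 && jj >= 1 && er[ii, jj]) hit <- TRUE
    }
    out[i, j] <- hit
  }
  out
}

oracle_close_box3 <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  offs <- list()
  for (di in -1:1) for (dj in -1:1) offs[[length(offs) + 1L]] <- c(di, dj)
  di <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    hit <- FALSE
    for (o in offs) {
      ii <- i - o[1]; jj <- j - o[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && mask[ii, jj])
        hit <- TRUE
    }
    di[i, j] <- hit
  }
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ok <- TRUE
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii < 1 || ii > nr || jj < 1 || jj > nc || !di[ii, jj]) ok <- FALSE
    }
    out[i, j] <- ok
  }
  out
}

# grain/confetti chain on a candidate mask, entirely via the oracles above
oracle_grain <- function(binary, scale, min_diam = 0.5) {
  opened <- oracle_open2x2(binary)
  labels <- oracle_label(opened, 8)
  tab <- oracle_table(labels, scale)
  keep <- which(2 * sqrt(tab$area_um2 / pi) > min_diam)
  mask <- matrix(FALSE, nrow(binary), ncol(binary))
  for (id in keep) mask[labels == id] <- TRUE
  list(mask = mask, tab = tab[keep, , drop = FALSE], labels = labels)
}

oracle_confetti <- function(grain_mask, scale, min_area = 8.42) {
  closed <- oracle_close_box3(grain_mask)
  labels <- oracle_label(closed, 8)
  labels[!grain_mask] <- 0L
  tab <- oracle_table(labels, scale)
  ids <- sort(unique(labels[labels > 0]))
  keep <- which(tab$area_um2 > min_area)
  mask <- matrix(FALSE, nrow(grain_mask), ncol(grain_mask))
  for (id in ids[keep]) mask[labels == id] <- TRUE
  list(mask = mask, tab = tab[keep, , drop = FALSE])
}

# exact two-sided Mann-Whitney p-value by enumerating all rank splits,
# using the doubled-tail convention
oracle_mw_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_stat(x, y)
  pool <- c(x, y)
  splits <- utils::combn(nx + ny, nx)
  us <- apply(splits, 2, function(ix) u_stat(pool[ix], pool[-ix]))
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# single-tile exponential-CLAHE mapping computed by explicit loops
oracle_clahe_map <- function(counts, npix, lambda, clip, nbins = 256) {
  minc <- ceiling(npix / nbins)
  cap <- minc + max(0, floor(clip * (npix - minc)))
  h <- counts
  for (it in 1:100) {
    excess <- 0
    for (b in seq_len(nbins)) if (h[b] > cap) {
      excess <- excess + h[b] - cap
      h[b] <- cap
    }
    if (excess < 1e-9) break
    under <- which(h < cap)
    if (!length(under)) break
    h[under] <- h[under] + excess / length(under)
  }
  P <- cumsum(h) / sum(h)
  g <- numeric(nbins)
  for (b in seq_len(nbins))
    g[b] <- -log(1 - P[b] * (1 - exp(-lambda))) / lambda
  as.integer(round(pmin(pmax(g, 0), 1) * 255))
}

# small scene presets used across tests
tiny_scene <- function(condition = "perilesional_like", fov = 128L, ...)
  melanin_scene(condition, fov_px = c(fov, fov), ...)
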