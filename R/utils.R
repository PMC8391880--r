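# small shared helpers

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Gaussian blur on a plain matrix (replicated boundary)
gauss_blur <- function(m, sigma) {
  img <- EBImage::Image(m)
  as.matrix(EBImage::imageData(EBImage::gblur(img, sigma = sigma,
                                              boundary = "replicate")))
}

# vectorized 3x3 median filter (replicate padding): odd-even transposition
# sort over the 9 shifted neighbour planes, so the whole image is filtered
# with a fixed number of pmin/pmax passes
median3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  planes <- vector("list", 9L)
  k <- 0L
  idx_r <- function(d) pmin(pmax(seq_len(nr) + d, 1L), nr)
  idx_c <- function(d) pmin(pmax(seq_len(nc) + d, 1L), nc)
  for (dj in -1:1) for (di in -1:1) {
    k <- k + 1L
    planes[[k]] <- m[idx_r(di), idx_c(dj)]
  }
  for (pass in 1:9) {
    start <- if (pass %% 2L) 1L else 2L
    for (i in seq(start, 8L, by = 2L)) {
      lo <- pmin(planes[[i]], planes[[i + 1L]])
      hi <- pmax(planes[[i]], planes[[i + 1L]])
      planes[[i]] <- lo; planes[[i + 1L]] <- hi
    }
  }
  planes[[5L]]
}

# population standard deviation (divide by n); the SD convention used for
# every per-object feature statistic
sd_pop <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  sqrt(mean((x - mean(x))^2))
}
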