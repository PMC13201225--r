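# Brute-force oracles kept independent of the package's EDT/partition code.

# all-pairs minimum physical distance from every voxel to the source mask
bruteEDT <- function(mask, sx = 8, sy = 8, sz = 33) {
  d <- dim(mask)
  src <- which(mask, arr.ind = TRUE)
  out <- array(NA_real_, d)
  allv <- which(array(TRUE, d), arr.ind = TRUE)
  for (q in seq_len(nrow(allv))) {
    dd <- sweep(src, 2, allv[q, ], "-")
    out[q] <- sqrt(min((dd[, 1] * sx)^2 + (dd[, 2] * sy)^2 +
                         (dd[, 3] * sz)^2))
  }
  out
}

# nearest of several source masks for a set of query voxels (subsampled),
# with ties broken in the order the masks are listed
bruteNearestRegion <- function(masks, quer, sx = 8, sy = 8, sz = 33) {
  srcs <- lapply(masks, function(m) which(m, arr.ind = TRUE))
  apply(quer, 1, function(p) {
    dmin <- vapply(srcs, function(s) {
      if (!nrow(s)) return(Inf)
      dd <- sweep(s, 2, p, "-")
      min((dd[, 1] * sx)^2 + (dd[, 2] * sy)^2 + (dd[, 3] * sz)^2)
    }, numeric(1))
    which.min(dmin)   # first minimum wins = listed priority
  })
}

# exhaustive max pairwise in-plane distance (pixel units)
bruteFeret <- function(xy) {
  if (nrow(xy) == 1) return(0)
  dd <- as.matrix(dist(xy))
  max(dd)
}
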