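# Shared low-level grid helpers used by the texture matrices and the
# synthetic generator.  All work on plain 3D arrays indexed [x, y, z].

# The 13 unique 3D grid offsets at Chebyshev distance 1 (one per
# direction/opposite pair of the 26-neighbourhood).
grid_offsets_13 <- function() {
  o <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  o <- o[!(o[, 1] == 0 & o[, 2] == 0 & o[, 3] == 0), , drop = FALSE]
  # keep one representative per +/- pair: first nonzero component positive
  keep <- apply(o, 1, function(v) v[match(TRUE, v != 0)] > 0)
  unname(o[keep, , drop = FALSE])
}

# Linear indices of all (from, to) voxel pairs separated by `offset`
# within a grid of dimensions `dims`.  Returns a 2-column integer matrix.
offset_pairs <- function(dims, offset) {
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, 1L - offset[a])
    hi <- min(dims[a], dims[a] - offset[a])
    if (lo > hi) integer(0) else lo:hi
  })
  nx <- length(rng[[1]]); ny <- length(rng[[2]]); nz <- length(rng[[3]])
  if (nx * ny * nz == 0L) return(matrix(integer(0), ncol = 2))
  x <- rep.int(rng[[1]], ny * nz)
  y <- rep.int(rep(rng[[2]], each = nx), nz)
  z <- rep(rng[[3]], each = nx * ny)
  s1 <- dims[1]; s2 <- dims[1] * dims[2]
  from <- x + s1 * (y - 1L) + s2 * (z - 1L)
  to <- (x + offset[1]) + s1 * (y + offset[2] - 1L) + s2 * (z + offset[3] - 1L)
  cbind(from, to)
}

# Voxel-centre coordinates (mm) of the in-mask voxels, one row per voxel.
mask_coords_mm <- function(indicator, spacing_mm, origin_mm = c(0, 0, 0)) {
  idx <- which(indicator, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, spacing_mm, `*`), 2, origin_mm, `+`)
}

# Separable Gaussian smoothing of a 3D array, zero-padded edges.
# `sigma_vox` is the kernel width per axis in voxel units; an axis with
# sigma 0 is left untouched.  Implemented as shift-and-add with a
# truncated (3 sigma) discrete kernel.
gaussian_smooth3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(-r:r)^2 / (2 * s^2))
    k <- k / sum(k)
    out <- array(0, d)
    for (j in seq_along(k)) {
      sh <- j - r - 1L  # shift in -r..r
      n <- d[axis]
      src_lo <- max(1L, 1L + sh); src_hi <- min(n, n + sh)
      if (src_lo > src_hi) next
      dst_lo <- src_lo - sh; dst_hi <- src_hi - sh
      src <- dst <- list(quote(expr = ), quote(expr = ), quote(expr = ))
      idx_src <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      idx_dst <- idx_src
      idx_src[[axis]] <- src_lo:src_hi
      idx_dst[[axis]] <- dst_lo:dst_hi
      out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
        k[j] * arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    }
    arr <- out
  }
  arr
}

# L2 norm of the truncated separable Gaussian kernel: the factor by which
# smoothing shrinks the standard deviation of white noise.
gaussian_kernel_l2 <- function(sigma_vox) {
  prod(vapply(sigma_vox, function(s) {
    if (s <= 0) return(1)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(-r:r)^2 / (2 * s^2))
    k <- k / sum(k)
    sqrt(sum(k^2))
  }, numeric(1)))
}
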