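# Grey-level texture matrices on a discretised ROI.
#
# Conventions, fixed across the package and mirrored by the test oracles:
#   * 3D neighbourhoods use the 13 unique voxel-grid offsets at Chebyshev
#     distance 1 (each direction/opposite pair counted once); direction
#     weights are all 1 and physical anisotropy is ignored.
#   * GLCM and GLRLM counts are pooled over all directions into a single
#     matrix before features are computed (no per-direction averaging).
#   * Out-of-mask voxels break runs, are excluded from neighbourhoods and
#     never co-occur.

#' Pooled symmetric grey-level co-occurrence matrix
#'
#' @param droi a [discretise()] result.
#' @param offsets integer matrix of grid offsets, one per row; default the
#'   13 unique 3D offsets at Chebyshev distance 1.  A restricted set is
#'   useful for hand-checked examples.
#' @return Ng x Ng matrix of probabilities, symmetric, summing to 1 (all
#'   zero if the ROI admits no voxel pair).
#' @export
glcm_matrix <- function(droi, offsets = grid_offsets_13()) {
  stopifnot(inherits(droi, "discretised_roi"))
  ng <- droi$ng
  lv <- droi$levels
  d <- dim(lv)
  counts <- numeric(ng * ng)
  for (r in seq_len(nrow(offsets))) {
    pr <- offset_pairs(d, offsets[r, ])
    if (!nrow(pr)) next
    i <- lv[pr[, 1]]; j <- lv[pr[, 2]]
    ok <- !is.na(i) & !is.na(j)
    if (!any(ok)) next
    i <- i[ok]; j <- j[ok]
    # symmetric: count each unordered neighbour pair in both orders
    counts <- counts + tabulate(i + ng * (j - 1L), ng * ng) +
      tabulate(j + ng * (i - 1L), ng * ng)
  }
  m <- matrix(counts, ng, ng)
  s <- sum(m)
  if (s > 0) m / s else m
}

#' GLCM features (20)
#'
#' Computed from the pooled symmetric normalised co-occurrence matrix
#' `p(i, j)`.  `Sum_of_Square_Variance` is `sum(p * (i - mu)^2)` with `mu`
#' the joint mean of `i`.  For a single-level ROI the variance-type
#' features are 0, `Maximum_Probability` is 1 and `Correlation` is defined
#' as 1.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of 20 features.
#' @export
glcm_features <- function(droi, offsets = grid_offsets_13()) {
  p <- glcm_matrix(droi, offsets)
  ng <- nrow(p)
  nm <- paste0(c("Maximum_Probability", "Joint_Average",
                 "Sum_of_Square_Variance", "Joint_Entropy",
                 "Angular_Second_Moment", "Contrast", "Dissimilarity",
                 "Inverse_Difference", "Inverse_Difference_Normalised",
                 "Inverse_Difference_Moment",
                 "Inverse_Difference_Moment_Normalised", "Inverse_Variance",
                 "Correlation", "Autocorrelation", "Cluster_Tendency",
                 "Cluster_Shade", "Cluster_Prominence", "Sum_Average",
                 "Sum_Entropy", "Difference_Entropy"), "_GLCM")
  if (sum(p) == 0) {  # no voxel pair at all (e.g. single-voxel ROI)
    out <- stats::setNames(numeric(20), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  mu <- sum(i * p)
  sig2 <- sum((i - mu)^2 * p)
  adiff <- abs(i - j)
  pos <- p > 0
  # marginal sums p_{x+y}(k), k = 2..2Ng and p_{|x-y|}(k), k = 0..Ng-1
  psum <- vapply(2:(2 * ng), function(k) sum(p[(i + j) == k]), numeric(1))
  pdiff <- vapply(0:(ng - 1), function(k) sum(p[adiff == k]), numeric(1))
  ent <- function(q) { q <- q[q > 0]; if (!length(q)) 0 else -sum(q * log2(q)) }
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 1
  out <- c(
    max(p), mu, sig2, ent(p), sum(p^2),
    sum(adiff^2 * p), sum(adiff * p),
    sum(p / (1 + adiff)), sum(p / (1 + adiff / ng)),
    sum(p / (1 + adiff^2)), sum(p / (1 + adiff^2 / ng^2)),
    sum(p[adiff > 0] / adiff[adiff > 0]^2),
    corr, sum(i * j * p),
    sum((i + j - 2 * mu)^2 * p), sum((i + j - 2 * mu)^3 * p),
    sum((i + j - 2 * mu)^4 * p),
    sum((2:(2 * ng)) * psum), ent(psum), ent(pdiff)
  )
  stats::setNames(out, nm)
}

#' Pooled grey-level run-length matrix
#'
#' Runs of equal grey level along each of the 13 directions; out-of-mask
#' voxels break runs; the 13 per-direction matrices are summed.
#'
#' @inheritParams glcm_matrix
#' @return Ng x Lmax matrix of run counts.
#' @export
glrlm_matrix <- function(droi, offsets = grid_offsets_13()) {
  stopifnot(inherits(droi, "discretised_roi"))
  ng <- droi$ng
  lv <- droi$levels
  d <- dim(lv)
  n <- length(lv)
  co <- arrayInd(seq_len(n), d)
  runs_level <- integer(0)
  runs_len <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    dvec <- offsets[r, ]
    # steps available walking backwards (against the direction) to the
    # line's entry voxel; (line anchor, t) orders voxels along each line
    t <- rep(Inf, n)
    for (a in 1:3) {
      if (dvec[a] == 1L) t <- pmin(t, co[, a] - 1L)
      else if (dvec[a] == -1L) t <- pmin(t, d[a] - co[, a])
    }
    ax <- co[, 1] - t * dvec[1]
    ay <- co[, 2] - t * dvec[2]
    az <- co[, 3] - t * dvec[3]
    anchor <- ax + d[1] * (ay - 1) + d[1] * d[2] * (az - 1)
    ord <- order(anchor, t)
    lo <- lv[ord]
    an <- anchor[ord]
    isna <- is.na(lo)
    newline <- c(TRUE, an[-1] != an[-n])
    cont <- c(FALSE, !isna[-1] & !isna[-n] & !newline[-1] &
                lo[-1] == lo[-n])
    start <- !isna & !cont
    run_id <- cumsum(start)
    lens <- tabulate(run_id[!isna])
    runs_level <- c(runs_level, lo[start])
    runs_len <- c(runs_len, lens)
  }
  if (!length(runs_len)) return(matrix(0, ng, 1))
  lmax <- max(runs_len)
  m <- matrix(0, ng, lmax)
  cnt <- tabulate(runs_level + ng * (runs_len - 1L), ng * lmax)
  m[] <- cnt
  m
}

#' GLRLM features (16)
#'
#' Standard run-length statistics of the pooled matrix: short/long-run
#' emphases, low/high grey-level emphases and their four crosses,
#' grey-level and run-length non-uniformity (plain and normalised), run
#' percentage (`Nr / (13 * Np)` under pooling, since each voxel lies on 13
#' lines), grey-level and run-length variance and run entropy (bits).
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(droi, offsets = grid_offsets_13()) {
  m <- glrlm_matrix(droi, offsets)
  np <- sum(droi$mask) * nrow(offsets)  # potential runs of length 1
  nr <- sum(m)
  nm <- paste0(c("Short_Run_Emphasis", "Long_Run_Emphasis",
                 "Low_Grey_Level_Run_Emphasis",
                 "High_Grey_Level_Run_Emphasis",
                 "Short_Run_Low_Grey_Level_Emphasis",
                 "Short_Run_High_Grey_Level_Emphasis",
                 "Long_Run_Low_Grey_Level_Emphasis",
                 "Long_Run_High_Grey_Level_Emphasis",
                 "Grey_Level_Non_Uniformity",
                 "Grey_Level_Non_Uniformity_Normalised",
                 "Run_Length_Non_Uniformity",
                 "Run_Length_Non_Uniformity_Normalised",
                 "Run_Percentage", "Grey_Level_Variance",
                 "Run_Length_Variance", "Run_Entropy"), "_GLRLM")
  if (nr == 0) {
    out <- stats::setNames(numeric(16), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ngl <- nrow(m); lmax <- ncol(m)
  i <- matrix(seq_len(ngl), ngl, lmax)
  l <- matrix(seq_len(lmax), ngl, lmax, byrow = TRUE)
  p <- m / nr
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  ri <- rowSums(m); rl <- colSums(m)
  pv <- p[p > 0]
  out <- c(
    sum(m / l^2) / nr, sum(m * l^2) / nr,
    sum(m / i^2) / nr, sum(m * i^2) / nr,
    sum(m / (i^2 * l^2)) / nr, sum(m * i^2 / l^2) / nr,
    sum(m * l^2 / i^2) / nr, sum(m * i^2 * l^2) / nr,
    sum(ri^2) / nr, sum(ri^2) / nr^2,
    sum(rl^2) / nr, sum(rl^2) / nr^2,
    nr / np,
    sum((i - mu_i)^2 * p), sum((l - mu_l)^2 * p),
    -sum(pv * log2(pv))
  )
  stats::setNames(out, nm)
}

#' Neighbourhood grey-tone difference table
#'
#' For each in-mask voxel the neighbourhood is its 26-connected in-mask
#' neighbours; voxels with no in-mask neighbour are excluded.  Returns the
#' per-level occurrence counts `n_i`, probabilities `p_i` and absolute
#' grey-tone difference sums `s_i`.
#'
#' @param droi a [discretise()] result.
#' @return list with `n`, `p`, `s` (length Ng) and `n_valid`.
#' @export
ngtdm_table <- function(droi) {
  stopifnot(inherits(droi, "discretised_roi"))
  lv <- droi$levels
  d <- dim(lv)
  ng <- droi$ng
  nb_sum <- numeric(length(lv))
  nb_cnt <- numeric(length(lv))
  offs <- grid_offsets_13()
  for (r in seq_len(nrow(offs))) {
    pr <- offset_pairs(d, offs[r, ])
    if (!nrow(pr)) next
    a <- pr[, 1]; b <- pr[, 2]
    va <- lv[a]; vb <- lv[b]
    ok <- !is.na(va) & !is.na(vb)
    if (!any(ok)) next
    a <- a[ok]; b <- b[ok]; va <- va[ok]; vb <- vb[ok]
    # contribute in both directions of the offset pair
    add_s <- c(vb, va); at <- c(a, b)
    o <- order(at)  # aggregate with rowsum-style accumulation
    acc <- rowsum(as.numeric(add_s[o]), at[o])
    ids <- as.integer(rownames(acc))
    nb_sum[ids] <- nb_sum[ids] + acc[, 1]
    cnt <- rowsum(rep(1, length(at)), at)
    nb_cnt[as.integer(rownames(cnt))] <-
      nb_cnt[as.integer(rownames(cnt))] + cnt[, 1]
  }
  valid <- which(!is.na(lv) & nb_cnt > 0)
  lev <- lv[valid]
  abar <- nb_sum[valid] / nb_cnt[valid]
  n <- tabulate(lev, ng)
  s <- numeric(ng)
  if (length(valid)) {
    agg <- rowsum(abs(lev - abar), lev)
    s[as.integer(rownames(agg))] <- agg[, 1]
  }
  nv <- length(valid)
  list(n = n, p = if (nv > 0) n / nv else n, s = s, n_valid = nv)
}

#' NGTDM features (5)
#'
#' Coarseness, contrast, busyness, complexity and strength from the
#' neighbourhood grey-tone difference table.  A zero coarseness
#' denominator (perfectly uniform ROI) is mapped to coarseness `1e6`; an
#' ROI in which no voxel has a neighbour gives all five features 0.
#'
#' @param droi a [discretise()] result.
#' @return named numeric vector of 5 features.
#' @export
ngtdm_features <- function(droi) {
  tb <- ngtdm_table(droi)
  nm <- paste0(c("Coarseness", "Contrast", "Busyness", "Complexity",
                 "Strength"), "_NGTDM")
  if (tb$n_valid == 0) {
    out <- stats::setNames(numeric(5), nm)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ng <- length(tb$n)
  p <- tb$p; s <- tb$s; nv <- tb$n_valid
  act <- which(p > 0)
  ngp <- length(act)
  ps <- sum(p * s)
  coarseness <- if (ps > 0) 1 / ps else 1e6
  if (ngp > 1) {
    ii <- rep(act, each = ngp); jj <- rep(act, ngp)
    pij <- p[ii] * p[jj]
    contrast <- sum(pij * (ii - jj)^2) / (ngp * (ngp - 1)) * sum(s) / nv
    busy_den <- sum(abs(ii * p[ii] - jj * p[jj]))
    busyness <- if (busy_den > 0) ps / busy_den else 0
    complexity <- sum(abs(ii - jj) * (p[ii] * s[ii] + p[jj] * s[jj]) /
                        (p[ii] + p[jj])) / nv
    strength_den <- sum(s)
    strength <- if (strength_den > 0)
      sum((p[ii] + p[jj]) * (ii - jj)^2) / strength_den else 0
  } else {
    contrast <- 0; busyness <- 0; complexity <- 0; strength <- 0
  }
  stats::setNames(c(coarseness, contrast, busyness, complexity, strength),
                  nm)
}

#' Grey-level size-zone table
#'
#' Zones are 26-connected components of equal grey level within the mask.
#'
#' @param droi a [discretise()] result.
#' @return matrix `m[i, s]`: number of zones of level i and size s.
#' @export
glszm_table <- function(droi) {
  stopifnot(inherits(droi, "discretised_roi"))
  lv <- droi$levels
  d <- dim(lv)
  ng <- droi$ng
  inmask <- which(!is.na(lv))
  rank <- integer(length(lv))
  rank[inmask] <- seq_along(inmask)
  offs <- grid_offsets_13()
  efrom <- integer(0); eto <- integer(0)
  for (r in seq_len(nrow(offs))) {
    pr <- offset_pairs(d, offs[r, ])
    if (!nrow(pr)) next
    a <- pr[, 1]; b <- pr[, 2]
    ok <- !is.na(lv[a]) & !is.na(lv[b]) & lv[a] == lv[b]
    if (!any(ok)) next
    efrom <- c(efrom, rank[a[ok]]); eto <- c(eto, rank[b[ok]])
  }
  g <- igraph::make_graph(as.vector(rbind(efrom, eto)),
                          n = length(inmask), directed = FALSE)
  comp <- igraph::components(g)
  # one row per zone: its level and size
  zl <- lv[inmask][match(seq_along(comp$csize), comp$membership)]
  zs <- comp$csize
  smax <- max(zs)
  m <- matrix(0, ng, smax)
  cnt <- tabulate(zl + ng * (zs - 1L), ng * smax)
  m[] <- cnt
  m
}

#' GLSZM features (11)
#'
#' Small/large-zone emphases, low/high grey-level zone emphases and their
#' crosses, grey-level and zone-size non-uniformity, and zone percentage
#' (`Nz / Np`).
#'
#' @param droi a [discretise()] result.
#' @return named numeric vector of 11 features.
#' @export
glszm_features <- function(droi) {
  m <- glszm_table(droi)
  nz <- sum(m)
  np <- sum(droi$mask)
  ngl <- nrow(m); smax <- ncol(m)
  i <- matrix(seq_len(ngl), ngl, smax)
  s <- matrix(seq_len(smax), ngl, smax, byrow = TRUE)
  zi <- rowSums(m); zsz <- colSums(m)
  out <- c(
    Small_Zone_Emphasis_GLSZM = sum(m / s^2) / nz,
    Large_Zone_Emphasis_GLSZM = sum(m * s^2) / nz,
    Low_Grey_Level_Zone_Emphasis_GLSZM = sum(m / i^2) / nz,
    High_Grey_Level_Zone_Emphasis_GLSZM = sum(m * i^2) / nz,
    Small_Zone_Low_Grey_Level_Emphasis_GLSZM = sum(m / (i^2 * s^2)) / nz,
    Small_Zone_High_Grey_Level_Emphasis_GLSZM = sum(m * i^2 / s^2) / nz,
    Large_Zone_Low_Grey_Level_Emphasis_GLSZM = sum(m * s^2 / i^2) / nz,
    Large_Zone_High_Grey_Level_Emphasis_GLSZM = sum(m * i^2 * s^2) / nz,
    Grey_Level_Non_Uniformity_GLSZM = sum(zi^2) / nz,
    Zone_Size_Non_Uniformity_GLSZM = sum(zsz^2) / nz,
    Zone_percentage_GLSZM = nz / np
  )
  out
}
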