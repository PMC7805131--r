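# Brute-force enumeration oracles for the texture families and survival
# statistics.  Everything here is written as plain nested loops, directly
# from the definitions, independently of the vectorised package code.

offsets13 <- ibmscore:::grid_offsets_13()

# Build a discretised_roi directly from an integer array (NA = outside).
droi_from_levels <- function(lv, spacing = c(1, 1, 1)) {
  mask <- !is.na(lv)
  ng <- max(lv, na.rm = TRUE)
  structure(list(levels = lv, mask = mask, ng = ng,
                 raw = as.numeric(lv[mask]), spacing_mm = spacing,
                 scheme = "fixed_bin_number", parameter = ng),
            class = "discretised_roi")
}

random_droi <- function(seed, dmax = 6, ng = 4, p_in = 0.75) {
  set.seed(seed)
  d <- sample(2:dmax, 3, replace = TRUE)
  lv <- array(sample.int(ng, prod(d), replace = TRUE), d)
  mask <- array(stats::runif(prod(d)) < p_in, d)
  if (sum(mask) < 2) mask[1:2] <- TRUE
  lv[!mask] <- NA_integer_
  droi_from_levels(lv)
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

oracle_glcm_matrix <- function(droi, offsets = offsets13) {
  lv <- droi$levels; d <- dim(lv); ng <- droi$ng
  cnt <- matrix(0, ng, ng)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    for (r in seq_len(nrow(offsets))) for (sgn in c(1, -1)) {
      p <- c(x, y, z) + sgn * offsets[r, ]
      if (!in_grid(p, d)) next
      b <- lv[p[1], p[2], p[3]]
      if (is.na(b)) next
      cnt[a, b] <- cnt[a, b] + 1
    }
  }
  if (sum(cnt) > 0) cnt / sum(cnt) else cnt
}

oracle_glcm_features <- function(droi, offsets = offsets13) {
  p <- oracle_glcm_matrix(droi, offsets)
  ng <- nrow(p)
  mu <- 0; for (i in 1:ng) for (j in 1:ng) mu <- mu + i * p[i, j]
  sig2 <- 0; for (i in 1:ng) for (j in 1:ng) sig2 <- sig2 + (i - mu)^2 * p[i, j]
  acc <- function(f) {
    s <- 0
    for (i in 1:ng) for (j in 1:ng) s <- s + f(i, j, p[i, j])
    s
  }
  jent <- acc(function(i, j, q) if (q > 0) -q * log2(q) else 0)
  psum <- numeric(2 * ng); pdif <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p[i, j]
  }
  hent <- function(v) { s <- 0; for (q in v) if (q > 0) s <- s - q * log2(q); s }
  sum_avg <- 0; for (k in 2:(2 * ng)) sum_avg <- sum_avg + k * psum[k]
  c(Maximum_Probability_GLCM = max(p),
    Joint_Average_GLCM = mu,
    Sum_of_Square_Variance_GLCM = sig2,
    Joint_Entropy_GLCM = jent,
    Angular_Second_Moment_GLCM = acc(function(i, j, q) q^2),
    Contrast_GLCM = acc(function(i, j, q) (i - j)^2 * q),
    Dissimilarity_GLCM = acc(function(i, j, q) abs(i - j) * q),
    Inverse_Difference_GLCM = acc(function(i, j, q) q / (1 + abs(i - j))),
    Inverse_Difference_Normalised_GLCM =
      acc(function(i, j, q) q / (1 + abs(i - j) / ng)),
    Inverse_Difference_Moment_GLCM =
      acc(function(i, j, q) q / (1 + (i - j)^2)),
    Inverse_Difference_Moment_Normalised_GLCM =
      acc(function(i, j, q) q / (1 + (i - j)^2 / ng^2)),
    Inverse_Variance_GLCM =
      acc(function(i, j, q) if (i != j) q / (i - j)^2 else 0),
    Correlation_GLCM = if (sig2 > 0)
      (acc(function(i, j, q) i * j * q) - mu^2) / sig2 else 1,
    Autocorrelation_GLCM = acc(function(i, j, q) i * j * q),
    Cluster_Tendency_GLCM = acc(function(i, j, q) (i + j - 2 * mu)^2 * q),
    Cluster_Shade_GLCM = acc(function(i, j, q) (i + j - 2 * mu)^3 * q),
    Cluster_Prominence_GLCM = acc(function(i, j, q) (i + j - 2 * mu)^4 * q),
    Sum_Average_GLCM = sum_avg,
    Sum_Entropy_GLCM = hent(psum),
    Difference_Entropy_GLCM = hent(pdif))
}

oracle_glrlm_matrix <- function(droi, offsets = offsets13) {
  lv <- droi$levels; d <- dim(lv); ng <- droi$ng
  runs_lv <- integer(0); runs_len <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    dir <- offsets[r, ]
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      v <- c(x, y, z)
      a <- lv[x, y, z]
      if (is.na(a)) next
      prev <- v - dir
      if (in_grid(prev, d) && !is.na(lv[prev[1], prev[2], prev[3]]) &&
          lv[prev[1], prev[2], prev[3]] == a) next  # not a run start
      len <- 1L
      nxt <- v + dir
      while (in_grid(nxt, d) && !is.na(lv[nxt[1], nxt[2], nxt[3]]) &&
             lv[nxt[1], nxt[2], nxt[3]] == a) {
        len <- len + 1L
        nxt <- nxt + dir
      }
      runs_lv <- c(runs_lv, a); runs_len <- c(runs_len, len)
    }
  }
  m <- matrix(0, ng, max(runs_len))
  for (k in seq_along(runs_lv))
    m[runs_lv[k], runs_len[k]] <- m[runs_lv[k], runs_len[k]] + 1
  m
}

oracle_glrlm_features <- function(droi, offsets = offsets13) {
  m <- oracle_glrlm_matrix(droi, offsets)
  nr <- sum(m); ng <- nrow(m); lmax <- ncol(m)
  np <- sum(droi$mask) * nrow(offsets)
  acc <- function(f) {
    s <- 0
    for (i in 1:ng) for (l in 1:lmax) s <- s + f(i, l, m[i, l])
    s
  }
  mu_i <- acc(function(i, l, q) i * q / nr)
  mu_l <- acc(function(i, l, q) l * q / nr)
  ri <- numeric(ng); rl <- numeric(lmax)
  for (i in 1:ng) for (l in 1:lmax) {
    ri[i] <- ri[i] + m[i, l]; rl[l] <- rl[l] + m[i, l]
  }
  c(Short_Run_Emphasis_GLRLM = acc(function(i, l, q) q / l^2) / nr,
    Long_Run_Emphasis_GLRLM = acc(function(i, l, q) q * l^2) / nr,
    Low_Grey_Level_Run_Emphasis_GLRLM = acc(function(i, l, q) q / i^2) / nr,
    High_Grey_Level_Run_Emphasis_GLRLM = acc(function(i, l, q) q * i^2) / nr,
    Short_Run_Low_Grey_Level_Emphasis_GLRLM =
      acc(function(i, l, q) q / (i^2 * l^2)) / nr,
    Short_Run_High_Grey_Level_Emphasis_GLRLM =
      acc(function(i, l, q) q * i^2 / l^2) / nr,
    Long_Run_Low_Grey_Level_Emphasis_GLRLM =
      acc(function(i, l, q) q * l^2 / i^2) / nr,
    Long_Run_High_Grey_Level_Emphasis_GLRLM =
      acc(function(i, l, q) q * i^2 * l^2) / nr,
    Grey_Level_Non_Uniformity_GLRLM = sum(ri^2) / nr,
    Grey_Level_Non_Uniformity_Normalised_GLRLM = sum(ri^2) / nr^2,
    Run_Length_Non_Uniformity_GLRLM = sum(rl^2) / nr,
    Run_Length_Non_Uniformity_Normalised_GLRLM = sum(rl^2) / nr^2,
    Run_Percentage_GLRLM = nr / np,
    Grey_Level_Variance_GLRLM = acc(function(i, l, q) (i - mu_i)^2 * q / nr),
    Run_Length_Variance_GLRLM = acc(function(i, l, q) (l - mu_l)^2 * q / nr),
    Run_Entropy_GLRLM = acc(function(i, l, q)
      if (q > 0) -(q / nr) * log2(q / nr) else 0))
}

# all 26 neighbour offsets
offsets26 <- rbind(offsets13, -offsets13)

oracle_ngtdm_features <- function(droi) {
  lv <- droi$levels; d <- dim(lv); ng <- droi$ng
  n <- numeric(ng); s <- numeric(ng); nvalid <- 0
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    a <- lv[x, y, z]
    if (is.na(a)) next
    nb <- c()
    for (r in seq_len(nrow(offsets26))) {
      p <- c(x, y, z) + offsets26[r, ]
      if (!in_grid(p, d)) next
      b <- lv[p[1], p[2], p[3]]
      if (!is.na(b)) nb <- c(nb, b)
    }
    if (!length(nb)) next
    nvalid <- nvalid + 1
    n[a] <- n[a] + 1
    s[a] <- s[a] + abs(a - mean(nb))
  }
  nm <- paste0(c("Coarseness", "Contrast", "Busyness", "Complexity",
                 "Strength"), "_NGTDM")
  if (nvalid == 0) return(setNames(numeric(5), nm))
  p <- n / nvalid
  act <- which(p > 0); ngp <- length(act)
  ps <- sum(p * s)
  coarse <- if (ps > 0) 1 / ps else 1e6
  contrast <- 0; busy_den <- 0; complexity <- 0; strength_num <- 0
  if (ngp > 1) {
    for (i in act) for (j in act) {
      contrast <- contrast + p[i] * p[j] * (i - j)^2
      busy_den <- busy_den + abs(i * p[i] - j * p[j])
      complexity <- complexity +
        abs(i - j) * (p[i] * s[i] + p[j] * s[j]) / (p[i] + p[j])
      strength_num <- strength_num + (p[i] + p[j]) * (i - j)^2
    }
    contrast <- contrast / (ngp * (ngp - 1)) * sum(s) / nvalid
    complexity <- complexity / nvalid
  }
  busy <- if (ngp > 1 && busy_den > 0) ps / busy_den else 0
  strength <- if (ngp > 1 && sum(s) > 0) strength_num / sum(s) else 0
  setNames(c(coarse, contrast, busy, complexity, strength), nm)
}

# flood-fill zones of equal level under 26-connectivity
oracle_glszm_matrix <- function(droi) {
  lv <- droi$levels; d <- dim(lv); ng <- droi$ng
  seen <- array(FALSE, d)
  zones_lv <- integer(0); zones_sz <- integer(0)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (seen[x, y, z] || is.na(lv[x, y, z])) next
    a <- lv[x, y, z]
    stack <- list(c(x, y, z)); seen[x, y, z] <- TRUE; size <- 0
    while (length(stack)) {
      v <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (r in seq_len(nrow(offsets26))) {
        p <- v + offsets26[r, ]
        if (!in_grid(p, d)) next
        if (seen[p[1], p[2], p[3]]) next
        b <- lv[p[1], p[2], p[3]]
        if (!is.na(b) && b == a) {
          seen[p[1], p[2], p[3]] <- TRUE
          stack[[length(stack) + 1]] <- p
        }
      }
    }
    zones_lv <- c(zones_lv, a); zones_sz <- c(zones_sz, size)
  }
  m <- matrix(0, ng, max(zones_sz))
  for (k in seq_along(zones_lv))
    m[zones_lv[k], zones_sz[k]] <- m[zones_lv[k], zones_sz[k]] + 1
  m
}

oracle_glszm_features <- function(droi) {
  m <- oracle_glszm_matrix(droi)
  nz <- sum(m); np <- sum(droi$mask)
  ng <- nrow(m); smax <- ncol(m)
  acc <- function(f) {
    t <- 0
    for (i in 1:ng) for (s in 1:smax) t <- t + f(i, s, m[i, s])
    t
  }
  zi <- numeric(ng); zs <- numeric(smax)
  for (i in 1:ng) for (s in 1:smax) {
    zi[i] <- zi[i] + m[i, s]; zs[s] <- zs[s] + m[i, s]
  }
  c(Small_Zone_Emphasis_GLSZM = acc(function(i, s, q) q / s^2) / nz,
    Large_Zone_Emphasis_GLSZM = acc(function(i, s, q) q * s^2) / nz,
    Low_Grey_Level_Zone_Emphasis_GLSZM = acc(function(i, s, q) q / i^2) / nz,
    High_Grey_Level_Zone_Emphasis_GLSZM = acc(function(i, s, q) q * i^2) / nz,
    Small_Zone_Low_Grey_Level_Emphasis_GLSZM =
      acc(function(i, s, q) q / (i^2 * s^2)) / nz,
    Small_Zone_High_Grey_Level_Emphasis_GLSZM =
      acc(function(i, s, q) q * i^2 / s^2) / nz,
    Large_Zone_Low_Grey_Level_Emphasis_GLSZM =
      acc(function(i, s, q) q * s^2 / i^2) / nz,
    Large_Zone_High_Grey_Level_Emphasis_GLSZM =
      acc(function(i, s, q) q * i^2 * s^2) / nz,
    Grey_Level_Non_Uniformity_GLSZM = sum(zi^2) / nz,
    Zone_Size_Non_Uniformity_GLSZM = sum(zs^2) / nz,
    Zone_percentage_GLSZM = nz / np)
}

# loop-based Harrell concordance, the oracle for the vectorised version
oracle_cindex <- function(scores, time, event) {
  n <- length(scores)
  conc <- 0; usable <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (time[i] == time[j]) {
      # tied times: usable only for an event/censored pair (event first)
      if (event[i] + event[j] == 1) {
        usable <- usable + 1
        ev <- if (event[i] == 1) i else j
        ot <- if (ev == i) j else i
        conc <- conc + if (scores[ev] > scores[ot]) 1 else
          if (scores[ev] == scores[ot]) 0.5 else 0
      }
      next
    }
    first <- if (time[i] < time[j]) i else j
    other <- if (first == i) j else i
    if (event[first] != 1) next
    usable <- usable + 1
    conc <- conc + if (scores[first] > scores[other]) 1 else
      if (scores[first] == scores[other]) 0.5 else 0
  }
  conc / usable
}
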