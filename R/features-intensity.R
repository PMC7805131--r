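#' First-order intensity features (24)
#'
#' Statistics of the raw in-mask intensity distribution.  All moments are
#' population moments (denominator n); kurtosis is excess kurtosis.
#' `Histogram_Entropy` (bits), `Uniformity` and `Mode` are computed on the
#' discretised histogram (default: fixed bin number 32 on in-mask values);
#' everything else uses raw intensities.  Percentile features use R's
#' default (type 7) quantile.
#'
#' Degenerate ROIs (a single voxel, or all voxels equal) give 0 for the
#' dispersion, skewness and kurtosis features rather than failing; the
#' returned vector then carries a `degenerate` attribute.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()].
#' @param droi optional [discretise()] result to reuse; otherwise computed
#'   with the default scheme.
#' @return named numeric vector of 24 features.
#' @export
intensity_features <- function(volume, mask, droi = NULL) {
  validate_pair(volume, mask)
  if (is.null(droi)) droi <- discretise(volume, mask)
  v <- volume$values[mask$indicator]
  n <- length(v)
  m <- mean(v)
  dev <- v - m
  m2 <- mean(dev^2)
  sdev <- sqrt(m2)
  degenerate <- n < 2 || m2 == 0
  skew <- if (degenerate) 0 else mean(dev^3) / m2^1.5
  kurt <- if (degenerate) 0 else mean(dev^4) / m2^2 - 3

  q <- stats::quantile(v, c(0.025, 0.10, 0.25, 0.5, 0.75, 0.90, 0.975),
                       names = FALSE)
  med <- q[4]
  trunc_v <- v[v >= q[2] & v <= q[6]]
  rmad <- if (length(trunc_v)) mean(abs(trunc_v - mean(trunc_v))) else 0

  # histogram-based members on the discretised levels
  counts <- tabulate(droi$levels[droi$mask], nbins = droi$ng)
  p <- counts / sum(counts)
  pos <- p > 0
  entropy <- -sum(p[pos] * log2(p[pos]))
  uniformity <- sum(p^2)
  mode_level <- which.max(counts)
  # map the modal bin back to an intensity: bin-centre on the raw range
  lo <- min(v); hi <- max(v)
  mode_val <- if (droi$ng == 1L) m else
    lo + (mode_level - 0.5) * (hi - lo) / droi$ng

  iqr <- q[5] - q[3]
  out <- c(
    Minimum = lo,
    Maximum = hi,
    Range = hi - lo,
    Mean = m,
    Median = med,
    Mode = mode_val,
    Variance = m2,
    Standard_Deviation = sdev,
    Skewness = skew,
    Kurtosis = kurt,
    Energy = sum(v^2),
    Root_Mean_Square = sqrt(mean(v^2)),
    Mean_Absolute_Deviation = mean(abs(dev)),
    Robust_Mean_Absolute_Deviation = rmad,
    Median_Absolute_Deviation = stats::median(abs(v - med)),
    Coefficient_of_Variation = if (m == 0) 0 else sdev / m,
    Histogram_Entropy = entropy,
    Uniformity = uniformity,
    Q025 = q[1],
    Q25 = q[3],
    Q75 = q[5],
    Q975 = q[7],
    Interquartile_Range = iqr,
    Quartile_Coefficient_of_Dispersion =
      if (q[5] + q[3] == 0) 0 else iqr / (q[5] + q[3])
  )
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}
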