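#' Discretise in-mask intensities to integer grey levels
#'
#' Texture matrices require integer grey levels 1..Ng.  Two schemes are
#' provided, computed on in-mask intensities only:
#' \describe{
#'   \item{fixed_bin_number}{`level = 1 + floor(N * (v - min) / (max - min))`
#'     with the top value clipped into bin N; a constant ROI gets Ng = 1.}
#'   \item{fixed_bin_width}{`level = 1 + floor((v - min) / w)`.}
#' }
#' The default (fixed bin number, N = 32) is stable across the intensity
#' ranges produced by the synthetic generator.
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()].
#' @param scheme `"fixed_bin_number"` or `"fixed_bin_width"`.
#' @param value bin count N (positive integer) or bin width w (> 0).
#' @return A `discretised_roi`: list with `levels` (integer 3D array, NA
#'   outside the mask), `mask` (logical array), `ng`, `spacing_mm`, and the
#'   scheme used.  A vector of in-mask raw values is kept in `raw` for the
#'   histogram-based intensity features.
#' @export
discretise <- function(volume, mask,
                       scheme = c("fixed_bin_number", "fixed_bin_width"),
                       value = 32) {
  scheme <- match.arg(scheme)
  validate_pair(volume, mask)
  if (!is.finite(value) || value <= 0)
    stop("discretisation parameter must be positive, got ", value)
  v <- volume$values[mask$indicator]
  lo <- min(v); hi <- max(v)
  lev <- integer(length(v))
  if (scheme == "fixed_bin_number") {
    n <- as.integer(value)
    if (n < 1) stop("bin number must be >= 1")
    if (hi == lo) {
      lev[] <- 1L
    } else {
      lev <- 1L + as.integer(floor(n * (v - lo) / (hi - lo)))
      lev[lev > n] <- n
    }
  } else {
    lev <- 1L + as.integer(floor((v - lo) / value))
  }
  grid <- array(NA_integer_, dim(mask$indicator))
  grid[mask$indicator] <- lev
  structure(list(levels = grid, mask = mask$indicator,
                 ng = max(lev), raw = v,
                 spacing_mm = mask$spacing_mm,
                 scheme = scheme, parameter = value),
            class = "discretised_roi")
}

#' @export
print.discretised_roi <- function(x, ...) {
  cat("discretised_roi:", sum(x$mask), "voxels,", x$ng, "grey levels (",
      x$scheme, "=", x$parameter, ")\n")
  invisible(x)
}
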