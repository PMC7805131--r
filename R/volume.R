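#' Construct a 3D image volume
#'
#' An `image_volume` couples a 3D scalar grid with its physical geometry:
#' voxel spacing in millimetres and the world position of the first voxel
#' centre.  Grids are indexed `[x, y, z]` (1-based in R); the world position
#' of voxel `(i, j, k)` is `origin + (i - 1, j - 1, k - 1) * spacing`.
#' No resampling is ever applied: features are computed on the native grid
#' and use physical units wherever geometry matters, matching extraction
#' from planning CTs acquired at different slice thicknesses (typically
#' 1.0 x 1.0 x 3.0 or 1.0 x 1.0 x 5.0 mm).
#'
#' @param values 3D numeric array of voxel values (e.g. HU).
#' @param spacing_mm numeric length-3, voxel spacing in mm, all > 0.
#' @param origin_mm numeric length-3, world coordinate of the first voxel
#'   centre in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(values, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array, got ",
         paste(dim(values), collapse = "x"))
  if (length(values) == 0L) stop("`values` must be non-empty")
  if (!all(is.finite(values))) stop("`values` must be finite throughout")
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive finite numbers")
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be three finite numbers")
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "image_volume")
}

#' Construct a binary region-of-interest mask
#'
#' The mask shares its grid, spacing and origin with a paired
#' [image_volume()]; any nonzero value in `indicator` counts as inside the
#' region.  A mask must contain at least one voxel.
#'
#' @param indicator 3D array (logical or numeric); nonzero means inside.
#' @param spacing_mm,origin_mm geometry, as for [image_volume()].
#' @return An object of class `roi_mask` whose `indicator` is logical.
#' @export
roi_mask <- function(indicator, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(indicator) || length(dim(indicator)) != 3L)
    stop("`indicator` must be a 3D array")
  ind <- indicator != 0
  if (!any(ind)) stop("mask is empty: no voxel is inside the ROI")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive numbers")
  structure(list(indicator = ind, spacing_mm = spacing_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "roi_mask")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume:", paste(dim(x$values), collapse = " x "),
      "voxels, spacing", paste(format(x$spacing_mm), collapse = " x "),
      "mm\n")
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("roi_mask:", sum(x$indicator), "of", length(x$indicator),
      "voxels inside, spacing",
      paste(format(x$spacing_mm), collapse = " x "), "mm\n")
  invisible(x)
}

#' Check that a mask is geometrically consistent with a volume
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()].
#' @param tol_mm spacing/origin agreement tolerance in mm.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_pair <- function(volume, mask, tol_mm = 1e-3) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "roi_mask"))
  if (!identical(dim(volume$values), dim(mask$indicator)))
    stop("mask shape (", paste(dim(mask$indicator), collapse = "x"),
         ") does not match volume shape (",
         paste(dim(volume$values), collapse = "x"), ")")
  if (any(abs(volume$spacing_mm - mask$spacing_mm) > tol_mm))
    stop("mask spacing (", paste(mask$spacing_mm, collapse = ", "),
         " mm) does not match volume spacing (",
         paste(volume$spacing_mm, collapse = ", "), " mm)")
  if (any(abs(volume$origin_mm - mask$origin_mm) > tol_mm))
    stop("mask origin does not match volume origin")
  invisible(TRUE)
}

#' Read a 3D volume from a NIfTI file
#'
#' Spacing is taken from the header `pixdim`; the origin is the translation
#' column of the stored transform.  Values are returned in native scalar
#' units; no resampling or reorientation is performed.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("cannot read volume: file does not exist: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot parse NIfTI file ", path, ": ",
                         conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume in ", path, " but found a ",
         length(d), "D grid (", paste(d, collapse = "x"), ")")
  xf <- RNifti::xform(img)
  image_volume(array(as.numeric(img), d),
               spacing_mm = abs(RNifti::pixdim(img)[1:3]),
               origin_mm = xf[1:3, 4])
}

#' Write a volume (or mask) to NIfTI
#'
#' @param volume an [image_volume()] or [roi_mask()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "roi_mask"))
    volume <- image_volume(array(as.numeric(volume$indicator),
                                 dim(volume$indicator)),
                           volume$spacing_mm, volume$origin_mm)
  stopifnot(inherits(volume, "image_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing_mm
  m <- diag(c(volume$spacing_mm, 1))
  m[1:3, 4] <- volume$origin_mm
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ROI mask from NIfTI and validate it against a volume
#'
#' Any nonzero label counts as inside.  Shape, spacing and origin must
#' agree with `volume` (tolerance `tol_mm`); an empty mask is rejected.
#'
#' @param path path to the mask file.
#' @param volume the paired [image_volume()].
#' @param tol_mm geometric agreement tolerance in mm.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path, volume, tol_mm = 1e-3) {
  raw <- read_volume(path)
  if (!any(raw$values != 0))
    stop("mask in ", path, " is empty (no nonzero voxel)")
  m <- roi_mask(raw$values != 0, raw$spacing_mm, raw$origin_mm)
  validate_pair(volume, m, tol_mm = tol_mm)
  m
}
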