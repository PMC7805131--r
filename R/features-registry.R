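#' The 96-feature registry
#'
#' Data-driven list of every imaging biomarker the extractor produces, in
#' its stable output order: 24 intensity, 20 geometric and 52 texture
#' features (GLCM 20, GLRLM 16, NGTDM 5, GLSZM 11).  The family census is
#' asserted every time the registry is built, so a miscounted catalogue
#' fails immediately rather than producing a short feature vector.
#'
#' @return data.frame with columns `name` and `family`
#'   (intensity/geometric/GLCM/GLRLM/NGTDM/GLSZM).
#' @export
feature_registry <- function() {
  intensity <- c("Minimum", "Maximum", "Range", "Mean", "Median", "Mode",
                 "Variance", "Standard_Deviation", "Skewness", "Kurtosis",
                 "Energy", "Root_Mean_Square", "Mean_Absolute_Deviation",
                 "Robust_Mean_Absolute_Deviation",
                 "Median_Absolute_Deviation", "Coefficient_of_Variation",
                 "Histogram_Entropy", "Uniformity", "Q025", "Q25", "Q75",
                 "Q975", "Interquartile_Range",
                 "Quartile_Coefficient_of_Dispersion")
  geometric <- c("Voxel_Count", "Volume", "Surface_Area",
                 "Surface_to_Volume_Ratio", "Sphericity", "Compactness_1",
                 "Compactness_2", "Spherical_Disproportion", "Asphericity",
                 "Major_axis_length", "Minor_axis_length",
                 "Least_axis_length", "Elongation", "Flatness",
                 "Maximum_3D_Diameter", "Volume_Density", "Area_Density",
                 "Volume_Density_AEE", "Centre_of_Mass_Shift",
                 "Integrated_Intensity")
  glcm <- paste0(c("Maximum_Probability", "Joint_Average",
                   "Sum_of_Square_Variance", "Joint_Entropy",
                   "Angular_Second_Moment", "Contrast", "Dissimilarity",
                   "Inverse_Difference", "Inverse_Difference_Normalised",
                   "Inverse_Difference_Moment",
                   "Inverse_Difference_Moment_Normalised",
                   "Inverse_Variance", "Correlation", "Autocorrelation",
                   "Cluster_Tendency", "Cluster_Shade",
                   "Cluster_Prominence", "Sum_Average", "Sum_Entropy",
                   "Difference_Entropy"), "_GLCM")
  glrlm <- paste0(c("Short_Run_Emphasis", "Long_Run_Emphasis",
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
  ngtdm <- paste0(c("Coarseness", "Contrast", "Busyness", "Complexity",
                    "Strength"), "_NGTDM")
  glszm <- c("Small_Zone_Emphasis_GLSZM", "Large_Zone_Emphasis_GLSZM",
             "Low_Grey_Level_Zone_Emphasis_GLSZM",
             "High_Grey_Level_Zone_Emphasis_GLSZM",
             "Small_Zone_Low_Grey_Level_Emphasis_GLSZM",
             "Small_Zone_High_Grey_Level_Emphasis_GLSZM",
             "Large_Zone_Low_Grey_Level_Emphasis_GLSZM",
             "Large_Zone_High_Grey_Level_Emphasis_GLSZM",
             "Grey_Level_Non_Uniformity_GLSZM",
             "Zone_Size_Non_Uniformity_GLSZM", "Zone_percentage_GLSZM")
  census <- c(intensity = 24L, geometric = 20L, GLCM = 20L, GLRLM = 16L,
              NGTDM = 5L, GLSZM = 11L)
  got <- c(length(intensity), length(geometric), length(glcm),
           length(glrlm), length(ngtdm), length(glszm))
  stopifnot(identical(unname(census), got), sum(got) == 96L)
  data.frame(
    name = c(intensity, geometric, glcm, glrlm, ngtdm, glszm),
    family = rep(names(census), census),
    stringsAsFactors = FALSE
  )
}

#' Extract all 96 imaging biomarkers for one volume/mask pair
#'
#' Runs the full feature stack on the native grid: intensity statistics on
#' raw in-mask values, geometry in physical units, and the four texture
#' families on the discretised ROI.  The output order follows
#' [feature_registry()] and is identical for every patient; extraction is
#' deterministic and depends only on in-mask voxels (the background value
#' never enters any feature).
#'
#' @param volume an [image_volume()].
#' @param mask an [roi_mask()].
#' @param scheme,value discretisation scheme and parameter, see
#'   [discretise()].
#' @return named numeric vector of exactly 96 finite features.
#' @export
extract_all <- function(volume, mask, scheme = "fixed_bin_number",
                        value = 32) {
  validate_pair(volume, mask)
  droi <- discretise(volume, mask, scheme = scheme, value = value)
  out <- c(intensity_features(volume, mask, droi),
           geometric_features(mask, volume),
           glcm_features(droi),
           glrlm_features(droi),
           ngtdm_features(droi),
           glszm_features(droi))
  reg <- feature_registry()
  if (!identical(names(out), reg$name))
    stop("feature extraction produced a vector inconsistent with the ",
         "registry: got ", length(out), " features")
  bad <- !is.finite(out)
  if (any(bad))
    stop("non-finite feature value(s): ",
         paste(names(out)[bad], collapse = ", "))
  out
}

#' Batch feature extraction over a cohort
#'
#' @param patients list of `list(volume=, mask=)` pairs, e.g. the
#'   `patients` element of [generate_cohort()].
#' @param ids optional character vector of patient ids.
#' @param ... passed to [extract_all()].
#' @return data.frame: `patient_id` plus 96 feature columns.
#' @export
extract_cohort <- function(patients, ids = NULL, ...) {
  if (is.null(ids)) ids <- sprintf("P%04d", seq_along(patients))
  feats <- t(vapply(patients,
                    function(p) extract_all(p$volume, p$mask, ...),
                    numeric(96L)))
  out <- data.frame(patient_id = ids, feats, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
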