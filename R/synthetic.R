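#' Parameters of a synthetic CT tumour phantom
#'
#' Describes an ellipsoidal tumour embedded in a CT-like grid: semi-axes in
#' mm, a mean enhancement level (HU-like), additive Gaussian texture noise
#' with a tunable spatial correlation length, and anisotropic voxel spacing
#' as on planning CTs (e.g. 1.0 x 1.0 x 3.0 mm).
#'
#' The noise field is stationary: white Gaussian noise convolved with a
#' Gaussian kernel of physical width `smoothing_sigma_mm`, then rescaled so
#' its marginal standard deviation is `noise_sd` regardless of the
#' correlation length.  `smoothing_sigma_mm` therefore controls texture
#' coarseness only, which is what the NGTDM family is meant to detect.
#'
#' @param semi_axes_mm three positive ellipsoid semi-axes (mm); each must be
#'   at least twice the largest voxel spacing so the mask is non-degenerate.
#' @param mean_intensity mean in-mask value (HU-like scalar).
#' @param noise_sd standard deviation of the in-mask noise field (>= 0).
#' @param smoothing_sigma_mm Gaussian correlation length of the noise in mm
#'   (>= 0; 0 gives white noise).
#' @param spacing_mm three positive voxel spacings in mm.
#' @param background constant value outside the mask.
#' @return A `tumour_params` object.
#' @export
tumour_params <- function(semi_axes_mm, mean_intensity = 60,
                          noise_sd = 10, smoothing_sigma_mm = 1.5,
                          spacing_mm = c(1, 1, 3), background = -50) {
  semi_axes_mm <- as.numeric(semi_axes_mm)
  spacing_mm <- as.numeric(spacing_mm)
  if (length(semi_axes_mm) != 3L || any(!is.finite(semi_axes_mm)) ||
      any(semi_axes_mm <= 0))
    stop("`semi_axes_mm` must be three positive lengths")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive spacings")
  if (any(semi_axes_mm < 2 * max(spacing_mm)))
    stop("degenerate tumour: every semi-axis must be at least twice the ",
         "largest voxel spacing (got semi-axes ",
         paste(semi_axes_mm, collapse = ", "), " mm at spacing ",
         paste(spacing_mm, collapse = ", "), " mm)")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (!is.finite(smoothing_sigma_mm) || smoothing_sigma_mm < 0)
    stop("`smoothing_sigma_mm` must be >= 0")
  structure(list(semi_axes_mm = semi_axes_mm,
                 mean_intensity = as.numeric(mean_intensity),
                 noise_sd = as.numeric(noise_sd),
                 smoothing_sigma_mm = as.numeric(smoothing_sigma_mm),
                 spacing_mm = spacing_mm,
                 background = as.numeric(background)),
            class = "tumour_params")
}

#' Generate one synthetic tumour volume and its ROI mask
#'
#' The mask is the discretised ellipsoid in physical coordinates (a voxel is
#' inside iff its centre satisfies the ellipsoid inequality).  In-mask
#' values are `mean_intensity` plus the correlated noise field; the
#' background is a distinct constant.  The same seed reproduces the output
#' bit for bit; the mask itself is noise-free, so it does not depend on the
#' seed.
#'
#' @param params a [tumour_params()] object.
#' @param seed integer RNG seed.
#' @param margin_voxels empty voxels padded around the ellipsoid.
#' @return list with `volume` ([image_volume()]), `mask` ([roi_mask()]) and
#'   `truth` (the input `params`).
#' @export
generate_tumour <- function(params, seed = 1L, margin_voxels = 2L) {
  stopifnot(inherits(params, "tumour_params"))
  sp <- params$spacing_mm
  half_n <- ceiling(params$semi_axes_mm / sp) + margin_voxels
  dims <- 2L * half_n + 1L
  centre <- half_n * sp  # world coord of grid centre, origin at voxel 1
  ax <- lapply(1:3, function(a) ((seq_len(dims[a]) - 1) * sp[a] - centre[a]) /
                 params$semi_axes_mm[a])
  q <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  inside <- q <= 1
  if (!any(inside))
    stop("degenerate axes: the discretised ellipsoid contains no voxel")

  vol <- array(params$background, dims)
  if (params$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    noise <- array(stats::rnorm(prod(dims)), dims)
    if (params$smoothing_sigma_mm > 0) {
      sig_vox <- params$smoothing_sigma_mm / sp
      noise <- gaussian_smooth3(noise, sig_vox) / gaussian_kernel_l2(sig_vox)
    }
    vol[inside] <- params$mean_intensity + params$noise_sd * noise[inside]
  } else {
    vol[inside] <- params$mean_intensity
  }
  list(volume = image_volume(vol, sp),
       mask = roi_mask(inside, sp),
       truth = params)
}

# Save/restore the global RNG state so generators are reproducible without
# clobbering the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Survival-generating truth for a synthetic cohort
#'
#' Event times are exponential with rate `baseline_rate * exp(lp)` per
#' patient (a constant-hazard Cox model, so proportional hazards holds
#' exactly); censoring is the minimum of an administrative horizon and a
#' uniform drop-out draw on `(0, censor_uniform_max)`.
#'
#' @param baseline_rate events per month at linear predictor 0 (> 0).
#' @param censor_horizon administrative censoring time in months (> 0).
#' @param censor_uniform_max upper bound of the uniform drop-out time
#'   (months); larger values censor less.
#' @param true_betas named numeric vector of coefficients on generative
#'   tumour parameters (used by [generate_cohort()]).
#' @return A `survival_truth` object.
#' @export
survival_truth <- function(baseline_rate = log(2) / 43,
                           censor_horizon = 72,
                           censor_uniform_max = 2 * censor_horizon,
                           true_betas = c(major_semi_axis = 0,
                                          smoothing_sigma = 0)) {
  if (!is.finite(baseline_rate) || baseline_rate <= 0)
    stop("`baseline_rate` must be > 0")
  if (!is.finite(censor_horizon) || censor_horizon <= 0)
    stop("`censor_horizon` must be > 0")
  if (!is.finite(censor_uniform_max) || censor_uniform_max <= 0)
    stop("`censor_uniform_max` must be > 0")
  structure(list(baseline_rate = baseline_rate,
                 censor_horizon = censor_horizon,
                 censor_uniform_max = censor_uniform_max,
                 true_betas = true_betas),
            class = "survival_truth")
}

#' Draw censored survival outcomes for given linear predictors
#'
#' @param linear_predictors finite numeric vector, one per patient.
#' @param truth a [survival_truth()].
#' @param seed integer RNG seed.
#' @return data.frame with columns `time_months` (> 0) and `event` (0/1).
#' @export
generate_survival <- function(linear_predictors, truth, seed = 1L) {
  stopifnot(inherits(truth, "survival_truth"))
  lp <- as.numeric(linear_predictors)
  if (any(!is.finite(lp)))
    stop("non-finite linear predictor at position ",
         which(!is.finite(lp))[1])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- length(lp)
  t_event <- stats::rexp(n, rate = truth$baseline_rate * exp(lp))
  t_cens <- pmin(truth$censor_horizon,
                 stats::runif(n, 0, truth$censor_uniform_max))
  data.frame(time_months = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens))
}

#' Configuration of a synthetic cohort
#'
#' Per-patient tumour parameters are drawn from uniform ranges chosen to
#' emulate oesophageal primaries on planning CT: roughly isotropic
#' transverse semi-axes, a longer cranio-caudal axis, soft-tissue
#' enhancement around 60 HU, and slice thickness sampled from 3 or 5 mm.
#' The survival linear predictor is a linear combination of standardised
#' generative parameters (major semi-axis and noise correlation length), so
#' size and texture features are informative by construction when the
#' corresponding `true_betas` are nonzero.
#'
#' @param transverse_range,long_axis_range uniform ranges (mm) for the two
#'   transverse semi-axes and the cranio-caudal semi-axis.
#' @param mean_intensity_range,noise_sd_range,smoothing_sigma_range uniform
#'   ranges for intensity level (HU), noise SD (HU) and noise correlation
#'   length (mm).
#' @param slice_thickness_mm slice thicknesses (mm) sampled per patient.
#' @param truth a [survival_truth()]; its `true_betas` may name
#'   `major_semi_axis` and/or `smoothing_sigma`.
#' @return A `cohort_config` object.
#' @export
cohort_config <- function(transverse_range = c(10, 16),
                          long_axis_range = c(15, 35),
                          mean_intensity_range = c(50, 70),
                          noise_sd_range = c(8, 15),
                          smoothing_sigma_range = c(0.5, 3),
                          slice_thickness_mm = c(3, 5),
                          truth = survival_truth()) {
  stopifnot(inherits(truth, "survival_truth"))
  structure(list(transverse_range = transverse_range,
                 long_axis_range = long_axis_range,
                 mean_intensity_range = mean_intensity_range,
                 noise_sd_range = noise_sd_range,
                 smoothing_sigma_range = smoothing_sigma_range,
                 slice_thickness_mm = slice_thickness_mm,
                 truth = truth),
            class = "cohort_config")
}

#' Generate a full synthetic cohort: tumours, masks and survival
#'
#' @param n number of patients (>= 2).
#' @param config a [cohort_config()].
#' @param seed integer RNG seed; the whole cohort is deterministic in it.
#' @return list with `patients` (list of `generate_tumour()` outputs),
#'   `cohort` (data.frame: patient_id, time_months, event, truth_* columns)
#'   and `truth` (the [survival_truth()] used).
#' @export
generate_cohort <- function(n, config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  if (n < 2) stop("`n` must be >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  runif_rng <- function(r) stats::runif(n, r[1], r[2])
  a <- runif_rng(config$transverse_range)
  b <- runif_rng(config$transverse_range)
  cc <- runif_rng(config$long_axis_range)
  mu <- runif_rng(config$mean_intensity_range)
  nsd <- runif_rng(config$noise_sd_range)
  sig <- runif_rng(config$smoothing_sigma_range)
  thick <- sample(config$slice_thickness_mm, n, replace = TRUE)
  tumour_seeds <- sample.int(.Machine$integer.max, n)
  survival_seed <- sample.int(.Machine$integer.max, 1)

  # standardise the generative drivers by their configured uniform moments
  std_unif <- function(x, r) (x - mean(r)) / (diff(r) / sqrt(12))
  major <- pmax(a, b, cc)
  betas <- config$truth$true_betas
  lp <- rep(0, n)
  if (!is.na(betas["major_semi_axis"]) && betas["major_semi_axis"] != 0)
    lp <- lp + betas[["major_semi_axis"]] *
      std_unif(major, config$long_axis_range)
  if (!is.na(betas["smoothing_sigma"]) && betas["smoothing_sigma"] != 0)
    lp <- lp + betas[["smoothing_sigma"]] *
      std_unif(sig, config$smoothing_sigma_range)

  patients <- vector("list", n)
  for (i in seq_len(n)) {
    p <- tumour_params(semi_axes_mm = c(a[i], b[i], cc[i]),
                       mean_intensity = mu[i], noise_sd = nsd[i],
                       smoothing_sigma_mm = sig[i],
                       spacing_mm = c(1, 1, thick[i]))
    patients[[i]] <- generate_tumour(p, seed = tumour_seeds[i])
  }
  surv <- generate_survival(lp, config$truth, seed = survival_seed)
  cohort <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                       time_months = surv$time_months,
                       event = surv$event,
                       truth_lp = lp,
                       truth_major_semi_axis = major,
                       truth_smoothing_sigma = sig,
                       truth_noise_sd = nsd,
                       truth_mean_intensity = mu,
                       truth_slice_thickness = thick,
                       stringsAsFactors = FALSE)
  list(patients = patients, cohort = cohort, truth = config$truth)
}

#' Write a synthetic cohort to disk
#'
#' Volumes and masks go to `<dir>/volumes/<id>.nii.gz` and
#' `<dir>/masks/<id>.nii.gz`; the cohort table (survival plus `truth_`
#' columns) to `<dir>/cohort.csv`.
#'
#' @param sim a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_files <- function(sim, dir) {
  vd <- file.path(dir, "volumes"); md <- file.path(dir, "masks")
  dir.create(vd, recursive = TRUE, showWarnings = FALSE)
  dir.create(md, recursive = TRUE, showWarnings = FALSE)
  ids <- sim$cohort$patient_id
  for (i in seq_along(sim$patients)) {
    write_volume(sim$patients[[i]]$volume,
                 file.path(vd, paste0(ids[i], ".nii.gz")))
    write_volume(sim$patients[[i]]$mask,
                 file.path(md, paste0(ids[i], ".nii.gz")))
  }
  utils::write.csv(sim$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  invisible(dir)
}
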