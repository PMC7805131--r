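#' Fit a LASSO-Cox signature with 10-fold cross-validation
#'
#' L1-penalised Cox regression over a 100-point log-spaced lambda grid
#' (from the smallest lambda shrinking every coefficient to zero down four
#' decades); the penalty is chosen as the minimiser of the cross-validated
#' partial-likelihood deviance.  Folds are stratified by event status and
#' fully determined by `seed`, so the fit is reproducible.  Features are
#' standardised with training statistics before fitting.
#'
#' @param cohort data.frame with `time_months`, `event` and features.
#' @param features character vector of candidate feature names.
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed controlling fold assignment.
#' @return A `lasso_fit`: list with `lambda` (grid), `cvm` (mean CV
#'   deviance), `lambda_min`, `beta` (nonzero coefficients at
#'   `lambda_min`, named), `path` (full coefficient matrix), `scaling`
#'   (training mean/sd), `foldid`, `features`.
#' @export
fit_lasso_cox <- function(cohort, features, folds = 10, seed = 1L) {
  stopifnot(all(c("time_months", "event") %in% names(cohort)))
  if (sum(cohort$event) < folds)
    stop("need at least as many events (", sum(cohort$event),
         ") as folds (", folds, ")")
  sc <- standardise_features(cohort[features])
  if (any(sc$constant))
    stop("constant feature(s) cannot enter the LASSO: ",
         paste(features[sc$constant], collapse = ", "))
  x <- as.matrix(sc$scaled)
  y <- survival::Surv(cohort$time_months, cohort$event)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  foldid <- make_event_stratified_folds(cohort$event, folds)

  # lambda grid: from the all-zero lambda down 4 decades, 100 points
  fit0 <- glmnet::glmnet(x, y, family = "cox", standardize = FALSE)
  lmax <- max(fit0$lambda)
  grid <- exp(seq(log(lmax), log(lmax * 1e-4), length.out = 100))
  cv <- glmnet::cv.glmnet(x, y, family = "cox", lambda = grid,
                          foldid = foldid, standardize = FALSE)
  b <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  nz <- b[b != 0]
  if (!length(nz))
    warning("all coefficients are zero at the selected lambda; ",
            "the signature is constant")
  structure(list(lambda = cv$lambda, cvm = cv$cvm,
                 lambda_min = cv$lambda.min, beta = nz,
                 path = as.matrix(stats::coef(cv$glmnet.fit)),
                 scaling = list(mean = sc$mean, sd = sc$sd),
                 foldid = foldid, features = features),
            class = "lasso_fit")
}

# Random fold labels balanced separately within events and censored
# records, re-drawn (with a warning) in the unlikely case a fold has no
# event.
make_event_stratified_folds <- function(event, folds, max_tries = 100) {
  n <- length(event)
  for (try in seq_len(max_tries)) {
    foldid <- integer(n)
    for (g in unique(event)) {
      idx <- which(event == g)
      foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    per_fold <- tapply(event, foldid, sum)
    if (all(per_fold > 0)) {
      if (try > 1) warning("refolded ", try - 1,
                           " time(s) to get events in every fold")
      return(foldid)
    }
  }
  stop("could not build folds with at least one event each")
}

#' Build a self-contained scoring formula from a LASSO fit
#'
#' The imaging-biomarker score is the log-partial hazard of the penalised
#' Cox model over standardised features, plus a constant chosen as the
#' smallest multiple of 0.1 that makes every training score strictly
#' positive.  The training scaling is embedded so the formula can be
#' applied verbatim to new patients.
#'
#' @param fit a [fit_lasso_cox()] result with >= 1 nonzero coefficient.
#' @param cohort the training cohort the fit was computed on.
#' @param endpoint label, `"OS"` or `"PFS"`.
#' @return A `score_formula`: list with `endpoint`, `terms` (named
#'   coefficients), `constant`, `scaling` (mean/sd per term feature).
#' @export
build_score <- function(fit, cohort, endpoint = "OS") {
  stopifnot(inherits(fit, "lasso_fit"))
  if (!length(fit$beta))
    stop("cannot build a score from an all-zero coefficient fit")
  feats <- names(fit$beta)
  sc <- standardise_features(cohort[feats],
                             stats = list(mean = fit$scaling$mean,
                                          sd = fit$scaling$sd))
  lp <- as.matrix(sc$scaled) %*% fit$beta
  cst <- positivity_constant(min(lp))
  structure(list(endpoint = endpoint, terms = fit$beta, constant = cst,
                 scaling = list(mean = fit$scaling$mean[feats],
                                sd = fit$scaling$sd[feats])),
            class = "score_formula")
}

# Smallest multiple of 0.1 c such that min_lp + c > 0 (c >= 0).
positivity_constant <- function(min_lp) {
  c0 <- (floor(-min_lp * 10) + 1) / 10
  max(0, c0)
}

#' The two published imaging-biomarker score formulas
#'
#' Frozen coefficient sets of the overall-survival (11 terms, constant
#' +2.5) and progression-free-survival (8 terms, constant -1.4) scores.
#' The formulas are interpreted as acting on standardised features: the
#' printed constants are only commensurate with the coefficients if the
#' feature values are on a unit scale, so the scaling spec is `"external"`
#' (the caller supplies already-standardised values, or passes a scaling
#' via `ibm_score()`).
#'
#' @param endpoint `"OS"` or `"PFS"`.
#' @return A `score_formula` with `scaling = "external"`.
#' @export
published_formula <- function(endpoint = c("OS", "PFS")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "OS") {
    terms <- c(Range = 0.019, Q975 = -3.231, Sphericity = -0.260,
               Major_axis_length = 0.093,
               Maximum_Probability_GLCM = 0.035,
               Sum_of_Square_Variance_GLCM = -0.304,
               Coarseness_NGTDM = -0.014, Contrast_NGTDM = -0.020,
               Busyness_NGTDM = 0.020,
               Small_Zone_Emphasis_GLSZM = 0.670,
               Zone_percentage_GLSZM = -0.064)
    constant <- 2.5
  } else {
    terms <- c(Q75 = -0.663, Q975 = -0.234, Volume_Density = -0.246,
               Sphericity = -0.010, Major_axis_length = 0.122,
               Contrast_NGTDM = -0.021,
               Small_Zone_Emphasis_GLSZM = 0.468,
               Zone_percentage_GLSZM = -0.069)
    constant <- -1.4
  }
  reg <- feature_registry()
  stopifnot(all(names(terms) %in% reg$name))
  structure(list(endpoint = endpoint, terms = terms, constant = constant,
                 scaling = "external"),
            class = "score_formula")
}

#' @export
print.score_formula <- function(x, ...) {
  cat("score_formula (", x$endpoint, "): ", length(x$terms),
      " terms, constant ", format(x$constant), "\n", sep = "")
  invisible(x)
}

#' Apply a scoring formula to feature values
#'
#' Applies the formula's scaling spec (training mean/sd embedded in a
#' fitted formula; none for a published formula, whose inputs must
#' already be standardised) and then the linear combination plus
#' constant.
#'
#' @param features named numeric vector (one patient) or data.frame
#'   (one row per patient) containing every formula feature.
#' @param formula a `score_formula`.
#' @return numeric score(s).
#' @export
ibm_score <- function(features, formula) {
  stopifnot(inherits(formula, "score_formula"))
  if (is.vector(features) && !is.null(names(features)))
    features <- as.data.frame(as.list(features))
  need <- names(formula$terms)
  miss <- setdiff(need, names(features))
  if (length(miss))
    stop("missing feature(s) required by the ", formula$endpoint,
         " formula: ", paste(miss, collapse = ", "))
  x <- as.matrix(features[need])
  if (is.list(formula$scaling)) {
    x <- sweep(x, 2, formula$scaling$mean[need])
    sd_use <- formula$scaling$sd[need]
    sd_use[sd_use == 0] <- 1
    x <- sweep(x, 2, sd_use, `/`)
  }
  as.numeric(x %*% formula$terms + formula$constant)
}

#' Write / read a scoring formula as JSON
#'
#' Coefficients survive the round trip bit-exactly (serialised at full
#' precision).
#'
#' @param formula a `score_formula`.
#' @param path file path.
#' @return `path` (write) or the `score_formula` (read).
#' @export
write_formula <- function(formula, path) {
  stopifnot(inherits(formula, "score_formula"))
  obj <- list(endpoint = formula$endpoint,
              terms = lapply(seq_along(formula$terms), function(i)
                list(feature = names(formula$terms)[i],
                     coefficient = formula$terms[[i]])),
              constant = formula$constant)
  if (is.list(formula$scaling))
    obj$scaling <- list(mean = as.list(formula$scaling$mean),
                        sd = as.list(formula$scaling$sd))
  else obj$scaling <- formula$scaling
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_formula
#' @export
read_formula <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  terms <- stats::setNames(
    vapply(obj$terms, function(t) as.numeric(t$coefficient), numeric(1)),
    vapply(obj$terms, function(t) t$feature, character(1)))
  scaling <- if (is.character(obj$scaling) ||
                 (is.list(obj$scaling) && is.null(obj$scaling$mean)))
    "external"
  else list(mean = unlist(obj$scaling$mean), sd = unlist(obj$scaling$sd))
  structure(list(endpoint = obj$endpoint, terms = terms,
                 constant = as.numeric(obj$constant), scaling = scaling),
            class = "score_formula")
}
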