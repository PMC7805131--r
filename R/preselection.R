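#' Standardise feature columns with training statistics
#'
#' Zero-mean, unit-variance scaling; the means and SDs are returned so the
#' identical transform can be applied to a validation cohort.  Constant
#' columns (SD 0) are left centred only and flagged.
#'
#' @param x data.frame or matrix of numeric feature columns.
#' @param stats optional list with `mean` and `sd` (from a training call)
#'   to apply instead of computing fresh statistics.
#' @return list with `scaled` (data.frame), `mean`, `sd`, `constant`
#'   (logical per column).
#' @export
standardise_features <- function(x, stats = NULL) {
  xm <- as.matrix(x)
  if (is.null(stats)) {
    mu <- colMeans(xm)
    sd <- apply(xm, 2, stats::sd)
  } else {
    mu <- stats$mean[colnames(xm)]
    sd <- stats$sd[colnames(xm)]
  }
  constant <- sd == 0 | !is.finite(sd)
  sd_use <- ifelse(constant, 1, sd)
  scaled <- sweep(sweep(xm, 2, mu), 2, sd_use, `/`)
  list(scaled = as.data.frame(scaled), mean = mu, sd = sd,
       constant = constant)
}

#' Univariable Cox screening of feature columns
#'
#' One single-covariate proportional-hazards fit per standardised feature;
#' a feature is kept iff its Wald p-value is below `p_threshold` (default
#' 0.25, deliberately liberal at this first stage).  Constant features are
#' dropped with a warning and reported with p = 1.
#'
#' @param cohort data.frame with `time_months`, `event` and the feature
#'   columns named in `features`.
#' @param features character vector of feature column names.
#' @param p_threshold Wald p-value cutoff.
#' @return A `screen_result`: data.frame (feature, coef, hr, p, kept,
#'   constant) plus attributes `scaling` (training mean/sd) and
#'   `p_threshold`.
#' @export
univariable_cox_screen <- function(cohort, features,
                                   p_threshold = 0.25) {
  stopifnot(all(c("time_months", "event") %in% names(cohort)))
  if (sum(cohort$event) < 2)
    stop("univariable screening needs at least 2 events, got ",
         sum(cohort$event))
  miss <- setdiff(features, names(cohort))
  if (length(miss)) stop("features not in cohort: ",
                         paste(miss, collapse = ", "))
  sc <- standardise_features(cohort[features])
  y <- survival::Surv(cohort$time_months, cohort$event)
  res <- data.frame(feature = features, coef = NA_real_, hr = NA_real_,
                    p = 1, kept = FALSE, constant = sc$constant,
                    stringsAsFactors = FALSE)
  for (k in seq_along(features)) {
    if (sc$constant[k]) next
    x <- sc$scaled[[k]]
    fit <- tryCatch(survival::coxph(y ~ x), error = function(e) NULL,
                    warning = function(w) suppressWarnings(
                      survival::coxph(y ~ x)))
    if (is.null(fit)) next
    s <- summary(fit)
    res$coef[k] <- unname(stats::coef(fit))
    res$hr[k] <- unname(exp(stats::coef(fit)))
    res$p[k] <- s$coefficients[1, "Pr(>|z|)"]
  }
  if (any(sc$constant))
    warning("constant feature(s) dropped from screening: ",
            paste(features[sc$constant], collapse = ", "))
  res$kept <- !sc$constant & is.finite(res$p) & res$p < p_threshold
  structure(res, class = c("screen_result", "data.frame"),
            scaling = list(mean = sc$mean, sd = sc$sd),
            p_threshold = p_threshold)
}

#' Prune highly correlated features, keeping the stronger of each pair
#'
#' Among screen-kept features, build the graph of pairs with
#' `|Pearson r| >= r_threshold`; repeatedly delete the feature with the
#' largest univariable p-value among those still incident to an edge,
#' until no edge remains.  Ties in p are broken by registry (column)
#' order: the later feature is removed.
#'
#' @param cohort data.frame holding the feature columns.
#' @param screen a [univariable_cox_screen()] result.
#' @param r_threshold absolute correlation threshold (default 0.8).
#' @return list with `retained` (character), `removed` (character, in
#'   deletion order) and `r` (correlation matrix of the screened set).
#' @export
correlation_prune <- function(cohort, screen, r_threshold = 0.8) {
  stopifnot(inherits(screen, "screen_result"))
  kept <- screen$feature[screen$kept]
  if (length(kept) < 2)
    return(list(retained = kept, removed = character(0),
                r = diag(length(kept))))
  r <- stats::cor(as.matrix(cohort[kept]))
  pvals <- stats::setNames(screen$p[match(kept, screen$feature)], kept)
  alive <- kept
  removed <- character(0)
  repeat {
    rr <- abs(r[alive, alive, drop = FALSE])
    diag(rr) <- 0
    edge <- rr >= r_threshold
    if (!any(edge)) break
    incident <- alive[rowSums(edge) > 0]
    # largest p among incident features; ties -> latest in registry order
    worst <- incident[order(-pvals[incident],
                            -match(incident, kept))][1]
    alive <- setdiff(alive, worst)
    removed <- c(removed, worst)
  }
  list(retained = alive, removed = removed, r = r)
}

#' Variance inflation factors of retained features
#'
#' `VIF_k = 1 / (1 - R^2_k)` where `R^2_k` comes from the OLS regression
#' of feature k on the other retained features.  A perfectly collinear
#' column is reported as `Inf`.
#'
#' @param cohort data.frame holding the feature columns.
#' @param features character vector (>= 2 names).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(cohort, features) {
  if (length(features) < 2) stop("VIF needs at least 2 features")
  x <- as.matrix(cohort[features])
  if (nrow(x) <= length(features) + 1)
    stop("VIF needs n > number of features + 1")
  out <- stats::setNames(numeric(length(features)), features)
  for (k in seq_along(features)) {
    fit <- stats::lm.fit(cbind(1, x[, -k, drop = FALSE]), x[, k])
    r2 <- 1 - sum(fit$residuals^2) /
      sum((x[, k] - mean(x[, k]))^2)
    out[k] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  out
}
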