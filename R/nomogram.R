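#' Build a score-based nomogram model
#'
#' Univariable Cox fit of survival on the imaging-biomarker score with a
#' Breslow baseline cumulative hazard, plus an affine 0-100 points scale
#' over the observed training score range.  Individual survival is
#' `S(t | x) = exp(-H0(t) * exp(beta * x))`.
#'
#' @param scores training scores.
#' @param time,event training survival data.
#' @param times prediction horizons in months (default 12, 36, 60).
#' @param min_events minimum number of events required.
#' @return A `nomogram_model`: list with `beta`, `basehaz` (time, hazard),
#'   `score_range`, `points(score)` function, `times`.
#' @export
build_nomogram <- function(scores, time, event, times = c(12, 36, 60),
                           min_events = 10) {
  if (sum(event) < min_events)
    stop("nomogram needs >= ", min_events, " events, got ", sum(event))
  df <- data.frame(score = scores, time = time, event = event)
  fit <- survival::coxph(survival::Surv(time, event) ~ score, data = df,
                         ties = "breslow")
  if (!fit$iter || any(!is.finite(stats::coef(fit))))
    stop("nomogram Cox fit did not converge")
  # Breslow baseline cumulative hazard at covariate value 0
  bh <- survival::basehaz(fit, centered = FALSE)
  rng <- range(scores)
  pts <- function(s) {
    if (diff(rng) == 0) rep(0, length(s))
    else 100 * (s - rng[1]) / diff(rng)
  }
  structure(list(beta = unname(stats::coef(fit)),
                 basehaz = data.frame(time = bh$time, hazard = bh$hazard),
                 score_range = rng, points = pts, times = times,
                 fit = fit),
            class = "nomogram_model")
}

#' Predict individual survival from a nomogram model
#'
#' Returns `S(t | score)` at the requested times (right-continuous step
#' lookup of the baseline hazard) and the median survival: the smallest
#' observed event time with `S <= 0.5`, or `NA` ("not reached") if the
#' curve never falls that far within follow-up.  Scores outside the
#' training range are flagged, not refused.
#'
#' @param model a [build_nomogram()] result.
#' @param score one score value.
#' @param times horizons in months (default the model's).
#' @return list with `times`, `surv`, `median` (NA = not reached),
#'   `extrapolated` (logical).
#' @export
predict_survival <- function(model, score, times = model$times) {
  stopifnot(inherits(model, "nomogram_model"))
  if (!length(model$basehaz$time)) stop("empty nomogram model")
  h0 <- stats::stepfun(model$basehaz$time, c(0, model$basehaz$hazard),
                       right = FALSE)
  lp <- model$beta * score
  surv <- exp(-h0(times) * exp(lp))
  curve <- exp(-model$basehaz$hazard * exp(lp))
  below <- which(curve <= 0.5)
  med <- if (length(below)) model$basehaz$time[min(below)] else NA_real_
  extrap <- score < model$score_range[1] || score > model$score_range[2]
  if (extrap)
    warning("score ", format(score), " lies outside the training range [",
            paste(format(model$score_range), collapse = ", "), "]")
  list(times = times, surv = surv, median = med, extrapolated = extrap)
}

#' Predicted event risk by a horizon, for decision curves
#'
#' @param model a [build_nomogram()] result.
#' @param scores numeric vector.
#' @param tau horizon in months.
#' @return numeric vector of risks `1 - S(tau | score)`.
#' @export
predicted_risk <- function(model, scores, tau) {
  h0 <- stats::stepfun(model$basehaz$time, c(0, model$basehaz$hazard),
                       right = FALSE)
  1 - exp(-h0(tau) * exp(model$beta * scores))
}
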