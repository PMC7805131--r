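#' Decision-curve analysis for a survival horizon
#'
#' For each threshold probability `p_t`, patients with predicted risk
#' `>= p_t` are treated as test-positive; the event probability among the
#' positives by `tau` is estimated with Kaplan-Meier inside the positive
#' group (so censoring is handled), and the net benefit is
#' `(n+/n) * (risk+ - (1 - risk+) * p_t / (1 - p_t))`.  Treat-all uses
#' the whole cohort as positive; treat-none has net benefit 0 by
#' definition.
#'
#' @param risks predicted event risks by `tau`, one per patient, in (0,1).
#' @param time,event survival data.
#' @param tau horizon in months.
#' @param thresholds threshold-probability grid, strictly inside (0,1).
#' @return A `decision_curve` data.frame: `threshold`, `nb_model`,
#'   `nb_all`, `nb_none`; thresholds with an empty positive group get
#'   `nb_model = 0` and are listed in the `empty_positive` attribute.
#' @export
decision_curve <- function(risks, time, event, tau,
                           thresholds = seq(0.05, 0.95, by = 0.05)) {
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  n <- length(risks)
  km_all <- km_estimate(time, event)
  rho <- 1 - km_all$surv_at(tau)  # cohort event probability by tau
  odds <- thresholds / (1 - thresholds)
  nb_all <- rho - (1 - rho) * odds
  empty <- logical(length(thresholds))
  nb_model <- vapply(seq_along(thresholds), function(k) {
    pos <- risks >= thresholds[k]
    if (!any(pos)) { empty[k] <<- TRUE; return(0) }
    km_pos <- km_estimate(time[pos], event[pos])
    risk_pos <- 1 - km_pos$surv_at(tau)
    (sum(pos) / n) * (risk_pos - (1 - risk_pos) * odds[k])
  }, numeric(1))
  out <- data.frame(threshold = thresholds, nb_model = nb_model,
                    nb_all = nb_all, nb_none = 0)
  class(out) <- c("decision_curve", "data.frame")
  attr(out, "tau") <- tau
  attr(out, "empty_positive") <- thresholds[empty]
  out
}

#' Compare the net benefit of two decision curves
#'
#' Tabulates the per-threshold difference between two strategies (e.g. an
#' imaging-biomarker score versus clinical stage) and the contiguous
#' threshold interval, if any, where the first strictly dominates.
#'
#' @param curve_a,curve_b [decision_curve()] results on the same grid and
#'   horizon.
#' @return list with `table` (threshold, nb_a, nb_b, diff) and
#'   `a_dominates` (range of thresholds where diff > 0, or NULL).
#' @export
compare_strategies <- function(curve_a, curve_b) {
  stopifnot(inherits(curve_a, "decision_curve"),
            inherits(curve_b, "decision_curve"))
  if (!isTRUE(all.equal(curve_a$threshold, curve_b$threshold)))
    stop("decision curves are on different threshold grids")
  if (!identical(attr(curve_a, "tau"), attr(curve_b, "tau")))
    stop("decision curves are at different horizons")
  d <- curve_a$nb_model - curve_b$nb_model
  tab <- data.frame(threshold = curve_a$threshold,
                    nb_a = curve_a$nb_model, nb_b = curve_b$nb_model,
                    diff = d)
  dom <- NULL
  if (any(d > 0)) dom <- range(curve_a$threshold[d > 0])
  list(table = tab, a_dominates = dom)
}
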