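#' Harrell's concordance index with bootstrap confidence interval
#'
#' The probability, over usable (comparable) patient pairs, that the
#' patient with the higher risk score fails earlier.  A pair is usable if
#' the shorter observed time belongs to an event.  Tied scores count 1/2.
#' The 95% CI is a seeded percentile bootstrap over patients.
#'
#' @param scores numeric risk scores (higher = higher risk).
#' @param time,event survival times and 0/1 event indicators.
#' @param n_boot bootstrap resamples for the CI (0 skips the CI).
#' @param seed bootstrap seed.
#' @return list with `c_index`, `ci` (length 2 or NULL), `n_pairs`.
#' @export
concordance_index <- function(scores, time, event, n_boot = 1000,
                              seed = 1L) {
  ci_point <- harrell_c(scores, time, event)
  if (is.na(ci_point$c))
    stop("no comparable pair: concordance is undefined")
  ci <- NULL
  if (n_boot > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    n <- length(scores)
    stats_b <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      harrell_c(scores[idx], time[idx], event[idx])$c
    }, numeric(1))
    ci <- unname(stats::quantile(stats_b, c(0.025, 0.975), na.rm = TRUE))
  }
  list(c_index = ci_point$c, ci = ci, n_pairs = ci_point$n_pairs)
}

# Vectorised O(n^2) pair enumeration, following the standard comparability
# rules: with distinct times the pair is usable iff the earlier time is an
# event; with tied times it is usable only when exactly one is an event
# (the event is taken to fail first).  Tied scores count 1/2.
harrell_c <- function(scores, time, event) {
  n <- length(scores)
  if (n < 2) return(list(c = NA_real_, n_pairs = 0))
  pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
  i <- pr[, 1]; j <- pr[, 2]
  t1 <- time[i]; t2 <- time[j]
  e1 <- event[i]; e2 <- event[j]
  s1 <- scores[i]; s2 <- scores[j]
  eq <- t1 == t2
  first_is_i <- ifelse(eq, e1 == 1 & e2 == 0, t1 < t2)
  usable <- ifelse(eq, e1 + e2 == 1,
                   ifelse(t1 < t2, e1 == 1, e2 == 1))
  s_first <- ifelse(first_is_i, s1, s2)
  s_other <- ifelse(first_is_i, s2, s1)
  conc <- sum((s_first[usable] > s_other[usable]) +
                0.5 * (s_first[usable] == s_other[usable]))
  n_usable <- sum(usable)
  list(c = if (n_usable > 0) conc / n_usable else NA_real_,
       n_pairs = n_usable)
}

#' Time-dependent ROC curve at a horizon
#'
#' Cumulative-case / dynamic-control ROC with Kaplan-Meier
#' inverse-probability-of-censoring weights: cases are patients with an
#' event by `tau` (weight `1 / G(T_i^-)`), controls are patients still
#' at risk beyond `tau` (weight `1 / G(tau)`), with `G` the censoring
#' survival function.  AUC is the trapezoid area under the (1-spec, sens)
#' curve; the optional CI is a seeded percentile bootstrap.
#'
#' @param scores risk scores (higher = higher risk).
#' @param time,event survival data.
#' @param tau horizon in months.
#' @param n_boot bootstrap resamples for the AUC CI (0 skips).
#' @param seed bootstrap seed.
#' @return A `roc_curve`: list with `tau`, `thresholds`, `sensitivity`,
#'   `specificity`, `youden`, `auc`, `ci`.
#' @export
time_dependent_roc <- function(scores, time, event, tau, n_boot = 0,
                               seed = 1L) {
  curve <- tdroc_curve(scores, time, event, tau)
  if (is.null(curve))
    stop("no events by tau = ", tau,
         " (or nobody at risk beyond it): ROC undefined")
  ci <- NULL
  if (n_boot > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(as.integer(seed))
    n <- length(scores)
    aucs <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      cv <- tdroc_curve(scores[idx], time[idx], event[idx], tau)
      if (is.null(cv)) NA_real_ else cv$auc
    }, numeric(1))
    ci <- unname(stats::quantile(aucs, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(c(curve, list(ci = ci)), class = "roc_curve")
}

tdroc_curve <- function(scores, time, event, tau) {
  is_case <- time <= tau & event == 1
  is_ctrl <- time > tau
  if (!any(is_case) || !any(is_ctrl)) return(NULL)
  # censoring KM: G(t) = P(censoring time > t)
  gfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  gfun <- stats::stepfun(gfit$time, c(1, gfit$surv), right = FALSE)
  g_case <- vapply(time[is_case], function(t) km_left_limit(gfit, t),
                   numeric(1))
  w_case <- ifelse(g_case > 0, 1 / g_case, 0)
  g_tau <- km_left_limit(gfit, tau, at = TRUE)
  w_ctrl <- rep(if (g_tau > 0) 1 / g_tau else 0, sum(is_ctrl))
  s_case <- scores[is_case]; s_ctrl <- scores[is_ctrl]
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(c) sum(w_case[s_case > c]) / sum(w_case),
                 numeric(1))
  spec <- vapply(thr, function(c) sum(w_ctrl[s_ctrl <= c]) / sum(w_ctrl),
                 numeric(1))
  # pad the curve endpoints for the trapezoid
  fpr <- c(1, 1 - spec, 0); tpr <- c(1, sens, 0)
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (utils::head(tpr[ord], -1) +
                                 utils::tail(tpr[ord], -1)) / 2)
  list(tau = tau, thresholds = thr, sensitivity = sens,
       specificity = spec, youden = sens + spec - 1, auc = auc)
}

# KM value just below t (left limit), or at t when `at` is TRUE.
km_left_limit <- function(fit, t, at = FALSE) {
  tt <- fit$time; ss <- fit$surv
  keep <- if (at) tt <= t else tt < t
  if (!any(keep)) 1 else ss[max(which(keep))]
}

#' Youden-index optimal cutoff of a time-dependent ROC
#'
#' The threshold maximising J = sensitivity + specificity - 1, with ties
#' broken toward the higher-specificity (higher) threshold; returned as
#' the midpoint between the chosen observed score and the next one above
#' it.  If J <= 0 everywhere the score does not separate (reversed or
#' null labels); the cutoff is still returned but flagged.
#'
#' @param roc a [time_dependent_roc()] result.
#' @return numeric cutoff with attribute `youden` (the maximal J); if
#'   `max(J) <= 0` an attribute `flag = "non_separating"` is set.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  thr <- roc$thresholds
  if (length(thr) < 2)
    stop("all scores are equal: no cutoff can be chosen")
  j <- roc$youden
  best <- which(j == max(j))
  pick <- best[which.max(roc$specificity[best])]  # tie -> higher spec
  cut <- if (pick < length(thr)) (thr[pick] + thr[pick + 1]) / 2
  else thr[pick] + (thr[pick] - thr[pick - 1]) / 2
  out <- cut
  attr(out, "youden") <- max(j)
  if (max(j) <= 0) attr(out, "flag") <- "non_separating"
  out
}

#' Kaplan-Meier estimate with Greenwood variance
#'
#' Product-limit estimator wrapped from [survival::survfit()], returned
#' with a right-continuous step lookup for probabilities at arbitrary
#' times.
#'
#' @param time,event survival data.
#' @return A `km_fit`: list with `time`, `surv`, `se` (Greenwood),
#'   `surv_at(t)` lookup function, and the underlying `survfit` object.
#' @export
km_estimate <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log")
  lookup <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  list(time = fit$time, surv = fit$surv, se = fit$std.err * fit$surv,
       surv_at = function(t) lookup(t), fit = fit)
}

#' Two-group log-rank test
#'
#' @param time,event survival data.
#' @param group two-level grouping vector.
#' @return list with `chisq`, `p` (1 df), `n` per group.
#' @export
log_rank <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("log_rank needs exactly 2 groups, got ",
                            nlevels(g))
  if (any(table(g) == 0)) stop("both groups must be non-empty")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  list(chisq = sd$chisq,
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = as.vector(table(g)))
}

#' Stratify a cohort at a score cutoff and test the split
#'
#' Patients with `score > cutoff` form the high-risk group.  Reports the
#' per-group KM survival at requested horizons, the high-vs-low hazard
#' ratio with Wald 95% CI, and the log-rank test.
#'
#' @param scores,time,event cohort data.
#' @param cutoff score threshold (typically from [youden_cutoff()] on the
#'   training cohort).
#' @param horizons months at which per-group survival is reported.
#' @return A `stratification_result` list.
#' @export
stratify_by_cutoff <- function(scores, time, event, cutoff,
                               horizons = c(12, 36, 60)) {
  high <- scores > cutoff
  if (all(high) || !any(high))
    stop("cutoff ", format(cutoff), " does not split the cohort")
  lr <- log_rank(time, event, high)
  fit <- survival::coxph(survival::Surv(time, event) ~ high)
  beta <- unname(stats::coef(fit)); se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  km_lo <- km_estimate(time[!high], event[!high])
  km_hi <- km_estimate(time[high], event[high])
  structure(list(
    cutoff = as.numeric(cutoff),
    group = ifelse(high, "high", "low"),
    km_at = data.frame(horizon = horizons,
                       low = km_lo$surv_at(horizons),
                       high = km_hi$surv_at(horizons)),
    hr = exp(beta),
    hr_ci = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
    log_rank_chisq = lr$chisq, log_rank_p = lr$p),
    class = "stratification_result")
}

#' Multivariable Cox model, full or backward likelihood-ratio stepwise
#'
#' `mode = "full"` fits all covariates at once.  `mode = "backward_LR"`
#' starts from the full model and repeatedly removes the covariate whose
#' removal has the largest likelihood-ratio p-value above `p_remove`
#' (default 0.10) until every remaining covariate is below it; both the
#' full (pre-removal) and final tables are returned.
#'
#' @param cohort data.frame with `time_months`, `event` and covariates.
#' @param covariates character vector of covariate column names.
#' @param mode `"full"` or `"backward_LR"`.
#' @param p_remove backward-elimination threshold.
#' @return list with `full` (coefficient table), `final` (table, equal to
#'   `full` in full mode), `removed` (in elimination order), `fit`.
#' @export
cox_multivariable <- function(cohort, covariates,
                              mode = c("full", "backward_LR"),
                              p_remove = 0.10) {
  mode <- match.arg(mode)
  stopifnot(all(covariates %in% names(cohort)))
  if (sum(cohort$event) <= length(covariates))
    stop("need more events (", sum(cohort$event),
         ") than covariates (", length(covariates), ")")
  y <- survival::Surv(cohort$time_months, cohort$event)
  fit_with <- function(vars) {
    if (!length(vars))
      return(survival::coxph(y ~ 1, data = cohort))
    f <- stats::as.formula(paste("y ~", paste(vars, collapse = " + ")))
    survival::coxph(f, data = cohort)
  }
  tab <- function(fit) {
    if (is.null(stats::coef(fit)) || !length(stats::coef(fit)))
      return(data.frame(term = character(0), hr = numeric(0),
                        lo = numeric(0), hi = numeric(0),
                        p = numeric(0)))
    s <- summary(fit)
    data.frame(term = rownames(s$coefficients),
               hr = s$coefficients[, "exp(coef)"],
               lo = s$conf.int[, "lower .95"],
               hi = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               row.names = NULL)
  }
  full_fit <- fit_with(covariates)
  cf <- stats::coef(full_fit)
  vc <- tryCatch(sqrt(diag(stats::vcov(full_fit))),
                 error = function(e) NA_real_)
  if (any(is.na(cf)) || any(!is.finite(vc)))
    warning("unstable full model (possible separation or collinearity)")
  removed <- character(0)
  current <- covariates
  if (mode == "backward_LR") {
    repeat {
      if (!length(current)) break
      fit_cur <- fit_with(current)
      lr_p <- vapply(current, function(v) {
        fit_red <- fit_with(setdiff(current, v))
        lr <- 2 * (fit_cur$loglik[2] -
                     fit_red$loglik[length(fit_red$loglik)])
        stats::pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
      }, numeric(1))
      worst <- which.max(lr_p)
      if (lr_p[worst] <= p_remove) break
      removed <- c(removed, current[worst])
      current <- current[-worst]
    }
  }
  final_fit <- fit_with(current)
  list(full = tab(full_fit), final = tab(final_fit),
       removed = removed, fit = final_fit)
}

#' Between-cohort balance tests
#'
#' Continuous variables: two-sided independent-samples t-test with pooled
#' variance.  Categorical variables: Pearson chi-squared without
#' continuity correction.  A category absent from both cohorts is dropped.
#'
#' @param cohort_a,cohort_b data.frames sharing the tested columns.
#' @param variables named character vector: values are column names,
#'   names give the type (`"continuous"` or `"categorical"`); an unnamed
#'   vector is typed automatically (numeric -> continuous).
#' @return data.frame with `variable`, `type`, `statistic`, `p`.
#' @export
cohort_balance <- function(cohort_a, cohort_b, variables) {
  if (is.null(names(variables)) || any(names(variables) == "")) {
    types <- vapply(variables, function(v)
      if (is.numeric(cohort_a[[v]])) "continuous" else "categorical",
      character(1))
    variables <- stats::setNames(variables, types)
  }
  rows <- lapply(seq_along(variables), function(k) {
    v <- variables[k]; type <- names(variables)[k]
    a <- cohort_a[[v]]; b <- cohort_b[[v]]
    if (type == "continuous") {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      data.frame(variable = unname(v), type = type,
                 statistic = unname(tt$statistic), p = tt$p.value)
    } else {
      fa <- factor(a); fb <- factor(b)
      lev <- union(levels(fa), levels(fb))
      counts <- rbind(table(factor(a, lev)), table(factor(b, lev)))
      counts <- counts[, colSums(counts) > 0, drop = FALSE]
      ct <- stats::chisq.test(counts, correct = FALSE)
      data.frame(variable = unname(v), type = type,
                 statistic = unname(ct$statistic), p = ct$p.value)
    }
  })
  do.call(rbind, rows)
}
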