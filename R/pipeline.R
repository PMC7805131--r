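#' Pipeline configuration
#'
#' Bundles every tunable of the full study replica.  All randomness flows
#' from the three named seeds, so a rerun with the same config is
#' reproducible end to end.
#'
#' @param n cohort size.
#' @param split_ratio training fraction (default 99/154, the published
#'   99:55 split).
#' @param sim_seed,fold_seed,boot_seed seeds for cohort simulation,
#'   cross-validation folds and bootstrap CIs.
#' @param endpoint label for the fitted signature.
#' @param scheme,bins discretisation scheme and parameter.
#' @param p_threshold,r_threshold,folds pre-selection and CV settings.
#' @param horizons evaluation horizons in months.
#' @param roc_tau horizon for the Youden cutoff ROC (default the largest
#'   horizon).
#' @param cohort synthetic [cohort_config()].
#' @param n_boot bootstrap resamples for CIs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n = 154, split_ratio = 99 / 154,
                            sim_seed = 1L, fold_seed = 2L,
                            boot_seed = 3L, endpoint = "OS",
                            scheme = "fixed_bin_number", bins = 32,
                            p_threshold = 0.25, r_threshold = 0.8,
                            folds = 10, horizons = c(12, 36, 60),
                            roc_tau = max(horizons),
                            cohort = cohort_config(),
                            n_boot = 200) {
  if (split_ratio <= 0 || split_ratio >= 1)
    stop("`split_ratio` must lie in (0, 1)")
  structure(list(n = n, split_ratio = split_ratio, sim_seed = sim_seed,
                 fold_seed = fold_seed, boot_seed = boot_seed,
                 endpoint = endpoint, scheme = scheme, bins = bins,
                 p_threshold = p_threshold, r_threshold = r_threshold,
                 folds = folds, horizons = horizons, roc_tau = roc_tau,
                 cohort = cohort, n_boot = n_boot),
            class = "pipeline_config")
}

#' Random training/validation split of patient ids
#'
#' Simple random partition: `round(n * ratio)` ids go to training, the
#' rest to validation; the two sets are disjoint and exhaustive and the
#' split is deterministic in the seed.
#'
#' @param ids patient identifiers.
#' @param ratio training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `training` and `validation` id vectors.
#' @export
random_split <- function(ids, ratio, seed = 1L) {
  n <- length(ids)
  if (n < 4) stop("need at least 4 patients to split")
  n_train <- round(n * ratio)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  tr <- sort(sample.int(n, n_train))
  list(training = ids[tr], validation = ids[-tr])
}

#' Run the full study replica on a synthetic cohort
#'
#' simulate -> extract -> split -> pre-select -> LASSO-Cox -> score ->
#' evaluate -> nomogram/DCA.  Every fitted quantity (feature scaling,
#' screening decisions, lambda, the score constant, the Youden cutoff,
#' the nomogram baseline) is learned on the training cohort only and
#' applied unchanged to the validation cohort; the returned report
#' carries a `lineage` record stating which cohort each stage consumed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; if given, the report is written to
#'   `report.json` and the per-patient tables to CSV files there.
#' @return A `study_report` list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  reg <- feature_registry()

  sim <- generate_cohort(config$n, config$cohort, seed = config$sim_seed)
  feats <- extract_cohort(sim$patients, ids = sim$cohort$patient_id,
                          scheme = config$scheme, value = config$bins)
  data <- merge(sim$cohort, feats, by = "patient_id", sort = FALSE)

  sp <- random_split(data$patient_id, config$split_ratio,
                     seed = config$sim_seed)
  train <- data[data$patient_id %in% sp$training, ]
  valid <- data[data$patient_id %in% sp$validation, ]

  balance <- cohort_balance(train, valid,
                            c(continuous = "truth_major_semi_axis",
                              continuous = "truth_smoothing_sigma",
                              continuous = "truth_mean_intensity",
                              categorical = "truth_slice_thickness"))

  screen <- univariable_cox_screen(train, reg$name,
                                   p_threshold = config$p_threshold)
  pruned <- correlation_prune(train, screen,
                              r_threshold = config$r_threshold)
  retained <- pruned$retained
  if (length(retained) < 2)
    stop("pre-selection retained fewer than 2 features; ",
         "nothing to fit (stage: preselection)")
  vifs <- if (nrow(train) > length(retained) + 1)
    vif(train, retained) else NULL

  fit <- suppressWarnings(
    fit_lasso_cox(train, retained, folds = config$folds,
                  seed = config$fold_seed))
  null_signature <- !length(fit$beta)
  if (null_signature) {
    # flat deviance curve, all coefficients shrunk away: the signature is
    # constant; scoring-dependent stages are skipped and flagged
    formula <- NULL
    train$score <- 0
    valid$score <- 0
  } else {
    formula <- build_score(fit, train, endpoint = config$endpoint)
    train$score <- ibm_score(train, formula)
    valid$score <- ibm_score(valid, formula)
  }

  eval_one <- function(d) {
    ci <- concordance_index(d$score, d$time_months, d$event,
                            n_boot = config$n_boot,
                            seed = config$boot_seed)
    aucs <- lapply(config$horizons, function(tau) {
      r <- tryCatch(time_dependent_roc(d$score, d$time_months, d$event,
                                       tau),
                    error = function(e) NULL)
      if (is.null(r)) NULL else list(tau = tau, auc = r$auc)
    })
    list(c_index = ci$c_index, c_index_ci = ci$ci,
         auc = Filter(Negate(is.null), aucs))
  }
  if (!null_signature) {
    roc_train <- time_dependent_roc(train$score, train$time_months,
                                    train$event, config$roc_tau)
    cutoff <- youden_cutoff(roc_train)
    strat_train <- stratify_by_cutoff(train$score, train$time_months,
                                      train$event, cutoff,
                                      horizons = config$horizons)
    strat_valid <- tryCatch(
      stratify_by_cutoff(valid$score, valid$time_months, valid$event,
                         cutoff, horizons = config$horizons),
      error = function(e) NULL)

    nomo <- build_nomogram(train$score, train$time_months, train$event,
                           times = config$horizons)
    dca_tau <- config$roc_tau
    dca_train <- decision_curve(
      predicted_risk(nomo, train$score, dca_tau),
      train$time_months, train$event, dca_tau)
    dca_valid <- decision_curve(
      predicted_risk(nomo, valid$score, dca_tau),
      valid$time_months, valid$event, dca_tau)
  } else {
    cutoff <- NA_real_
    strat_train <- strat_valid <- NULL
    dca_train <- dca_valid <- NULL
  }

  report <- list(
    schema_version = "1.0",
    config = config[setdiff(names(config), "cohort")],
    seeds = list(sim = config$sim_seed, folds = config$fold_seed,
                 bootstrap = config$boot_seed),
    split = list(n_training = nrow(train), n_validation = nrow(valid)),
    balance = balance,
    screening = list(n_kept = sum(screen$kept),
                     n_retained = length(retained),
                     retained = retained,
                     removed_correlated = pruned$removed,
                     vif = vifs),
    signature = list(lambda_min = fit$lambda_min,
                     n_terms = length(fit$beta),
                     terms = as.list(fit$beta),
                     constant = if (!null_signature) formula$constant,
                     flag = if (null_signature) "all_zero"),
    evaluation = list(training = eval_one(train),
                      validation = eval_one(valid),
                      cutoff = as.numeric(cutoff),
                      stratification_training = if (!is.null(strat_train))
                        strat_train[c("hr", "hr_ci", "log_rank_p")],
                      stratification_validation = if (!is.null(strat_valid))
                        strat_valid[c("hr", "hr_ci", "log_rank_p")]),
    lineage = list(
      fitted_on = "training",
      applied_to = "validation",
      stages = c(scaling = "training", screening = "training",
                 correlation_prune = "training", lambda = "training",
                 score_constant = "training", cutoff = "training",
                 nomogram_baseline = "training")),
    scores = list(training = train[c("patient_id", "score",
                                     "time_months", "event")],
                  validation = valid[c("patient_id", "score",
                                       "time_months", "event")]),
    dca = list(training = dca_train, validation = dca_valid)
  )
  class(report) <- "study_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(feats, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(report$scores$training,
                     file.path(out_dir, "scores_training.csv"),
                     row.names = FALSE)
    utils::write.csv(report$scores$validation,
                     file.path(out_dir, "scores_validation.csv"),
                     row.names = FALSE)
    if (!is.null(formula))
      write_formula(formula, file.path(out_dir, "formula.json"))
    json <- report
    json$scores <- NULL
    jsonlite::write_json(json, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         na = "null")
  }
  report
}
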