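make_scored_cohort <- function(n, beta = 1, seed = 1, rate = 0.03) {
  set.seed(seed)
  score <- rnorm(n)
  s <- generate_survival(beta * score,
                         survival_truth(baseline_rate = rate,
                                        censor_horizon = 120,
                                        censor_uniform_max = 400),
                         seed = seed + 100)
  data.frame(score = score, time = s$time_months, event = s$event)
}

test_that("an uninformative score predicts the marginal KM curve", {
  d <- make_scored_cohort(400, beta = 0, seed = 51)
  m <- build_nomogram(d$score, d$time, d$event)
  km <- km_estimate(d$time, d$event)
  for (sc in c(-1, 0, 1)) {
    pr <- predict_survival(m, sc, times = c(12, 36, 60))
    expect_equal(pr$surv, km$surv_at(c(12, 36, 60)), tolerance = 0.06)
  }
  # beta ~ 0: predictions nearly identical across scores
  p_lo <- predict_survival(m, min(d$score))$surv
  p_hi <- predict_survival(m, max(d$score))$surv
  expect_lt(max(abs(p_lo - p_hi)), 0.1)
})

test_that("predictions recover a known exponential truth", {
  # S(t | x) = exp(-rate * exp(x) * t): compare at the true generating rates
  d <- make_scored_cohort(800, beta = 1, seed = 52, rate = 0.02)
  m <- build_nomogram(d$score, d$time, d$event)
  for (x in c(-1, 0, 1)) {
    pr <- predict_survival(m, x, times = c(12, 36))
    truth <- exp(-0.02 * exp(1 * x) * c(12, 36))
    expect_equal(pr$surv, truth, tolerance = 0.07)
  }
})

test_that("the points mapping is affine from 0 to 100", {
  d <- make_scored_cohort(100, seed = 53)
  m <- build_nomogram(d$score, d$time, d$event)
  expect_equal(m$points(min(d$score)), 0)
  expect_equal(m$points(max(d$score)), 100)
  mid <- (min(d$score) + max(d$score)) / 2
  expect_equal(m$points(mid), 50)
})

test_that("median survival reports 'not reached' when the curve stays high", {
  # very low hazard: S never drops to 0.5 within follow-up
  d <- make_scored_cohort(150, beta = 0, seed = 54, rate = 0.001)
  m <- build_nomogram(d$score, d$time, d$event, min_events = 5)
  pr <- predict_survival(m, 0)
  expect_true(is.na(pr$median))
  # high hazard: median is an observed event time
  d2 <- make_scored_cohort(150, beta = 0, seed = 55, rate = 0.05)
  m2 <- build_nomogram(d2$score, d2$time, d2$event)
  pr2 <- predict_survival(m2, 0)
  expect_false(is.na(pr2$median))
  expect_true(pr2$median %in% m2$basehaz$time)
})

test_that("survival is monotone in time and in score", {
  d <- make_scored_cohort(300, beta = 1, seed = 56)
  m <- build_nomogram(d$score, d$time, d$event)
  pr <- predict_survival(m, 0.5, times = c(6, 12, 24, 48, 60))
  expect_true(all(diff(pr$surv) <= 0))
  s5 <- vapply(seq(-1.5, 1.5, by = 0.5),
               function(x) predict_survival(m, x, times = 60)$surv,
               numeric(1))
  expect_true(all(diff(s5) <= 0))  # higher score, lower 5-year survival
})

test_that("extrapolated scores are flagged", {
  d <- make_scored_cohort(100, seed = 57)
  m <- build_nomogram(d$score, d$time, d$event)
  expect_warning(pr <- predict_survival(m, max(d$score) + 10),
                 "outside the training range")
  expect_true(pr$extrapolated)
})

test_that("treat-all net benefit matches the closed form without censoring", {
  set.seed(58)
  n <- 300
  s <- generate_survival(rnorm(n), survival_truth(baseline_rate = 0.03,
                                                  censor_horizon = 1e6,
                                                  censor_uniform_max = 1e7),
                         seed = 59)
  tau <- 36
  rho <- mean(s$time_months <= tau)  # all events: plain prevalence
  risks <- runif(n)
  grid <- seq(0.05, 0.95, by = 0.05)
  dc <- decision_curve(risks, s$time_months, s$event, tau, grid)
  expect_equal(dc$nb_all, rho - (1 - rho) * grid / (1 - grid),
               tolerance = 1e-12)
  expect_true(all(dc$nb_none == 0))
  # p_t -> 0 limit: treat-all tends to the prevalence
  dc0 <- decision_curve(risks, s$time_months, s$event, tau, 1e-6)
  expect_equal(dc0$nb_all, rho, tolerance = 1e-4)
})

test_that("calibrated risks dominate treat-all on a mid-range grid", {
  set.seed(60)
  n <- 4000
  lp <- rnorm(n)
  s <- generate_survival(lp, survival_truth(baseline_rate = 0.02,
                                            censor_horizon = 1e6,
                                            censor_uniform_max = 1e7),
                         seed = 61)
  tau <- 36
  true_risk <- 1 - exp(-0.02 * exp(lp) * tau)  # exactly calibrated
  grid <- seq(0.2, 0.8, by = 0.1)
  dc <- decision_curve(true_risk, s$time_months, s$event, tau, grid)
  expect_true(all(dc$nb_model >= dc$nb_all - 1e-9))
  expect_true(all(dc$nb_model >= -1e-9))
})

test_that("empty positive groups yield zero benefit and a flag", {
  set.seed(62)
  s <- generate_survival(rep(0, 50), survival_truth(), seed = 63)
  dc <- decision_curve(rep(0.1, 50), s$time_months, s$event, 36,
                       c(0.05, 0.5))
  expect_equal(dc$nb_model[2], 0)
  expect_equal(attr(dc, "empty_positive"), 0.5)
})

test_that("strategy comparison needs a shared grid and finds dominance", {
  set.seed(64)
  n <- 600
  lp <- rnorm(n)
  s <- generate_survival(lp, survival_truth(baseline_rate = 0.02,
                                            censor_horizon = 120,
                                            censor_uniform_max = 400),
                         seed = 65)
  tau <- 60
  d <- data.frame(score = lp, time = s$time_months, event = s$event)
  m <- build_nomogram(d$score, d$time, d$event)
  risk_score <- predicted_risk(m, d$score, tau)
  # "clinical stage": the score coarsened to three bins loses information
  stage <- cut(d$score, breaks = quantile(d$score, c(0, 1/3, 2/3, 1)),
               include.lowest = TRUE, labels = FALSE)
  stage_score <- ave(d$score, stage)
  m2 <- build_nomogram(stage_score, d$time, d$event)
  risk_stage <- predicted_risk(m2, stage_score, tau)
  grid <- seq(0.15, 0.85, by = 0.05)
  dc_score <- decision_curve(risk_score, d$time, d$event, tau, grid)
  dc_stage <- decision_curve(risk_stage, d$time, d$event, tau, grid)
  cmp <- compare_strategies(dc_score, dc_stage)
  expect_true(!is.null(cmp$a_dominates))
  mid <- cmp$table$threshold >= 0.3 & cmp$table$threshold <= 0.7
  expect_gt(mean(cmp$table$diff[mid] >= 0), 0.5)
  # identical inputs: zero difference everywhere
  cmp0 <- compare_strategies(dc_score, dc_score)
  expect_true(all(cmp0$table$diff == 0))
  # disjoint grids are rejected
  dc_other <- decision_curve(risk_score, d$time, d$event, tau,
                             seq(0.1, 0.9, by = 0.1))
  expect_error(compare_strategies(dc_score, dc_other), "grid")
})
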