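test_that("perfectly anti-ordered scores give concordance 1", {
  # higher score = higher risk: the highest score dies first
  time <- c(1, 2, 3, 4, 5); event <- rep(1, 5)
  scores <- c(5, 4, 3, 2, 1)
  ci <- concordance_index(scores, time, event, n_boot = 0)
  expect_equal(ci$c_index, 1)
  expect_equal(ci$n_pairs, 10)
})

test_that("uninformative scores concord at chance", {
  set.seed(31)
  s <- generate_survival(rep(0, 500), survival_truth(), seed = 31)
  ci <- concordance_index(rnorm(500), s$time_months, s$event, n_boot = 50,
                          seed = 2)
  expect_gt(ci$c_index, 0.45)
  expect_lt(ci$c_index, 0.55)
  expect_length(ci$ci, 2)
  expect_lt(ci$ci[1], ci$c_index)
  expect_gt(ci$ci[2], ci$c_index)
})

test_that("concordance equals exhaustive pair enumeration with censoring", {
  # 5-patient table, one censored record
  time <- c(2, 4, 4, 7, 9)
  event <- c(1, 1, 0, 1, 1)
  scores <- c(0.9, 0.3, 0.7, 0.4, 0.1)
  ci <- concordance_index(scores, time, event, n_boot = 0)
  expect_equal(ci$c_index, oracle_cindex(scores, time, event))
  # and the survival-package implementation agrees (risk direction flipped)
  cf <- survival::concordance(survival::Surv(time, event) ~ scores,
                              reverse = TRUE)
  expect_equal(ci$c_index, unname(cf$concordance))
})

test_that("concordance is invariant under increasing score transforms", {
  set.seed(32)
  s <- generate_survival(rnorm(60), survival_truth(), seed = 33)
  sc <- rnorm(60)
  c1 <- concordance_index(sc, s$time_months, s$event, n_boot = 0)$c_index
  c2 <- concordance_index(exp(2 * sc) + 5, s$time_months, s$event,
                          n_boot = 0)$c_index
  expect_equal(c1, c2)
})

test_that("without censoring the time-dependent ROC is the empirical ROC", {
  time <- c(1, 2, 3, 4, 6, 7, 8, 9)
  event <- rep(1, 8)
  scores <- c(8, 7, 5, 6, 3, 4, 2, 1)
  tau <- 5
  roc <- time_dependent_roc(scores, time, event, tau)
  # cases: time <= 5 (4 patients), controls the rest; all weights equal
  labels <- as.integer(time <= tau)
  # Mann-Whitney fraction of correctly ordered case/control pairs
  pairs <- expand.grid(i = which(labels == 1), j = which(labels == 0))
  mw <- mean(scores[pairs$i] > scores[pairs$j]) +
    0.5 * mean(scores[pairs$i] == scores[pairs$j])
  expect_equal(roc$auc, mw)
  expect_equal(max(roc$youden), 1)  # this toy score separates perfectly
})

test_that("the time-dependent AUC is invariant to monotone transforms", {
  set.seed(34)
  s <- generate_survival(rnorm(80), survival_truth(), seed = 35)
  sc <- rnorm(80)
  a1 <- time_dependent_roc(sc, s$time_months, s$event, 36)$auc
  a2 <- time_dependent_roc(10 * sc^3 + sc, s$time_months, s$event, 36)$auc
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("a perfectly separating score has AUC 1 and Youden 1", {
  time <- c(1, 2, 3, 10, 11, 12)
  event <- c(1, 1, 1, 0, 0, 0)
  scores <- c(3, 2.5, 2, 1, 0.5, 0.2)
  roc <- time_dependent_roc(scores, time, event, 5)
  expect_equal(roc$auc, 1)
  cut <- youden_cutoff(roc)
  expect_equal(attr(cut, "youden"), 1)
  expect_gt(cut, 1); expect_lt(cut, 2)
})

test_that("the Youden cutoff lands between the separating scores", {
  time <- c(10, 9, 2, 1); event <- c(0, 0, 1, 1)
  scores <- c(1, 2, 3, 4)
  roc <- time_dependent_roc(scores, time, event, 5)
  cut <- youden_cutoff(roc)
  expect_equal(as.numeric(cut), 2.5)
  expect_equal(attr(cut, "youden"), 1)
})

test_that("Youden ties resolve toward higher specificity", {
  # two cutoffs reach the same J; the higher threshold must win
  time <- c(1, 2, 8, 9, 10); event <- c(1, 1, 0, 0, 0)
  scores <- c(5, 3, 4, 2, 1)
  roc <- time_dependent_roc(scores, time, event, 5)
  best_j <- max(roc$youden)
  cands <- roc$thresholds[roc$youden == best_j]
  cut <- youden_cutoff(roc)
  expect_gte(as.numeric(cut), max(cands))
})

test_that("an anti-predictive score is flagged as non-separating", {
  time <- c(1, 2, 9, 10); event <- c(1, 1, 0, 0)
  scores <- c(1, 2, 3, 4)  # reversed
  roc <- time_dependent_roc(scores, time, event, 5)
  cut <- youden_cutoff(roc)
  expect_identical(attr(cut, "flag"), "non_separating")
  expect_error(youden_cutoff(
    time_dependent_roc(c(1, 1, 1, 1) + 0 * time, time, event, 5)))
})

test_that("Kaplan-Meier reproduces hand product-limit computations", {
  km <- km_estimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv_at(2), 0.5)
  expect_equal(km$surv_at(3.5), 0.25)
  km_c <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_c$surv_at(3), 1)
  # 6-record mixed table: events at 2 (n=6), 4 (n=4), 7 (n=2);
  # censored at 3 and 5; S(7) = (5/6)(3/4)(1/2)
  km_m <- km_estimate(c(2, 3, 4, 5, 7, 8), c(1, 0, 1, 0, 1, 0))
  expect_equal(km_m$surv_at(2), 5 / 6)
  expect_equal(km_m$surv_at(4), 5 / 6 * 3 / 4)
  expect_equal(km_m$surv_at(7), 5 / 6 * 3 / 4 * 1 / 2)
  # KM with no censoring equals the empirical survivor function
  tt <- c(5, 1, 3, 2, 4)
  km_u <- km_estimate(tt, rep(1, 5))
  expect_equal(km_u$surv_at(3), mean(tt > 3))
})

test_that("the log-rank statistic matches the O-E hand formula", {
  # identical groups: chi-square 0, p 1
  t0 <- c(1, 2, 3, 4); e0 <- c(1, 1, 0, 1)
  lr0 <- log_rank(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)
  # small table evaluated by hand: O, E and V accumulated per event time
  time <- c(1, 2, 3, 4, 5, 6); event <- rep(1, 6)
  grp <- c("a", "b", "a", "b", "a", "b")
  oe <- 0; v <- 0
  for (t in sort(time[event == 1])) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp == "a")
    d <- sum(time == t & event == 1)
    o1 <- sum(time == t & event == 1 & grp == "a")
    oe <- oe + o1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  lr <- log_rank(time, event, grp)
  expect_equal(lr$chisq, oe^2 / v, tolerance = 1e-10)
})

test_that("the log-rank test detects a threefold rate difference", {
  hits <- 0
  for (seed in 1:20) {
    sa <- generate_survival(rep(0, 200),
                            survival_truth(baseline_rate = 0.03,
                                           censor_horizon = 120,
                                           censor_uniform_max = 500),
                            seed = seed)
    sb <- generate_survival(rep(log(3), 200),
                            survival_truth(baseline_rate = 0.03,
                                           censor_horizon = 120,
                                           censor_uniform_max = 500),
                            seed = seed + 400)
    lr <- log_rank(c(sa$time_months, sb$time_months),
                   c(sa$event, sb$event), rep(c("a", "b"), each = 200))
    hits <- hits + (lr$p < 0.001)
  }
  expect_gte(hits, 19)
})

test_that("stratification at a good cutoff yields a significant split", {
  for (seed in 1:5) {
    lp <- rnorm(200)
    s <- generate_survival(lp, survival_truth(baseline_rate = 0.02,
                                              censor_horizon = 120,
                                              censor_uniform_max = 400),
                          seed = 50 + seed)
    roc <- time_dependent_roc(lp, s$time_months, s$event, 60)
    cut <- youden_cutoff(roc)
    st <- stratify_by_cutoff(lp, s$time_months, s$event, cut)
    expect_gt(st$hr, 1)
    expect_lt(st$log_rank_p, 0.05)
    expect_equal(sort(unique(st$group)), c("high", "low"))
  }
})

test_that("multivariable Cox recovers a planted binary hazard ratio", {
  set.seed(36)
  x <- rbinom(1000, 1, 0.5)
  z <- rnorm(1000)
  s <- generate_survival(log(2) * x + 0.3 * z,
                         survival_truth(baseline_rate = 0.02,
                                        censor_horizon = 120,
                                        censor_uniform_max = 400),
                         seed = 37)
  d <- data.frame(time_months = s$time_months, event = s$event,
                  x = x, z = z)
  fit <- cox_multivariable(d, c("x", "z"), mode = "full")
  hr_x <- fit$full$hr[fit$full$term == "x"]
  expect_gt(hr_x, 1.7); expect_lt(hr_x, 2.3)
})

test_that("a duplicated covariate is flagged as unstable", {
  set.seed(38)
  s <- generate_survival(rnorm(100), survival_truth(), seed = 39)
  d <- data.frame(time_months = s$time_months, event = s$event,
                  a = rnorm(100))
  d$b <- d$a
  expect_warning(cox_multivariable(d, c("a", "b"), mode = "full"))
})

test_that("backward elimination empties a null model most of the time", {
  empty <- 0
  for (seed in 1:20) {
    set.seed(600 + seed)
    s <- generate_survival(rep(0, 150),
                           survival_truth(baseline_rate = 0.02,
                                          censor_horizon = 120,
                                          censor_uniform_max = 400),
                           seed = 700 + seed)
    d <- data.frame(time_months = s$time_months, event = s$event,
                    a = rnorm(150), b = rnorm(150), c = rnorm(150))
    fit <- cox_multivariable(d, c("a", "b", "c"), mode = "backward_LR")
    empty <- empty + (nrow(fit$final) == 0)
  }
  expect_gt(empty, 10)  # removal threshold 0.10 per covariate
})

test_that("backward elimination keeps a strong predictor", {
  set.seed(40)
  x <- rnorm(300)
  s <- generate_survival(0.9 * x, survival_truth(baseline_rate = 0.02,
                                                 censor_horizon = 120,
                                                 censor_uniform_max = 400),
                         seed = 41)
  d <- data.frame(time_months = s$time_months, event = s$event, x = x,
                  junk = rnorm(300))
  fit <- cox_multivariable(d, c("x", "junk"), mode = "backward_LR")
  expect_true("x" %in% fit$final$term)
  expect_false("junk" %in% fit$final$term)
  expect_equal(fit$removed, "junk")
})

test_that("balance tests reproduce the degenerate and printed cases", {
  a <- data.frame(sex = rep(c("M", "F"), c(50, 25)), age = rnorm(75, 60))
  b <- a
  out <- cohort_balance(a, b, c(categorical = "sex", continuous = "age"))
  expect_equal(out$p, c(1, 1))
  expect_equal(out$statistic, c(0, 0), tolerance = 1e-12)
  # published male/female split: 77/22 vs 42/13 -> p = 0.841
  a2 <- data.frame(sex = rep(c("M", "F"), c(77, 22)))
  b2 <- data.frame(sex = rep(c("M", "F"), c(42, 13)))
  out2 <- cohort_balance(a2, b2, c(categorical = "sex"))
  expect_equal(out2$p, 0.841, tolerance = 5e-4)
})
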