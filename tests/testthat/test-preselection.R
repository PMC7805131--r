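# synthetic feature-matrix cohorts (no imaging) for the screening cascade
make_feature_cohort <- function(n, betas, n_noise = 10, seed = 1,
                                baseline = 0.02) {
  set.seed(seed)
  k <- length(betas)
  x <- matrix(rnorm(n * (k + n_noise)), n)
  colnames(x) <- c(sprintf("sig%02d", seq_len(k)),
                   sprintf("noise%02d", seq_len(n_noise)))
  lp <- as.vector(x[, seq_len(k), drop = FALSE] %*% betas)
  s <- generate_survival(lp, survival_truth(baseline_rate = baseline,
                                            censor_horizon = 120,
                                            censor_uniform_max = 500),
                         seed = seed + 1)
  cbind(data.frame(time_months = s$time_months, event = s$event),
        as.data.frame(x))
}

test_that("a planted risk factor passes the univariable screen", {
  d <- make_feature_cohort(500, betas = 0.8, seed = 2)
  sc <- univariable_cox_screen(d, c("sig01", paste0("noise0", 1:5)))
  expect_true(sc$kept[sc$feature == "sig01"])
  expect_lt(sc$p[sc$feature == "sig01"], 1e-6)
  expect_gt(sc$hr[sc$feature == "sig01"], 1)
})

test_that("pure-noise features are kept at roughly the nominal 25% rate", {
  hits <- 0
  for (r in 1:100) {
    d <- make_feature_cohort(120, betas = 0, n_noise = 1, seed = 100 + r)
    sc <- univariable_cox_screen(d, "noise01")
    hits <- hits + sc$kept[1]
  }
  expect_gt(hits / 100, 0.15)
  expect_lt(hits / 100, 0.35)
})

test_that("constant features are dropped with a warning and p = 1", {
  d <- make_feature_cohort(80, betas = 0.5, seed = 3)
  d$flat <- 1
  expect_warning(sc <- univariable_cox_screen(d, c("sig01", "flat")),
                 "constant")
  expect_false(sc$kept[sc$feature == "flat"])
  expect_equal(sc$p[sc$feature == "flat"], 1)
  expect_true(sc$constant[sc$feature == "flat"])
})

test_that("screening requires events", {
  d <- make_feature_cohort(30, betas = 0, seed = 4)
  d$event <- 0
  expect_error(univariable_cox_screen(d, "noise01"), "event")
})

test_that("the keep-set shrinks as the screening threshold tightens", {
  d <- make_feature_cohort(150, betas = c(0.8, 0.4), n_noise = 20, seed = 5)
  feats <- setdiff(names(d), c("time_months", "event"))
  kept <- vapply(c(0.5, 0.25, 0.1, 0.01), function(th)
    sum(univariable_cox_screen(d, feats, p_threshold = th)$kept),
    numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("of a perfectly correlated pair, the weaker one is pruned", {
  d <- make_feature_cohort(200, betas = 0.8, n_noise = 2, seed = 6)
  d$twin <- d$sig01  # r = 1 with the planted feature
  sc <- univariable_cox_screen(d, c("sig01", "twin", "noise01", "noise02"),
                               p_threshold = 1.1)  # keep everything
  pr <- correlation_prune(d, sc, r_threshold = 0.8)
  # identical columns tie in p; registry order keeps the earlier one
  expect_true("sig01" %in% pr$retained)
  expect_false("twin" %in% pr$retained)
  expect_equal(pr$removed, "twin")
})

test_that("one of three mutually correlated features survives", {
  set.seed(7)
  base <- rnorm(300)
  d <- make_feature_cohort(300, betas = 0.5, n_noise = 1, seed = 7)
  d$c1 <- base + rnorm(300, sd = 0.05)
  d$c2 <- base + rnorm(300, sd = 0.05)
  d$c3 <- base + rnorm(300, sd = 0.05)
  sc <- univariable_cox_screen(d, c("c1", "c2", "c3"), p_threshold = 1.1)
  pr <- correlation_prune(d, sc, r_threshold = 0.8)
  expect_length(pr$retained, 1)
  expect_length(pr$removed, 2)
})

test_that("an uncorrelated set passes pruning unchanged, and the pruned
           set never contains a correlated pair", {
  for (seed in 1:5) {
    d <- make_feature_cohort(150, betas = 0, n_noise = 12, seed = 20 + seed)
    feats <- setdiff(names(d), c("time_months", "event"))
    sc <- univariable_cox_screen(d, feats, p_threshold = 1.1)
    pr <- correlation_prune(d, sc, r_threshold = 0.8)
    r <- abs(cor(as.matrix(d[pr$retained])))
    diag(r) <- 0
    expect_lt(max(r), 0.8)
  }
  # independent columns at n=150 are essentially never pruned
  d <- make_feature_cohort(150, betas = 0, n_noise = 8, seed = 99)
  feats <- setdiff(names(d), c("time_months", "event"))
  sc <- univariable_cox_screen(d, feats, p_threshold = 1.1)
  expect_length(correlation_prune(d, sc)$removed, 0)
})

test_that("VIF matches the closed form from a known covariance", {
  # build columns with *exact* sample correlation via orthogonalisation
  set.seed(8)
  n <- 400
  # columns exactly zero-mean, unit-SD and mutually uncorrelated
  z <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n))))[, 2:4] * sqrt(n - 1)
  rho <- 0.6
  d <- data.frame(x1 = z[, 1],
                  x2 = rho * z[, 1] + sqrt(1 - rho^2) * z[, 2],
                  x3 = z[, 3])
  # x1 regressed on (x2, x3): R^2 = rho^2 -> VIF = 1/(1 - rho^2)
  v <- vif(d, c("x1", "x2", "x3"))
  expect_equal(unname(v["x1"]), 1 / (1 - rho^2), tolerance = 1e-8)
  expect_equal(unname(v["x3"]), 1, tolerance = 1e-8)
})

test_that("VIF flags independence, near-collinearity and exact collinearity", {
  set.seed(9)
  d <- data.frame(a = rnorm(300), b = rnorm(300), c = rnorm(300))
  expect_true(all(vif(d, c("a", "b", "c")) < 1.1))
  d$almost <- d$a + rnorm(300, sd = 0.01)
  expect_gt(vif(d, c("a", "almost", "b"))["a"], 10)
  d$copy <- d$a
  expect_equal(unname(vif(d, c("a", "copy", "b"))["copy"]), Inf)
})
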