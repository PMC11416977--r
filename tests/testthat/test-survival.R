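test_that("KM fit reproduces the hand product-limit example", {
  fit <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(fit$surv[fit$time == 1], 2 / 3)
  expect_equal(fit$surv[fit$time == 3], 0)
  expect_equal(fit$rmean, 1 + (2 / 3) * 2, tolerance = 1e-9)
  # no events: survival stays at 1
  f2 <- km_fit(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(f2$surv == 1))
  expect_equal(f2$rmean, 6)
  # all events at distinct times: S(t_(k)) = (n-k)/n
  f3 <- km_fit(1:5, rep(1, 5))
  expect_equal(f3$surv, (4:0) / 5)
})

test_that("KM with no censoring reproduces the empirical survival function", {
  set.seed(5)
  t <- round(rexp(40, 0.2), 2)
  fit <- km_fit(t, rep(1, 40))
  for (k in seq_along(fit$time))
    expect_equal(fit$surv[k], mean(t > fit$time[k]), tolerance = 1e-12)
})

test_that("identical groups give null log-rank and Breslow tests", {
  t <- rep(c(1, 2, 3, 4), 2)
  e <- rep(1, 8)
  g <- rep(c("a", "b"), each = 4)
  res <- compare_survival(t, e, g)
  expect_equal(res$logrank_chisq, 0, tolerance = 1e-9)
  expect_equal(res$breslow_chisq, 0, tolerance = 1e-9)
  expect_equal(res$logrank_p, 1, tolerance = 1e-6)
  expect_equal(res$breslow_p, 1, tolerance = 1e-6)
})

test_that("log-rank beats Breslow under late-separating proportional hazards", {
  lr_rej <- 0; br_rej <- 0
  for (seed in 1:200) {
    set.seed(seed)
    n <- 100
    t1 <- rexp(n, 0.1); t2 <- rexp(n, 0.05)  # HR = 0.5
    t <- c(t1, t2); e <- rep(1, 2 * n)
    g <- rep(c(0, 1), each = n)
    res <- compare_survival(t, e, g)
    lr_rej <- lr_rej + (res$logrank_p < 0.05)
    br_rej <- br_rej + (res$breslow_p < 0.05)
  }
  expect_gt(lr_rej, br_rej)
  expect_gt(lr_rej / 200, 0.8)
})

test_that("Breslow is more sensitive than log-rank to early differences", {
  # one arm suffers an early excess of events, after which the hazards
  # coincide: the number-at-risk weighting concentrates on the early
  # informative phase
  wins <- 0
  for (seed in 1:60) {
    set.seed(seed)
    n <- 80
    burst <- runif(n) < 0.25
    g0 <- ifelse(burst, runif(n, 0, 0.4), 0.5 + rexp(n, 0.1))
    g1 <- 0.5 + rexp(n, 0.1)
    t <- c(g0, g1); e <- rep(1, 2 * n)
    g <- rep(c(0, 1), each = n)
    res <- compare_survival(t, e, g)
    wins <- wins + (res$breslow_p < res$logrank_p)
  }
  expect_gt(wins / 60, 0.5)
})

test_that("Cox coefficient matches 1-D partial-likelihood grid search", {
  set.seed(6)
  n <- 40
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, 0.1 * exp(0.8 * x))
  e <- rep(1, n)
  fit <- cox_fit(cbind(x = x), t, e)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, bf_cox_loglik, numeric(1), x = x, times = t,
               events = e)
  expect_equal(unname(fit$coef), grid[which.max(ll)], tolerance = 1e-3)
  expect_equal(unname(fit$hr), exp(grid[which.max(ll)]), tolerance = 1e-3)
})

test_that("Cox confidence intervals cover a null covariate about 95% of the time", {
  cover <- 0
  for (seed in 1:60) {
    set.seed(seed)
    n <- 120
    x <- rnorm(n)
    t <- rexp(n, 0.1)
    fit <- cox_fit(cbind(x = x), t, rep(1, n))
    lo <- exp(fit$coef - 1.96 * fit$se)
    hi <- exp(fit$coef + 1.96 * fit$se)
    if (lo <= 1 && hi >= 1) cover <- cover + 1
  }
  expect_gt(cover / 60, 0.85)
})

test_that("Cox estimator is nearly unbiased at n = 500 under the generator", {
  ests <- vapply(1:10, function(seed) {
    clin <- sample_ici_clinical(cohort_spec(n_cases = 500,
                                            survival_link = log(0.5),
                                            censoring_rate = 0,
                                            seed = seed))
    z <- scale(clin$cd8_pct)[, 1]
    unname(cox_fit(cbind(z = z), clin$pfs_months, clin$event)$coef)
  }, numeric(1))
  expect_lt(abs(mean(ests) - log(0.5)) / abs(log(0.5)), 0.1)
})

test_that("degenerate covariates are rejected", {
  t <- rexp(20, 0.1); e <- rep(1, 20); x <- rnorm(20)
  expect_error(cox_fit(cbind(a = x, b = x), t, e), "rank")
  expect_error(cox_fit(cbind(a = rep(1, 20)), t, e), "constant")
})

test_that("risk-score AUC is centering-invariant and null-calibrated", {
  set.seed(8)
  clin <- sample_ici_clinical(cohort_spec(n_cases = 101,
                                          survival_link = log(0.2),
                                          seed = 31))
  z <- scale(clin$cd8_pct)[, 1]
  fit <- cox_fit(cbind(z = z), clin$pfs_months, clin$event)
  y12 <- encode_pfs12(clin$pfs_months, clin$event)
  r1 <- cox_risk_auc(fit, y12)
  fit2 <- cox_fit(cbind(z = z + 100), clin$pfs_months, clin$event)
  r2 <- cox_risk_auc(fit2, y12)
  expect_equal(r1$auc, r2$auc, tolerance = 1e-9)
  expect_gt(r1$auc, 0.7)  # strong planted effect discriminates
  # null link: chance-level risk AUC on average
  aucs <- vapply(1:10, function(seed) {
    c0 <- sample_ici_clinical(cohort_spec(n_cases = 101, survival_link = 0,
                                          seed = seed))
    z0 <- scale(c0$cd8_pct)[, 1]
    f0 <- cox_fit(cbind(z = z0), c0$pfs_months, c0$event)
    cox_risk_auc(f0, encode_pfs12(c0$pfs_months, c0$event))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("strong planted CD8 effect yields high risk AUC in most seeds", {
  hits <- 0
  for (seed in 1:20) {
    clin <- sample_ici_clinical(cohort_spec(n_cases = 101,
                                            survival_link = log(0.2),
                                            seed = seed))
    z <- scale(clin$cd8_pct)[, 1]
    fit <- cox_fit(cbind(z = z), clin$pfs_months, clin$event)
    auc <- cox_risk_auc(fit, encode_pfs12(clin$pfs_months,
                                          clin$event))$auc
    if (auc >= 0.8) hits <- hits + 1
  }
  expect_gt(hits / 20, 0.5)
})
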