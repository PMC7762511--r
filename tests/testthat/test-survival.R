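test_that("Kaplan-Meier estimate matches hand-computed products", {
  # n = 2, deaths at t = 1 and 2: S = (1 - 1/2), then * (1 - 1/1)
  k <- km_estimate(c(1, 2), c(1, 1))
  expect_equal(k$surv, c(0.5, 0))

  # censoring reduces the risk set only
  k2 <- km_estimate(c(1, 2, 3, 4, 5), c(1, 0, 1, 1, 0))
  expect_equal(k2$time, c(1, 3, 4))
  expect_equal(k2$surv, c(4 / 5, 4 / 5 * 2 / 3, 4 / 5 * 2 / 3 * 1 / 2))

  # all censored: S identically 1
  k3 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_equal(nrow(k3), 0L)
  expect_equal(km_surv(k3, c(0, 2, 10)), c(1, 1, 1))

  # duplicating every record leaves the estimator unchanged
  t <- c(1, 2, 2, 3, 5); e <- c(1, 0, 1, 1, 0)
  expect_equal(km_estimate(c(t, t), c(e, e))$surv, km_estimate(t, e)$surv)

  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank test matches the hand example and basic contracts", {
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(lr$chi_square, 2.88, tolerance = 0.01)
  expect_equal(lr$p_value, 0.089, tolerance = 0.01)
  expect_equal(lr$df, 1L)

  # identical groups: no signal
  t <- c(1, 3, 5, 7); e <- c(1, 0, 1, 1)
  lr0 <- logrank_test(c(t, t), c(e, e), rep(c("A", "B"), each = 4))
  expect_equal(lr0$chi_square, 0)
  expect_equal(lr0$p_value, 1)

  # three groups: df contract
  set.seed(2)
  lr3 <- logrank_test(rexp(30), rbinom(30, 1, 0.7), rep(1:3, each = 10))
  expect_equal(lr3$df, 2L)

  expect_error(logrank_test(1:4, rep(1, 4), rep("A", 4)), "2 groups")
})

test_that("log-rank is invariant to relabeling and time shifts", {
  set.seed(8)
  t <- rexp(60); e <- rbinom(60, 1, 0.7)
  g <- sample(c("a", "b", "c"), 60, TRUE)
  lr <- logrank_test(t, e, g)
  relab <- c(a = "z", b = "x", c = "y")[g]
  expect_equal(logrank_test(t, e, relab)$chi_square, lr$chi_square)
  expect_equal(logrank_test(t + 5, e, g)$chi_square, lr$chi_square)
})

test_that("log-rank agrees with survival::survdiff", {
  skip_if_not_installed("survival")
  set.seed(17)
  t <- rexp(80); e <- rbinom(80, 1, 0.6)
  g <- sample(c("a", "b", "c"), 80, TRUE)
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  expect_equal(logrank_test(t, e, g)$chi_square, sd$chisq, tolerance = 1e-8)
})

test_that("cox_fit maximizes the partial likelihood (grid-search oracle)", {
  times <- c(2, 4, 6, 8, 10, 12, 14, 16)
  events <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 1, 1, 0, 0, 1, 0, 0)
  fit <- cox_fit(times, events, cbind(x = x))
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, function(b) oracle_cox_loglik(times, events, x, b),
               numeric(1))
  expect_equal(fit$table$beta, grid[which.max(ll)], tolerance = 2e-4,
               ignore_attr = TRUE)
  expect_true(fit$converged)
  # the fitted log partial likelihood matches the oracle at beta-hat
  expect_equal(fit$loglik,
               oracle_cox_loglik(times, events, x, fit$table$beta),
               tolerance = 1e-8)
})

test_that("cox_fit agrees with survival::coxph under both tie methods", {
  skip_if_not_installed("survival")
  set.seed(12)
  n <- 120
  X <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5), c = runif(n))
  t <- round(rexp(n, exp(0.4 * X[, 1] - 0.5 * X[, 2])), 1)  # induce ties
  e <- rbinom(n, 1, 0.7)
  for (tm in c("efron", "breslow")) {
    fit <- cox_fit(t, e, X, tie_method = tm)
    ref <- survival::coxph(survival::Surv(t, e) ~ X, ties = tm)
    expect_equal(fit$table$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$table$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  }
})

test_that("cox_fit CI/HR structure and time-scaling invariance hold", {
  set.seed(3)
  n <- 100
  x <- rnorm(n)
  t <- rexp(n, exp(0.5 * x)); e <- rbinom(n, 1, 0.8)
  fit <- cox_fit(t, e, cbind(x = x))
  expect_true(fit$table$ci_lower < fit$table$hr &&
                fit$table$hr < fit$table$ci_upper)
  expect_gt(fit$table$hr, 0)
  fit2 <- cox_fit(2 * t, e, cbind(x = x))
  expect_equal(fit2$table$beta, fit$table$beta, tolerance = 1e-7)
})

test_that("cox_fit is near the null under identical group distributions", {
  set.seed(4)
  n <- 200
  g <- rep(0:1, each = n / 2)
  t <- rexp(n); e <- rbinom(n, 1, 0.7)   # survival independent of g
  fit <- cox_fit(t, e, cbind(g = g))
  expect_lt(abs(fit$table$beta), 0.15)
})

test_that("score test at beta = 0 equals the two-group log-rank chi-square", {
  set.seed(21)
  n <- 50
  t <- rexp(n)                         # continuous: no ties
  e <- rbinom(n, 1, 0.7)
  g <- rbinom(n, 1, 0.5)
  st <- cox_score_test(t, e, cbind(g))
  lr <- logrank_test(t, e, g)
  expect_equal(st$chi_square, lr$chi_square, tolerance = 1e-6)
})

test_that("cox_fit flags degenerate inputs instead of failing silently", {
  expect_error(cox_fit(1:10, rep(1, 10), cbind(k = rep(1, 10))), "constant")
  expect_error(cox_fit(1:4, c(1, 0, 0, 0),
                       cbind(a = rnorm(4), b = rnorm(4))), "fewer events")
  # perfect separation: group 0 dies first, group 1 never before
  t <- c(1, 2, 3, 4, 10, 11, 12, 13)
  e <- rep(1, 8)
  g <- c(0, 0, 0, 0, 1, 1, 1, 1)
  fit <- cox_fit(t, e, cbind(g = g))
  expect_equal(fit$flag, "monotone_likelihood")
})
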