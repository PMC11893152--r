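test_that("OLS recovers exact fits and standard identities", {
  x <- 1:20
  f <- fit_linear(2 * x, cbind(intercept = 1, x = x))
  expect_equal(unname(f$coefficients), c(0, 2), tolerance = 1e-12)
  expect_equal(f$residual_variance, 0, tolerance = 1e-20)

  # slope on a two-group indicator equals the difference of group means
  set.seed(21)
  grp <- rep(0:1, each = 30); y <- rnorm(60) + grp
  f2 <- fit_linear(y, cbind(intercept = 1, grp = grp))
  expect_equal(unname(f2$coefficients["grp"]),
               mean(y[grp == 1]) - mean(y[grp == 0]))

  # residuals orthogonal to every design column
  X <- cbind(intercept = 1, a = rnorm(60), b = runif(60))
  f3 <- fit_linear(y, X)
  expect_lt(max(abs(crossprod(X, f3$residuals))), 1e-9)

  # agreement with lm as an independent route
  lmfit <- lm(y ~ X - 1)
  expect_equal(unname(f3$coefficients), unname(coef(lmfit)), tolerance = 1e-10)
  expect_equal(unname(f3$se),
               unname(sqrt(diag(vcov(lmfit)))), tolerance = 1e-10)
})

test_that("OLS on pure noise finds no slope and flags rank problems", {
  set.seed(8)
  x <- rnorm(1000); y <- rnorm(1000)
  f <- fit_linear(y, cbind(intercept = 1, x = x))
  expect_lt(abs(f$coefficients[["x"]]), 3 * f$se[["x"]])
  expect_error(fit_linear(y, cbind(intercept = 1, x = x, x2 = 2 * x)),
               "collinear.*x2")
  expect_error(fit_linear(1:3, cbind(a = 1:3, b = 4:6, c = 7:9, d = 1:3)),
               "n > p")
})

test_that("Wald inference matches the normal tail exactly", {
  w0 <- wald(0, 1)
  expect_equal(w0$p, 1)
  expect_equal(w0$ci_low, -w0$ci_high)
  expect_equal(wald(1.959964, 1)$p, 0.05, tolerance = 1e-6)
  expect_equal(wald(2.51, 1)$p, 2 * pnorm(-2.51))
  expect_equal(wald(2.51, 1)$p, 0.01207, tolerance = 1e-3)
  expect_error(wald(1, 0), "se")
  expect_error(wald(1, -1), "se")
})

test_that("Cox coefficients maximize the grid-searched partial likelihood", {
  co <- tiny_cohorts()[[1]]
  fit <- fit_cox(co$time, co$event, cbind(x = co$x))
  expect_equal(fit$coefficients[["x"]],
               oracle_grid_cox(co$time, co$event, co$x), tolerance = 2e-3)
  expect_equal(fit$loglik,
               oracle_breslow_loglik(co$time, co$event, co$x,
                                     fit$coefficients),
               tolerance = 1e-8)
})

test_that("Cox fit agrees with survival::coxph under Breslow ties", {
  co <- small_test_cohort(n = 3000, hr50_a = 0.8)
  X <- cbind(score = as.numeric(co$scores$lpa),
             adjustment_design(co$data))
  y <- co$data
  fit <- fit_cox(y$time_cvd, y$event_cvd, X)
  ref <- survival::coxph(survival::Surv(y$time_cvd, y$event_cvd) ~ X,
                         ties = "breslow")
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-6)
})

test_that("Cox estimates are rank-based: invariant to monotone time transforms", {
  co <- tiny_cohorts()[[3]]
  X <- cbind(x = co$x)
  b0 <- fit_cox(co$time, co$event, X)$coefficients
  b_shift <- fit_cox(co$time + 100, co$event, X)$coefficients
  b_mono <- fit_cox(exp(co$time / 2), co$event, X)$coefficients
  expect_equal(b0, b_shift, tolerance = 1e-8)
  expect_equal(b0, b_mono, tolerance = 1e-8)
})

test_that("score test at beta = 0 equals the log-rank statistic without censoring", {
  set.seed(14)
  n <- 60
  x <- rep(0:1, each = n / 2)
  time <- rexp(n, 0.1 * exp(0.7 * x))
  event <- rep(1L, n)
  sc <- cox_score_test(time, event, cbind(x = x))
  lr <- survival::survdiff(survival::Surv(time, event) ~ x)$chisq
  expect_equal(sc, unname(lr), tolerance = 1e-8)
})

test_that("Cox validation catches degenerate designs and missing events", {
  t <- c(1, 2, 3, 4); e <- c(1, 0, 1, 1)
  expect_error(fit_cox(t, e, cbind(x = rep(0, 4))), "collinear")
  expect_error(fit_cox(t, rep(0, 4), cbind(x = rnorm(4))), "no events")
  expect_error(fit_cox(c(-1, 2, 3, 4), e, cbind(x = rnorm(4))), "> 0")
})

test_that("monotone likelihood (perfect separation) is flagged, not silent", {
  # covariate perfectly orders events before censorings
  time <- c(1, 2, 3, 10, 11, 12)
  event <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)
  fit <- fit_cox(time, event, cbind(x = x))
  expect_false(fit$converged)
})

test_that("null covariates stay within 3 SE of zero in 95% of replicates", {
  set.seed(31)
  inside <- logical(200)
  for (r in 1:200) {
    n <- 5000
    x <- rnorm(n)
    time <- rexp(n, 0.05)
    event <- as.integer(time <= 10)
    fit <- fit_cox(pmin(time, 10), event, cbind(x = x))
    inside[r] <- abs(fit$coefficients) < 3 * fit$se
  }
  expect_gte(mean(inside), 0.95)
})
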