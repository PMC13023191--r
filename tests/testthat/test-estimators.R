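test_that("logistic kernel matches the glm oracle", {
  # 8-row fixture
  y8 <- c(0, 1, 0, 1, 1, 0, 1, 1)
  z8 <- c(0, 0, 1, 1, 0, 1, 1, 0)
  f <- fit_logistic(y8, list(z = z8))
  expect_equal(unname(f$coefficients), unname(oracle_logistic(y8, list(z = z8))),
               tolerance = 1e-6)
  # larger simulated design with two regressors
  set.seed(7)
  z <- rbinom(500, 1, 0.4)
  u <- rnorm(500)
  y <- rbinom(500, 1, plogis(-0.3 + 0.9 * z + 0.5 * u))
  f <- fit_logistic(y, list(z = z, u = u))
  orc <- oracle_logistic(y, list(z = z, u = u))
  expect_equal(unname(f$coefficients), unname(orc), tolerance = 1e-6)
  expect_true(f$converged)
  expect_equal(f$n_used, 500L)
  expect_true(all(f$fitted_values > 0 & f$fitted_values < 1))
  # standard errors agree with glm's
  df <- data.frame(y = y, z = z, u = u)
  g <- stats::glm(y ~ z + u, family = stats::binomial(), data = df)
  expect_equal(unname(f$standard_errors), unname(sqrt(diag(stats::vcov(g)))),
               tolerance = 1e-4)
})

test_that("logistic kernel recovers generating parameters at scale", {
  set.seed(17)
  n <- 1e5
  z <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(0.5 + 1.0 * z))
  f <- fit_logistic(y, list(z = z))
  expect_true(all(abs(f$coefficients - c(0.5, 1.0)) < 3 * f$standard_errors))
})

test_that("degenerate logistic inputs are reported, not silently fit", {
  set.seed(5)
  z <- rbinom(100, 1, 0.5)
  # perfect separation: response equals a regressor
  f <- fit_logistic(z, list(z = z))
  expect_false(f$converged)
  expect_error(fit_logistic(rep(1, 50), list(z = rbinom(50, 1, 0.5))),
               "constant")
  expect_error(fit_logistic(z, list(a = z, b = z)), "rank-deficient")
  expect_error(fit_logistic(c(0, 1, 2, 1), list(z = c(0, 1, 0, 1))), "0 and 1")
})

test_that("linear probability kernel is exact least squares", {
  # slope on a binary regressor = difference in group means
  z <- rep(c(0, 1), each = 10)
  y <- c(rep(c(1, 0, 0, 0, 0), 2), rep(c(1, 1, 0, 0), length.out = 10))
  f <- fit_lpm(y, list(z = z))
  expect_equal(unname(f$coefficients["z"]),
               mean(y[z == 1]) - mean(y[z == 0]), tolerance = 1e-12)
  # identity case
  f2 <- fit_lpm(z, list(z = z))
  expect_equal(unname(f2$coefficients), c(0, 1), tolerance = 1e-12)
  # 12-row fixture vs closed-form normal equations
  set.seed(9)
  z12 <- rbinom(12, 1, 0.5)
  u12 <- rnorm(12)
  y12 <- rbinom(12, 1, 0.5)
  f3 <- fit_lpm(y12, list(z = z12, u = u12))
  expect_equal(unname(f3$coefficients),
               unname(oracle_ols(y12, list(z = z12, u = u12))),
               tolerance = 1e-10)
})

test_that("prevalence transformation and its inverse are exact", {
  expect_equal(transform_coefficient(1, 0.5), 0.25)
  expect_equal(transform_coefficient(0, 0.37), 0)
  expect_equal(transform_coefficient(-2, 0.2), -0.32)
  expect_equal(inverse_transform(0.25, 0.5), 1)
  expect_equal(inverse_transform(0, 0.9), 0)
  expect_error(transform_coefficient(1, 0), "pr")
  expect_error(inverse_transform(1, 1), "pr")
  for (b in seq(-3, 3, by = 0.5)) {
    for (p in seq(0.05, 0.95, by = 0.1)) {
      expect_equal(inverse_transform(transform_coefficient(b, p), p), b,
                   tolerance = 1e-12)
    }
  }
})

test_that("Wald ratio via logistic regression has its structural identities", {
  fx <- mr_fixture_20()
  # X = Y elementwise: both regressions coincide, ratio is exactly 1
  same <- list(Z = fx$Z, X = fx$X, Y = fx$X)
  expect_equal(wald_logistic(same)$estimate, 1, tolerance = 1e-9)
  # instrument recoding flips both slopes, leaving every Wald ratio invariant
  flipped <- list(Z = 1 - fx$Z, X = fx$X, Y = fx$Y)
  for (est in list(wald_logistic, wald_lpm, wald_transformation)) {
    expect_equal(est(flipped)$estimate, est(fx)$estimate, tolerance = 1e-8)
  }
  # ratio of two independent oracle logistic fits
  w <- wald_logistic(fx)
  a1 <- oracle_logistic(fx$X, list(Z = fx$Z))["Z"]
  g1 <- oracle_logistic(fx$Y, list(Z = fx$Z))["Z"]
  expect_equal(w$estimate, unname(g1 / a1), tolerance = 1e-6)
  expect_equal(w$numerator, unname(g1), tolerance = 1e-6)
  expect_equal(w$denominator, unname(a1), tolerance = 1e-6)
})

test_that("LPM Wald ratio composes OLS slopes with the inverse transformation", {
  # constructed group means: exposure prevalences 0.3/0.5, outcome 0.45/0.55
  Z <- rep(c(0, 1), each = 20)
  X <- c(rep(1, 6), rep(0, 14), rep(1, 10), rep(0, 10))
  Y <- c(rep(1, 9), rep(0, 11), rep(1, 11), rep(0, 9))
  w <- wald_lpm(list(Z = Z, X = X, Y = Y))
  expect_equal(w$pr_y, 0.5)
  expect_equal(w$estimate, (0.1 / 0.2) / 0.25, tolerance = 1e-10)
  # zero numerator gives a zero estimate
  Y0 <- rep(c(1, 0), 20)
  expect_equal(wald_lpm(list(Z = Z, X = X, Y = Y0))$estimate, 0,
               tolerance = 1e-10)
  # fixture vs oracle OLS + inverse transform
  fx <- mr_fixture_20()
  w2 <- wald_lpm(fx)
  a1 <- unname(oracle_ols(fx$X, list(Z = fx$Z))[2])
  g1 <- unname(oracle_ols(fx$Y, list(Z = fx$Z))[2])
  expect_equal(w2$estimate, (g1 / a1) / (mean(fx$Y) * (1 - mean(fx$Y))),
               tolerance = 1e-10)
})

test_that("transformation Wald ratio reduces to its algebraic composition", {
  fx <- mr_fixture_20()
  wt <- wald_transformation(fx)
  wl <- wald_logistic(fx)
  pr_x <- mean(fx$X)
  # the Y-prevalence factors cancel: estimate = logistic ratio / (pr_x(1-pr_x))
  expect_equal(wt$estimate, wl$estimate / (pr_x * (1 - pr_x)),
               tolerance = 1e-9)
  expect_equal(wt$pr_x, pr_x)
  expect_equal(wt$pr_y, mean(fx$Y))
  # with equal sample prevalences the identity holds at the common prevalence
  bal <- list(Z = fx$Z, X = fx$X, Y = rev(fx$X))
  expect_equal(mean(bal$X), mean(bal$Y))
  pv <- mean(bal$X) * (1 - mean(bal$X))
  expect_equal(wald_transformation(bal)$estimate,
               wald_logistic(bal)$estimate / pv, tolerance = 1e-9)
  # zero numerator gives a zero estimate
  Ynull <- rep(rep(c(1, 0), 5), 2)
  expect_equal(wald_transformation(list(Z = fx$Z, X = fx$X,
                                        Y = Ynull))$estimate, 0,
               tolerance = 1e-10)
})

test_that("IV estimators match hand-composed oracle fits", {
  fx <- mr_fixture_20()
  # SEM: logistic Y ~ X
  sem <- estimate_sem(fx)
  expect_equal(sem$estimate, unname(oracle_logistic(fx$Y, list(X = fx$X))["X"]),
               tolerance = 1e-6)
  # TSPS: logistic Y ~ fitted first-stage probabilities
  cf1 <- oracle_logistic(fx$X, list(Z = fx$Z))
  phat <- plogis(cf1[1] + cf1[2] * fx$Z)
  tsps <- estimate_tsps(fx)
  expect_equal(tsps$estimate,
               unname(oracle_logistic(fx$Y, list(Phat = phat))["Phat"]),
               tolerance = 1e-5)
  # TSRI: logistic Y ~ X + residual; estimate is the X coefficient
  ehat <- fx$X - phat
  tsri <- estimate_tsri(fx)
  orc <- oracle_logistic(fx$Y, list(X = fx$X, e = ehat))
  expect_equal(tsri$estimate, unname(orc["X"]), tolerance = 1e-5)
  expect_equal(tsri$residual_coefficient, unname(orc["e"]), tolerance = 1e-5)
  # with covariates in both stages
  fc <- mr_fixture_cov()
  sem_c <- estimate_sem(fc$data, fc$covariates)
  orc_c <- oracle_logistic(fc$data$Y, c(list(X = fc$data$X),
                                        as.list(fc$covariates)))
  expect_equal(sem_c$estimate, unname(orc_c["X"]), tolerance = 1e-6)
})

test_that("TSRI with a null residual collapses onto the SEM fit", {
  fx <- mr_fixture_20()
  # composing stage 2 with the residual forced to zero leaves logistic Y ~ X
  direct <- fit_logistic(fx$Y, list(X = fx$X))
  sem <- estimate_sem(fx)
  expect_equal(sem$estimate, unname(direct$coefficients["X"]),
               tolerance = 1e-12)
})

test_that("degenerate estimator inputs yield valid = FALSE, user errors stop", {
  set.seed(13)
  Z <- rbinom(200, 1, 0.3)
  X <- rbinom(200, 1, plogis(0.5 * Z))
  # Y identical to X: outcome stage is perfectly separated
  sem <- estimate_sem(list(Z = Z, X = X, Y = X))
  expect_false(sem$valid)
  expect_true(is.na(sem$estimate))
  # constant-zero covariate column is a user error
  expect_error(estimate_tsps(list(Z = Z, X = X,
                                  Y = rbinom(200, 1, 0.5)),
                             covariates = data.frame(c0 = rep(0, 200))),
               "rank-deficient")
  # constant instrument: no estimator can proceed, all flagged invalid
  const <- list(Z = rep(1, 100), X = rbinom(100, 1, 0.5),
                Y = rbinom(100, 1, 0.5))
  expect_false(wald_logistic(const)$valid)
  expect_false(estimate_tsps(const)$valid)
})

test_that("the pooled fast path agrees with the public estimators", {
  cfgs <- list(sim_config(alpha1 = 0.7, beta1 = 1, n = 400, seed = 61,
                          n_reps = 3),
               sim_config(alpha1 = 0.01, beta1 = 0, cx = 1.5, cy = 1.5,
                          n = 400, seed = 62, n_reps = 3),
               sim_config(alpha1 = 0.1, beta1 = 1, cx = 1.5, cy = 1.5,
                          n = 400, seed = 63, n_reps = 3))
  for (cfg in cfgs) {
    for (r in 0:2) {
      d <- draw_dataset(cfg, r)
      pooled <- mr_estimates(d)
      single <- c(wald_logistic(d)$estimate, wald_lpm(d)$estimate,
                  wald_transformation(d)$estimate,
                  estimate_sem(d)$estimate, estimate_tsps(d)$estimate,
                  estimate_tsri(d)$estimate)
      expect_equal(pooled$estimate, single, tolerance = 1e-10)
    }
  }
})

test_that("estimator results serialize to a tidy CSV", {
  fx <- mr_fixture_20()
  path <- tempfile(fileext = ".csv")
  write_estimates_csv(list(wald_logistic(fx), estimate_tsri(fx)), path)
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 2)
  expect_true(all(c("method", "estimate", "valid") %in% names(back)))
  expect_equal(back$method, c("logistic", "tsri"))
})
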