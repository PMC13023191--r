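# Fitting kernels and causal-effect estimators.
#
# Every logistic stage in the package runs through .logistic_irls(), a lean
# iteratively-reweighted least-squares maximum-likelihood fit sized for the
# small fixed designs used here (2-3 columns plus covariates, thousands of
# rows). All linear-probability stages run through .lpm_fit(), a QR
# least-squares fit. The user-facing estimators are thin compositions of
# these two kernels, so the simulation study and the applied workflow share
# the same arithmetic.

# ---- design handling --------------------------------------------------------

# Accepts a named list, data.frame or matrix of regressor columns and returns
# a numeric design matrix with an implicit leading intercept.
.build_design <- function(design, n = NULL) {
  if (is.null(design)) {
    if (is.null(n)) stop("empty design needs a row count", call. = FALSE)
    return(matrix(1, nrow = n, ncol = 1, dimnames = list(NULL, "(Intercept)")))
  }
  if (is.matrix(design)) design <- as.data.frame(design)
  if (is.list(design)) {
    lens <- lengths(design)
    if (length(unique(lens)) != 1L)
      stop("design columns must share a common length", call. = FALSE)
    design <- as.data.frame(design)
  }
  if (is.null(names(design)) || any(!nzchar(names(design))))
    stop("design columns must be named", call. = FALSE)
  m <- as.matrix(design)
  storage.mode(m) <- "double"
  if (any(!is.finite(m)))
    stop("design contains non-finite values", call. = FALSE)
  cbind("(Intercept)" = 1, m)
}

.check_binary <- function(v, what) {
  if (!all(v %in% c(0, 1)))
    stop(sprintf("'%s' must contain only 0 and 1", what), call. = FALSE)
  invisible(v)
}

# column-sd on the design (intercept gets sd 1 so only slopes are scaled)
.design_scales <- function(x) {
  s <- apply(x, 2, stats::sd)
  s[1] <- 1
  s[s == 0] <- 1
  s
}

# ---- logistic kernel --------------------------------------------------------

# IRLS maximum likelihood for logistic regression. Returns coefficients,
# fitted probabilities, convergence flag and the final weighted cross-product
# (for standard errors). Separation is reported through 'separated': the fit
# failed to converge, or a standardized slope exceeds .sep_threshold while
# the linear predictor has drifted into the numerically-saturated region
# (|eta| > .eta_threshold, fitted probabilities within ~2e-9 of 0/1).
# Requiring both keeps legitimately large but finite estimates — e.g. the
# near-collinear exposure/residual pair of a weak-instrument TSRI stage —
# while still catching perfect prediction, where the estimates and the
# linear predictor diverge together. A rank-deficient system surfaces as
# ok = FALSE.
.sep_threshold <- 15
.eta_threshold <- 20
.irls_tol <- 1e-8
.irls_maxit <- 100L

.logistic_irls <- function(x, y, maxit = .irls_maxit, tol = .irls_tol) {
  p <- ncol(x)
  beta <- numeric(p)
  eta <- numeric(nrow(x))
  dev <- Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtwx <- crossprod(x, x * w)
    beta_new <- tryCatch(solve(xtwx, crossprod(x, w * z)),
                         error = function(e) NULL)
    if (is.null(beta_new))
      return(list(coefficients = rep(NA_real_, p), fitted = rep(NA_real_, nrow(x)),
                  converged = FALSE, separated = FALSE, ok = FALSE,
                  xtwx = NULL, iterations = it))
    beta <- drop(beta_new)
    eta <- drop(x %*% beta)
    mu <- stats::plogis(eta)
    newdev <- -2 * sum(y * log(pmax(mu, 1e-300)) +
                       (1 - y) * log(pmax(1 - mu, 1e-300)))
    if (abs(newdev - dev) / (abs(newdev) + 0.1) < tol) {
      converged <- TRUE
      dev <- newdev
      break
    }
    dev <- newdev
  }
  std_slopes <- abs(beta) * .design_scales(x)
  eta <- drop(x %*% beta)
  diverged <- any(std_slopes[-1] > .sep_threshold) &&
    max(abs(eta)) > .eta_threshold
  separated <- !converged || diverged
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  list(coefficients = stats::setNames(beta, colnames(x)),
       fitted = mu, converged = converged, separated = separated, ok = TRUE,
       xtwx = crossprod(x, x * w), iterations = it)
}

#' Fit a logistic regression stage
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares, the shared engine behind every logistic stage of the Wald and
#' instrumental-variable estimators. An intercept is always included.
#'
#' @param response Binary 0/1 vector.
#' @param design Named list, data frame or matrix of regressor columns
#'   (intercept added implicitly).
#' @param se Compute standard errors (default `TRUE`).
#' @return An object of class `"glm_fit"`: a list with `coefficients`,
#'   `standard_errors`, `fitted_values`, `converged` (`FALSE` on separation
#'   or non-convergence) and `n_used`.
#' @examples
#' set.seed(1)
#' z <- rbinom(500, 1, 0.5)
#' y <- rbinom(500, 1, plogis(0.2 + 0.8 * z))
#' fit_logistic(y, list(z = z))$coefficients
#' @export
fit_logistic <- function(response, design, se = TRUE) {
  .check_binary(response, "response")
  x <- .build_design(design, n = length(response))
  if (nrow(x) != length(response))
    stop("response and design lengths differ", call. = FALSE)
  if (length(unique(response)) < 2L)
    stop("response is constant: degenerate fit", call. = FALSE)
  if (qr(x)$rank < ncol(x))
    stop("design is rank-deficient (collinear columns)", call. = FALSE)
  f <- .logistic_irls(x, response)
  if (!f$ok)
    stop("design is rank-deficient (collinear columns)", call. = FALSE)
  ses <- rep(NA_real_, ncol(x))
  if (se && !f$separated) {
    cov <- tryCatch(solve(f$xtwx), error = function(e) NULL)
    if (!is.null(cov)) ses <- sqrt(diag(cov))
  }
  structure(list(coefficients = f$coefficients,
                 standard_errors = stats::setNames(ses, colnames(x)),
                 fitted_values = f$fitted,
                 converged = f$converged && !f$separated,
                 n_used = length(response)),
            class = "glm_fit")
}

# ---- linear-probability kernel ----------------------------------------------

.lpm_fit <- function(x, y, se = TRUE) {
  fit <- stats::lm.fit(x, y)
  beta <- fit$coefficients
  ses <- rep(NA_real_, ncol(x))
  if (se) {
    df <- length(y) - fit$rank
    if (df > 0) {
      sigma2 <- sum(fit$residuals^2) / df
      R <- qr.R(fit$qr)
      cov <- tryCatch(chol2inv(R) * sigma2, error = function(e) NULL)
      if (!is.null(cov)) ses <- sqrt(diag(cov))
    }
  }
  list(coefficients = stats::setNames(beta, colnames(x)),
       standard_errors = stats::setNames(ses, colnames(x)),
       fitted = drop(x %*% ifelse(is.na(beta), 0, beta)))
}

#' Fit a linear probability model stage
#'
#' Ordinary least squares of a binary response on the design columns; the
#' slope on a single binary regressor is the difference in group means of
#' the response.
#'
#' @inheritParams fit_logistic
#' @return An object of class `"glm_fit"` with coefficients on the
#'   probability scale; `converged` is always `TRUE` for a full-rank fit.
#' @export
fit_lpm <- function(response, design, se = TRUE) {
  .check_binary(response, "response")
  x <- .build_design(design, n = length(response))
  if (nrow(x) != length(response))
    stop("response and design lengths differ", call. = FALSE)
  if (length(unique(response)) < 2L)
    stop("response is constant: degenerate fit", call. = FALSE)
  if (qr(x)$rank < ncol(x))
    stop("design is rank-deficient (collinear columns)", call. = FALSE)
  f <- .lpm_fit(x, response, se = se)
  structure(list(coefficients = f$coefficients,
                 standard_errors = f$standard_errors,
                 fitted_values = f$fitted,
                 converged = TRUE,
                 n_used = length(response)),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Fitted stage (n = %d, converged = %s)\n", x$n_used,
              x$converged))
  print(cbind(estimate = x$coefficients, se = x$standard_errors))
  invisible(x)
}

# ---- scale transformation ---------------------------------------------------

#' Convert a log-odds coefficient to the linear-probability scale
#'
#' Uses the prevalence-based approximation
#' `beta_linear = beta_logistic * pr * (1 - pr)`, where `pr` is the marginal
#' prevalence of the binary trait the coefficient acts on.
#'
#' @param beta_logistic Coefficient on the log-odds scale.
#' @param pr Trait prevalence, strictly between 0 and 1.
#' @return Coefficient on the linear (probability) scale.
#' @seealso [inverse_transform()], the exact inverse at the same `pr`.
#' @examples
#' transform_coefficient(1, 0.5)    # 0.25
#' transform_coefficient(-2, 0.2)   # -0.32
#' @export
transform_coefficient <- function(beta_logistic, pr) {
  if (any(!is.finite(pr)) || any(pr <= 0) || any(pr >= 1))
    stop("'pr' must lie strictly between 0 and 1", call. = FALSE)
  beta_logistic * pr * (1 - pr)
}

#' Convert a linear-probability coefficient back to the log-odds scale
#'
#' `beta_logistic = beta_linear / (pr * (1 - pr))`; the exact inverse of
#' [transform_coefficient()] at the same prevalence.
#'
#' @param beta_linear Coefficient on the linear (probability) scale.
#' @param pr Trait prevalence, strictly between 0 and 1.
#' @return Coefficient on the log-odds scale.
#' @export
inverse_transform <- function(beta_linear, pr) {
  if (any(!is.finite(pr)) || any(pr <= 0) || any(pr >= 1))
    stop("'pr' must lie strictly between 0 and 1", call. = FALSE)
  beta_linear / (pr * (1 - pr))
}

# ---- shared input handling for estimators -----------------------------------

.ratio_floor <- 1e-8

.check_mr_data <- function(data) {
  stopifnot(is.data.frame(data) || is.list(data))
  for (nm in c("Z", "X", "Y")) {
    if (is.null(data[[nm]]))
      stop(sprintf("data must contain a '%s' column", nm), call. = FALSE)
    .check_binary(data[[nm]], nm)
  }
  lens <- c(length(data$Z), length(data$X), length(data$Y))
  if (length(unique(lens)) != 1L)
    stop("Z, X and Y must share a common length", call. = FALSE)
  invisible(data)
}

# Validates optional covariates and returns them as a named data.frame (or
# NULL). A constant or collinear covariate block is a user error, distinct
# from the rank deficiency an estimator can itself produce (e.g. a constant
# first-stage fitted value), which is reported as valid = FALSE.
.check_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  cov <- as.data.frame(covariates)
  if (nrow(cov) != n)
    stop("covariates must have one row per subject", call. = FALSE)
  if (is.null(names(cov)) || any(!nzchar(names(cov))))
    stop("covariates must be named", call. = FALSE)
  x <- .build_design(cov)
  if (qr(x)$rank < ncol(x))
    stop("covariate block is rank-deficient (constant or collinear column)",
         call. = FALSE)
  cov
}

.bind_design <- function(core, covariates) {
  if (is.null(covariates)) return(core)
  c(core, as.list(covariates))
}

.wald_estimate <- function(method, estimate, numerator, denominator,
                           pr_x = NA_real_, pr_y = NA_real_, valid = TRUE) {
  structure(list(method = method,
                 estimate = if (valid) estimate else NA_real_,
                 numerator = numerator, denominator = denominator,
                 pr_x = pr_x, pr_y = pr_y, valid = valid),
            class = "wald_estimate")
}

.causal_estimate <- function(method, estimate, first_stage = NULL,
                             second_stage = NULL, residual_coefficient = NULL,
                             valid = TRUE) {
  structure(list(method = method,
                 estimate = if (valid) estimate else NA_real_,
                 residual_coefficient = residual_coefficient,
                 first_stage = first_stage, second_stage = second_stage,
                 valid = valid),
            class = "causal_estimate")
}

#' @export
print.wald_estimate <- function(x, ...) {
  cat(sprintf("Wald ratio (%s): %s\n", x$method,
              if (x$valid) format(x$estimate) else "invalid fit"))
  invisible(x)
}

#' @export
print.causal_estimate <- function(x, ...) {
  cat(sprintf("IV estimate (%s): %s\n", x$method,
              if (x$valid) format(x$estimate) else "invalid fit"))
  invisible(x)
}

# try a fit; NULL signals a failed (degenerate/separated) stage
.try_stage <- function(kernel, response, design, se) {
  f <- tryCatch(kernel(response, design, se = se), error = function(e) NULL)
  if (is.null(f) || !f$converged) return(NULL)
  f
}

# ---- Wald-ratio estimators --------------------------------------------------

#' Wald ratio from two logistic regressions
#'
#' Fits `logit P(X=1) = alpha0 + alpha1 Z` and `logit P(Y=1) = gamma0 +
#' gamma1 Z` (plus covariates in both stages, if supplied) and returns the
#' ratio `gamma1 / alpha1` — the causal effect of X on Y on the log-odds
#' scale, as used with binary-trait GWAS summary statistics.
#'
#' @param data Data frame (or list) with binary columns `Z`, `X`, `Y`.
#' @param covariates Optional named data frame of adjustment columns, entered
#'   in both regressions.
#' @param se Compute stage standard errors (default `FALSE`; the ratio itself
#'   carries no standard error).
#' @return A `"wald_estimate"`; `valid = FALSE` if either stage fails, is
#'   separated, or the instrument-exposure slope is below `1e-8` in absolute
#'   value.
#' @export
wald_logistic <- function(data, covariates = NULL, se = FALSE) {
  .check_mr_data(data)
  cov <- .check_covariates(covariates, length(data$Z))
  fx <- .try_stage(fit_logistic, data$X, .bind_design(list(Z = data$Z), cov), se)
  fy <- .try_stage(fit_logistic, data$Y, .bind_design(list(Z = data$Z), cov), se)
  if (is.null(fx) || is.null(fy))
    return(.wald_estimate("logistic", NA_real_, NA_real_, NA_real_, valid = FALSE))
  a1 <- unname(fx$coefficients["Z"])
  g1 <- unname(fy$coefficients["Z"])
  if (!is.finite(a1) || abs(a1) < .ratio_floor)
    return(.wald_estimate("logistic", NA_real_, g1, a1, valid = FALSE))
  .wald_estimate("logistic", g1 / a1, g1, a1)
}

#' Wald ratio from two linear probability models
#'
#' Fits `X = alpha0 + alpha1 Z` and `Y = gamma0 + gamma1 Z` by ordinary least
#' squares, forms the slope ratio on the probability scale, and converts it
#' to the log-odds scale with [inverse_transform()] at the sample prevalence
#' of the outcome.
#'
#' @inheritParams wald_logistic
#' @return A `"wald_estimate"` with `pr_y` recording the prevalence used;
#'   `valid = FALSE` if the outcome prevalence is 0 or 1, a stage fails, or
#'   the denominator slope is below the `1e-8` floor.
#' @export
wald_lpm <- function(data, covariates = NULL, se = FALSE) {
  .check_mr_data(data)
  cov <- .check_covariates(covariates, length(data$Z))
  pr_y <- mean(data$Y)
  if (pr_y <= 0 || pr_y >= 1)
    return(.wald_estimate("lpm", NA_real_, NA_real_, NA_real_, valid = FALSE))
  fx <- .try_stage(fit_lpm, data$X, .bind_design(list(Z = data$Z), cov), se)
  fy <- .try_stage(fit_lpm, data$Y, .bind_design(list(Z = data$Z), cov), se)
  if (is.null(fx) || is.null(fy))
    return(.wald_estimate("lpm", NA_real_, NA_real_, NA_real_, valid = FALSE))
  a1 <- unname(fx$coefficients["Z"])
  g1 <- unname(fy$coefficients["Z"])
  if (!is.finite(a1) || abs(a1) < .ratio_floor)
    return(.wald_estimate("lpm", NA_real_, g1, a1, pr_y = pr_y, valid = FALSE))
  .wald_estimate("lpm", inverse_transform(g1 / a1, pr_y), g1, a1, pr_y = pr_y)
}

#' Wald ratio via the prevalence transformation of logistic slopes
#'
#' Fits the same two logistic regressions as [wald_logistic()], converts each
#' slope to the linear scale with [transform_coefficient()] — the
#' instrument-exposure slope at the sample prevalence of X, the
#' instrument-outcome slope at the sample prevalence of Y — takes the ratio
#' on the linear scale, and converts the result back to the log-odds scale
#' with [inverse_transform()] at the prevalence of Y.
#'
#' @inheritParams wald_logistic
#' @return A `"wald_estimate"` recording both prevalences used.
#' @export
wald_transformation <- function(data, covariates = NULL, se = FALSE) {
  .check_mr_data(data)
  cov <- .check_covariates(covariates, length(data$Z))
  pr_x <- mean(data$X)
  pr_y <- mean(data$Y)
  if (pr_x <= 0 || pr_x >= 1 || pr_y <= 0 || pr_y >= 1)
    return(.wald_estimate("transformation", NA_real_, NA_real_, NA_real_,
                          valid = FALSE))
  fx <- .try_stage(fit_logistic, data$X, .bind_design(list(Z = data$Z), cov), se)
  fy <- .try_stage(fit_logistic, data$Y, .bind_design(list(Z = data$Z), cov), se)
  if (is.null(fx) || is.null(fy))
    return(.wald_estimate("transformation", NA_real_, NA_real_, NA_real_,
                          valid = FALSE))
  a1 <- transform_coefficient(unname(fx$coefficients["Z"]), pr_x)
  g1 <- transform_coefficient(unname(fy$coefficients["Z"]), pr_y)
  if (!is.finite(a1) || abs(a1) < .ratio_floor)
    return(.wald_estimate("transformation", NA_real_, g1, a1,
                          pr_x = pr_x, pr_y = pr_y, valid = FALSE))
  .wald_estimate("transformation", inverse_transform(g1 / a1, pr_y), g1, a1,
                 pr_x = pr_x, pr_y = pr_y)
}

# ---- instrumental-variable estimators ---------------------------------------

#' Structural-equation (exposure-outcome logistic) estimator
#'
#' Specifies the two logistic equations `logit P(X=1) = alpha0 + alpha1 Z`
#' and `logit P(Y=1) = beta0 + beta_sem X` (plus covariates in both). With
#' binary responses no cross-equation error term exists, so simultaneous and
#' sequential maximum likelihood coincide and the causal coefficient is the
#' slope of the outcome-on-exposure logistic fit; the instrument never enters
#' the outcome equation.
#'
#' @inheritParams wald_logistic
#' @param se Compute stage standard errors (default `TRUE`; the outcome-stage
#'   errors are the ones reported for applied cohort analyses).
#' @return A `"causal_estimate"` with both stage fits attached.
#' @export
estimate_sem <- function(data, covariates = NULL, se = TRUE) {
  .check_mr_data(data)
  cov <- .check_covariates(covariates, length(data$Z))
  fx <- .try_stage(fit_logistic, data$X, .bind_design(list(Z = data$Z), cov), se)
  fy <- .try_stage(fit_logistic, data$Y, .bind_design(list(X = data$X), cov), se)
  if (is.null(fx) || is.null(fy))
    return(.causal_estimate("sem", NA_real_, fx, fy, valid = FALSE))
  .causal_estimate("sem", unname(fy$coefficients["X"]), fx, fy)
}

#' Two-stage predictor substitution (TSPS)
#'
#' Stage 1 fits `logit P(X=1) = alpha0 + alpha1 Z` (plus covariates) and
#' produces fitted exposure probabilities; stage 2 fits a logistic regression
#' of Y on those fitted probabilities (plus covariates). The causal estimate
#' is the stage-2 coefficient on the fitted probability.
#'
#' @inheritParams estimate_sem
#' @return A `"causal_estimate"`; `valid = FALSE` when the stage-2 design is
#'   numerically rank-deficient (e.g. the fitted probability is constant
#'   because the estimated instrument-exposure slope is exactly zero) or a
#'   stage fails.
#' @export
estimate_tsps <- function(data, covariates = NULL, se = TRUE) {
  .check_mr_data(data)
  cov <- .check_covariates(covariates, length(data$Z))
  fx <- .try_stage(fit_logistic, data$X, .bind_design(list(Z = data$Z), cov), se)
  if (is.null(fx))
    return(.causal_estimate("tsps", NA_real_, fx, NULL, valid = FALSE))
  phat <- fx$fitted_values
  fy <- tryCatch(
    fit_logistic(data$Y, .bind_design(list(Phat = phat), cov), se = se),
    error = function(e) NULL)
  if (is.null(fy) || !fy$converged)
    return(.causal_estimate("tsps", NA_real_, fx, fy, valid = FALSE))
  .causal_estimate("tsps", unname(fy$coefficients["Phat"]), fx, fy)
}

#' Two-stage residual inclusion (TSRI)
#'
#' Stage 1 as in [estimate_tsps()]; the first-stage residual
#' `e = X - Phat` is then included alongside the observed exposure in a
#' stage-2 logistic regression of Y on X and e (plus covariates). The causal
#' estimate is the stage-2 coefficient on X; the residual coefficient is
#' reported as well.
#'
#' @inheritParams estimate_sem
#' @return A `"causal_estimate"` with `residual_coefficient` set;
#'   `valid = FALSE` when X and the residual are collinear (the estimated
#'   instrument-exposure slope is exactly zero) or a stage fails.
#' @export
estimate_tsri <- function(data, covariates = NULL, se = TRUE) {
  .check_mr_data(data)
  cov <- .check_covariates(covariates, length(data$Z))
  fx <- .try_stage(fit_logistic, data$X, .bind_design(list(Z = data$Z), cov), se)
  if (is.null(fx))
    return(.causal_estimate("tsri", NA_real_, fx, NULL, valid = FALSE))
  resid <- data$X - fx$fitted_values
  fy <- tryCatch(
    fit_logistic(data$Y, .bind_design(list(X = data$X, e = resid), cov),
                 se = se),
    error = function(e) NULL)
  if (is.null(fy) || !fy$converged)
    return(.causal_estimate("tsri", NA_real_, fx, fy, valid = FALSE))
  .causal_estimate("tsri", unname(fy$coefficients["X"]), fx, fy,
                   residual_coefficient = unname(fy$coefficients["e"]))
}

# ---- fast shared-kernel path for the bias study -----------------------------

# Computes all six estimates from one pass over the shared stage fits:
# logistic X~Z and Y~Z feed the logistic and transformation Wald ratios and
# the TSPS/TSRI first stage; least-squares X~Z and Y~Z feed the LPM Wald
# ratio; three further logistic fits give SEM, TSPS and TSRI. 'cov' is an
# optional numeric matrix of adjustment covariates entered in every stage.
# Identical kernels to the public estimators (asserted by the test suite);
# skips standard errors and object construction for speed.
.estimate_all_fast <- function(Z, X, Y, cov = NULL) {
  out <- c(wald_logistic = NA_real_, wald_lpm = NA_real_,
           wald_transformation = NA_real_, sem = NA_real_, tsps = NA_real_,
           tsri = NA_real_)
  if (length(unique(X)) < 2L || length(unique(Y)) < 2L ||
      length(unique(Z)) < 2L)
    return(out)
  xz <- cbind("(Intercept)" = 1, Z = as.numeric(Z), cov)
  fx <- .logistic_irls(xz, X)
  fy <- .logistic_irls(xz, Y)
  pr_x <- mean(X)
  pr_y <- mean(Y)
  ok_x <- fx$ok && !fx$separated
  ok_y <- fy$ok && !fy$separated
  if (ok_x && ok_y) {
    a1 <- fx$coefficients["Z"]
    g1 <- fy$coefficients["Z"]
    if (abs(a1) >= .ratio_floor) {
      out["wald_logistic"] <- g1 / a1
      a1t <- a1 * pr_x * (1 - pr_x)
      g1t <- g1 * pr_y * (1 - pr_y)
      if (abs(a1t) >= .ratio_floor)
        out["wald_transformation"] <- (g1t / a1t) / (pr_y * (1 - pr_y))
    }
  }
  lx <- stats::lm.fit(xz, X)$coefficients
  ly <- stats::lm.fit(xz, Y)$coefficients
  if (all(is.finite(c(lx, ly))) && abs(lx["Z"]) >= .ratio_floor &&
      pr_y > 0 && pr_y < 1)
    out["wald_lpm"] <- (ly["Z"] / lx["Z"]) / (pr_y * (1 - pr_y))
  fs <- .logistic_irls(cbind("(Intercept)" = 1, X = as.numeric(X), cov), Y)
  if (fs$ok && !fs$separated) out["sem"] <- fs$coefficients["X"]
  if (ok_x) {
    phat <- fx$fitted
    ft <- .logistic_irls(cbind("(Intercept)" = 1, Phat = phat, cov), Y)
    if (ft$ok && !ft$separated) out["tsps"] <- ft$coefficients["Phat"]
    fr <- .logistic_irls(cbind("(Intercept)" = 1, X = as.numeric(X),
                               e = X - phat, cov), Y)
    if (fr$ok && !fr$separated) out["tsri"] <- fr$coefficients["X"]
  }
  out
}

#' All six causal estimates for one dataset
#'
#' Runs the three Wald-ratio estimators and the three instrumental-variable
#' estimators on the same data through the shared fitting kernels.
#'
#' @inheritParams wald_logistic
#' @return A data frame with columns `method`, `estimate`, `valid`; methods
#'   are `wald_logistic`, `wald_lpm`, `wald_transformation`, `sem`, `tsps`,
#'   `tsri`. Estimates are on the log-odds scale.
#' @examples
#' cfg <- sim_config(alpha1 = 0.7, beta1 = 1, n = 500, seed = 3)
#' mr_estimates(draw_dataset(cfg, 0))
#' @export
mr_estimates <- function(data, covariates = NULL) {
  .check_mr_data(data)
  if (is.null(covariates)) {
    est <- .estimate_all_fast(data$Z, data$X, data$Y)
  } else {
    fits <- list(wald_logistic = wald_logistic(data, covariates),
                 wald_lpm = wald_lpm(data, covariates),
                 wald_transformation = wald_transformation(data, covariates),
                 sem = estimate_sem(data, covariates, se = FALSE),
                 tsps = estimate_tsps(data, covariates, se = FALSE),
                 tsri = estimate_tsri(data, covariates, se = FALSE))
    est <- vapply(fits, function(f) if (f$valid) f$estimate else NA_real_,
                  numeric(1))
  }
  data.frame(method = names(est), estimate = unname(est),
             valid = is.finite(unname(est)), row.names = NULL)
}

#' Serialize estimator results to a tidy CSV
#'
#' One row per estimate: `method, estimate, valid` plus any auxiliary fields
#' present (`numerator`, `denominator`, `pr_x`, `pr_y`,
#' `residual_coefficient`).
#'
#' @param estimates A list of `"wald_estimate"` / `"causal_estimate"`
#'   objects, or a data frame as returned by [mr_estimates()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_estimates_csv <- function(estimates, path) {
  if (is.data.frame(estimates)) {
    utils::write.csv(estimates, path, row.names = FALSE)
    return(invisible(path))
  }
  rows <- lapply(estimates, function(e) {
    data.frame(method = e$method, estimate = e$estimate, valid = e$valid,
               numerator = if (!is.null(e$numerator)) e$numerator else NA,
               denominator = if (!is.null(e$denominator)) e$denominator else NA,
               pr_x = if (!is.null(e$pr_x)) e$pr_x else NA,
               pr_y = if (!is.null(e$pr_y)) e$pr_y else NA,
               residual_coefficient = if (!is.null(e$residual_coefficient))
                 e$residual_coefficient else NA)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
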