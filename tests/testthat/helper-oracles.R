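# Independent oracles used across the test files. These deliberately avoid
# the package's own fitting kernels: logistic fits go through stats::glm,
# least squares through the closed-form normal equations, quantiles through
# naive interpolation of the sorted sample, and Fisher p-values through
# exact hypergeometric enumeration.

oracle_logistic <- function(response, design) {
  df <- data.frame(y = response, as.data.frame(design))
  fml <- stats::as.formula(paste("y ~", paste(names(as.data.frame(design)),
                                              collapse = " + ")))
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = df,
                                     control = stats::glm.control(epsilon = 1e-12,
                                                                  maxit = 200)))
  stats::coef(fit)
}

oracle_ols <- function(response, design) {
  x <- cbind(1, as.matrix(as.data.frame(design)))
  drop(solve(crossprod(x), crossprod(x, response)))
}

# naive sort-based quantile with linear interpolation between order stats
oracle_quantile <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

# exact two-sided Fisher p-value by enumeration over all 2x2 tables with the
# observed margins: sum hypergeometric probabilities not exceeding the
# observed one (with the standard relative-tolerance guard).
oracle_fisher <- function(tab) {
  m <- rowSums(tab)[1]
  n2 <- rowSums(tab)[2]
  k <- colSums(tab)[1]
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small deterministic MR fixture: 20 subjects, all margins informative
mr_fixture_20 <- function() {
  list(Z = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
       X = c(0, 0, 0, 1, 0, 0, 1, 0, 0, 1, 1, 1, 0, 1, 1, 0, 1, 1, 1, 0),
       Y = c(0, 1, 0, 0, 0, 1, 1, 0, 0, 0, 1, 0, 1, 1, 0, 1, 1, 1, 0, 1))
}

# fixture with differing exposure/outcome prevalences and some covariates
mr_fixture_cov <- function(n = 120, seed = 42) {
  set.seed(seed)
  Z <- rbinom(n, 1, 0.4)
  C1 <- rbinom(n, 1, 0.5)
  C2 <- rbinom(n, 1, 0.3)
  X <- rbinom(n, 1, plogis(-1 + 1.2 * Z + 0.5 * C1 - 0.3 * C2))
  Y <- rbinom(n, 1, plogis(-1.5 + 0.8 * X + 0.4 * C1 + 0.6 * C2))
  list(data = list(Z = Z, X = X, Y = Y),
       covariates = data.frame(C1 = C1, C2 = C2))
}
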