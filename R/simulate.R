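#' Inverse-logit (expit) function
#'
#' Maps a linear predictor on the log-odds scale to a probability,
#' `1 / (1 + exp(-t))`. Computed via [stats::plogis()], which is numerically
#' stable and saturates smoothly for very large `|t|`.
#'
#' @param t Numeric vector of log-odds values.
#' @return Probabilities in (0, 1), same length as `t`.
#' @examples
#' expit(0)    # 0.5
#' expit(-2)   # 0.1192029
#' @export
expit <- function(t) stats::plogis(t)

#' Simulation configuration for the confounded binary-IV model
#'
#' One cell of a simulation grid. The data-generating model is
#' \deqn{Z_i \sim Bern(p_Z), \quad U_i \sim N(0, 1),}
#' \deqn{X_i \sim Bern(expit(\alpha_0 + \alpha_1 Z_i + c_x U_i)),}
#' \deqn{Y_i \sim Bern(expit(\beta_0 + \beta_1 X_i + c_y U_i)),}
#' so `alpha1` is the instrument strength, `beta1` the true causal effect of
#' exposure on outcome (both on the log-odds scale), and `cx`, `cy` the
#' effects of the latent standard-normal confounder on exposure and outcome.
#'
#' @param alpha0 Exposure intercept (log-odds).
#' @param alpha1 Instrument strength (log-odds per unit Z).
#' @param beta0 Outcome intercept (log-odds).
#' @param beta1 True causal effect of X on Y (log-odds).
#' @param cx Confounder effect on the exposure (log-odds per unit U).
#' @param cy Confounder effect on the outcome (log-odds per unit U).
#' @param pZ Instrument prevalence, in (0, 1).
#' @param n Sample size per replicate (>= 2).
#' @param n_reps Number of Monte-Carlo replicates (>= 1).
#' @param seed Master random seed (integer); each replicate derives its own
#'   substream from `(seed, rep_index)`, see [draw_dataset()].
#' @return An object of class `"sim_config"` (a validated named list).
#' @seealso [draw_dataset()], [build_core_grid()], [build_sensitivity_grid()]
#' @export
sim_config <- function(alpha0 = 0, alpha1 = 0.01, beta0 = 0, beta1 = 0,
                       cx = 0.01, cy = 0.01, pZ = 0.2, n = 1000L,
                       n_reps = 8000L, seed = 1L) {
  cfg <- list(alpha0 = as.numeric(alpha0), alpha1 = as.numeric(alpha1),
              beta0 = as.numeric(beta0), beta1 = as.numeric(beta1),
              cx = as.numeric(cx), cy = as.numeric(cy),
              pZ = as.numeric(pZ), n = as.integer(n),
              n_reps = as.integer(n_reps), seed = as.integer(seed))
  eff <- c(cfg$alpha0, cfg$alpha1, cfg$beta0, cfg$beta1, cfg$cx, cfg$cy)
  if (any(!is.finite(eff)))
    stop("all effect parameters must be finite", call. = FALSE)
  if (!is.finite(cfg$pZ) || cfg$pZ <= 0 || cfg$pZ >= 1)
    stop("'pZ' must lie strictly between 0 and 1", call. = FALSE)
  if (is.na(cfg$n) || cfg$n < 2L) stop("'n' must be >= 2", call. = FALSE)
  if (is.na(cfg$n_reps) || cfg$n_reps < 1L)
    stop("'n_reps' must be >= 1", call. = FALSE)
  if (is.na(cfg$seed)) stop("'seed' must be an integer", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Binary-IV simulation configuration\n")
  cat(sprintf("  exposure : logit(pX) = %g + %g*Z + %g*U\n",
              x$alpha0, x$alpha1, x$cx))
  cat(sprintf("  outcome  : logit(pY) = %g + %g*X + %g*U\n",
              x$beta0, x$beta1, x$cy))
  cat(sprintf("  pZ = %g, n = %d, n_reps = %d, seed = %d\n",
              x$pZ, x$n, x$n_reps, x$seed))
  invisible(x)
}

# Deterministic per-replicate substream seed: an LCG-style mix of the master
# seed and the replicate counter, so replicate r is reproducible without
# generating replicates 0..r-1. Modulus 2^31 - 1 keeps the result a valid
# R integer seed.
.rep_seed <- function(seed, rep_index) {
  m <- 2147483647
  s <- (abs(as.numeric(seed)) %% m)
  as.integer((s * 48271 + as.numeric(rep_index) + 1) %% m)
}

#' Draw one simulated dataset
#'
#' Generates one replicate from the confounded binary-IV model of
#' [sim_config()]. The random stream is a deterministic function of
#' `(cfg$seed, rep_index)`, so any replicate can be regenerated in isolation
#' and replicates carry distinct substreams.
#'
#' @param cfg A [sim_config()] object.
#' @param rep_index Zero-based replicate index, in `[0, cfg$n_reps)`.
#' @return A `data.frame` with `cfg$n` rows and columns `Z`, `X`, `Y`
#'   (binary integer) and `U` (the simulated confounder; whether estimators
#'   may condition on it is the caller's choice — see
#'   [run_cell()]'s `adjust_confounder`).
#' @examples
#' cfg <- sim_config(alpha1 = 0.7, beta1 = 1, n = 200, seed = 7)
#' d <- draw_dataset(cfg, 0)
#' colMeans(d[c("Z", "X", "Y")])
#' @export
draw_dataset <- function(cfg, rep_index = 0L) {
  stopifnot(inherits(cfg, "sim_config"))
  rep_index <- as.integer(rep_index)
  if (is.na(rep_index) || rep_index < 0L || rep_index >= cfg$n_reps)
    stop("'rep_index' must lie in [0, n_reps)", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.rep_seed(cfg$seed, rep_index))
  n <- cfg$n
  Z <- stats::rbinom(n, 1L, cfg$pZ)
  U <- stats::rnorm(n)
  X <- stats::rbinom(n, 1L, expit(cfg$alpha0 + cfg$alpha1 * Z + cfg$cx * U))
  Y <- stats::rbinom(n, 1L, expit(cfg$beta0 + cfg$beta1 * X + cfg$cy * U))
  data.frame(Z = Z, X = X, Y = Y, U = U)
}

#' Scenario grid constructor
#'
#' @param label Scenario identifier (e.g. `"A"` or `"sens2"`).
#' @param cells List of [sim_config()] objects.
#' @return An object of class `"scenario_grid"`.
#' @export
scenario_grid <- function(label, cells) {
  stopifnot(is.character(label), length(label) == 1L, is.list(cells))
  if (!all(vapply(cells, inherits, logical(1), "sim_config")))
    stop("every cell must be a 'sim_config'", call. = FALSE)
  structure(list(label = label, cells = cells), class = "scenario_grid")
}

#' @export
print.scenario_grid <- function(x, ...) {
  cat(sprintf("Scenario grid '%s': %d cells\n", x$label, length(x$cells)))
  invisible(x)
}

# distinct, reproducible per-cell seed derived from a master seed
.cell_seed <- function(seed, index) {
  m <- 2147483647
  as.integer(((abs(as.numeric(seed)) %% m) * 10007 + index) %% m)
}

#' Build the four core bias-study scenarios
#'
#' Scenarios A and B carry a null causal effect (`beta1 = 0`), C and D a
#' positive effect (`beta1 = 1`); A and C use weak confounding
#' (`cx = cy = 0.01`), B and D strong confounding (`cx = cy = 1.5`). Each
#' scenario is crossed with the supplied instrument strengths. All other
#' parameters take the study defaults: `n = 1000`, `pZ = 0.2`,
#' `alpha0 = beta0 = 0`.
#'
#' @param alpha1_values Instrument strengths to cross with each scenario.
#' @param n_reps Replicates per cell (default 8000).
#' @param n Sample size per replicate.
#' @param seed Master seed; each cell receives a distinct derived seed.
#' @return A list of four `"scenario_grid"` objects labelled `A`–`D`.
#' @export
build_core_grid <- function(alpha1_values = c(0.01, 0.05, 0.1, 0.5, 0.7),
                            n_reps = 8000L, n = 1000L, seed = 1L) {
  if (length(alpha1_values) == 0L)
    stop("'alpha1_values' must be nonempty", call. = FALSE)
  scen <- list(A = list(beta1 = 0, c = 0.01), B = list(beta1 = 0, c = 1.5),
               C = list(beta1 = 1, c = 0.01), D = list(beta1 = 1, c = 1.5))
  idx <- 0L
  lapply(names(scen), function(lab) {
    s <- scen[[lab]]
    cells <- lapply(alpha1_values, function(a1) {
      idx <<- idx + 1L
      sim_config(alpha0 = 0, alpha1 = a1, beta0 = 0, beta1 = s$beta1,
                 cx = s$c, cy = s$c, pZ = 0.2, n = n, n_reps = n_reps,
                 seed = .cell_seed(seed, idx))
    })
    scenario_grid(lab, cells)
  })
}

#' Build one of the four sensitivity-analysis grids
#'
#' Grid 1 varies the sample size (50, 200, 500, 1000, 1500); grid 2 the
#' instrument prevalence (0.1, 0.2, 0.5, 0.8); grid 3 the exposure/outcome
#' prevalence through the intercepts, crossing the instrument strengths
#' (0.01, 0.05, 0.1, 0.5, 0.7) with intercept pairs (0,0), (1,1), (3,3),
#' (-2,-2); grid 4 the confounder effect (0.01, 0.1, 0.5, 1, 1.5, 2). Every
#' grid is crossed with `beta1` in \{0, 1\} and — except grid 4, which varies
#' the confounder itself — with confounder effects in \{0.01, 1.5\}.
#' Parameters a grid does not vary keep the study defaults `alpha1 = 0.01`,
#' `n = 1000`, `pZ = 0.2`, `alpha0 = beta0 = 0`. `cx` and `cy` always move
#' together, as in every printed scenario.
#'
#' @param which Grid id, one of 1, 2, 3, 4.
#' @param n_reps Replicates per cell (default 8000).
#' @param seed Master seed; cells receive distinct derived seeds.
#' @return A `"scenario_grid"` labelled `"sens<which>"`.
#' @export
build_sensitivity_grid <- function(which, n_reps = 8000L, seed = 1L) {
  if (!length(which) == 1L || !which %in% 1:4)
    stop("'which' must be one of 1, 2, 3, 4", call. = FALSE)
  base <- list(alpha0 = 0, alpha1 = 0.01, beta0 = 0, beta1 = 0,
               cx = 0.01, cy = 0.01, pZ = 0.2, n = 1000L)
  grid <- switch(as.character(which),
    "1" = expand.grid(beta1 = c(0, 1), c = c(0.01, 1.5),
                      n = c(50L, 200L, 500L, 1000L, 1500L)),
    "2" = expand.grid(beta1 = c(0, 1), c = c(0.01, 1.5),
                      pZ = c(0.1, 0.2, 0.5, 0.8)),
    "3" = expand.grid(beta1 = c(0, 1), c = c(0.01, 1.5),
                      alpha1 = c(0.01, 0.05, 0.1, 0.5, 0.7),
                      intercept = c(0, 1, 3, -2)),
    "4" = expand.grid(beta1 = c(0, 1), c = c(0.01, 0.1, 0.5, 1, 1.5, 2)))
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    row <- grid[i, , drop = FALSE]
    p <- base
    p$beta1 <- row$beta1
    p$cx <- p$cy <- row$c
    if (!is.null(row$n)) p$n <- row$n
    if (!is.null(row$pZ)) p$pZ <- row$pZ
    if (!is.null(row$alpha1)) p$alpha1 <- row$alpha1
    if (!is.null(row$intercept)) p$alpha0 <- p$beta0 <- row$intercept
    sim_config(alpha0 = p$alpha0, alpha1 = p$alpha1, beta0 = p$beta0,
               beta1 = p$beta1, cx = p$cx, cy = p$cy, pZ = p$pZ, n = p$n,
               n_reps = n_reps, seed = .cell_seed(seed, i + 1000L * which))
  })
  scenario_grid(paste0("sens", which), cells)
}

#' Monte-Carlo prevalence of exposure and outcome under a configuration
#'
#' Estimates the marginal prevalences P(X = 1) and P(Y = 1) implied by a
#' configuration from one large simulated draw — the quantities tabulated per
#' sensitivity-grid cell rather than hard-coded.
#'
#' @param cfg A [sim_config()] object.
#' @param n_large Monte-Carlo sample size (>= 1e4).
#' @return Named numeric vector `c(pX = ..., pY = ...)`.
#' @export
prevalence_summary <- function(cfg, n_large = 1e5) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_large < 1e4) stop("'n_large' must be >= 1e4", call. = FALSE)
  big <- sim_config(alpha0 = cfg$alpha0, alpha1 = cfg$alpha1,
                    beta0 = cfg$beta0, beta1 = cfg$beta1, cx = cfg$cx,
                    cy = cfg$cy, pZ = cfg$pZ, n = as.integer(n_large),
                    n_reps = 1L, seed = cfg$seed)
  d <- draw_dataset(big, 0L)
  c(pX = mean(d$X), pY = mean(d$Y))
}

#' Serialize scenario grids to a JSON configuration file
#'
#' The schema is a JSON array of grids, each `{label, cells: [...]}` with one
#' object of simulation parameters per cell. [read_grid_json()] restores the
#' grids exactly.
#'
#' @param grids A `"scenario_grid"` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_json <- function(grids, path) {
  if (inherits(grids, "scenario_grid")) grids <- list(grids)
  payload <- lapply(grids, function(g) {
    list(label = g$label, cells = lapply(g$cells, unclass))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_grid_json
#' @export
read_grid_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(g) {
    cells <- lapply(g$cells, function(cl) do.call(sim_config, cl))
    scenario_grid(g$label, cells)
  })
}

#' Write / read a simulated dataset as CSV
#'
#' Plain CSV with header `Z,X,Y,U`, one row per subject, for cross-language
#' fixture sharing.
#'
#' @param data Data frame with columns `Z`, `X`, `Y`, `U`.
#' @param path File path.
#' @return `path` invisibly (write) or the data frame (read).
#' @export
write_dataset_csv <- function(data, path) {
  stopifnot(all(c("Z", "X", "Y", "U") %in% names(data)))
  utils::write.csv(data[c("Z", "X", "Y", "U")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("Z", "X", "Y", "U") %in% names(d)))
  d
}
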