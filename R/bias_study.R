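# Replicated Monte-Carlo bias study: per-replicate differences between the
# instrumental-variable estimators and the Wald ratios, summarised as
# median / Q1 / Q3 per grid cell.

.iv_methods <- c("sem", "tsps", "tsri")
.wald_methods <- c("wald_logistic", "wald_lpm", "wald_transformation")

#' Bias of an IV estimate relative to a Wald-ratio estimate
#'
#' The study's bias convention is the signed difference
#' `iv_estimate - wald_estimate`, both on the log-odds scale.
#'
#' @param iv_estimate Instrumental-variable estimate (SEM, TSPS or TSRI).
#' @param wald_estimate Wald-ratio estimate (logistic, LPM or transformation).
#' @return `iv_estimate - wald_estimate`.
#' @examples
#' compute_bias(0.09, 0.23)   # -0.14
#' compute_bias(1.47, 0.23)   # 1.24
#' @export
compute_bias <- function(iv_estimate, wald_estimate) {
  iv_estimate - wald_estimate
}

#' Run all replicates of one simulation cell
#'
#' For each replicate draws a dataset under `cfg`, runs all six estimators,
#' and records the nine pairwise biases. By default the simulated confounder
#' `U` is supplied to every estimator as a measured adjustment covariate
#' (entering both stages of the IV estimators and both regressions of each
#' Wald method), mirroring a confounder-adjusted cohort analysis: the
#' resulting bias isolates the scale and noncollapsibility differences
#' between the methods, net of residual confounding. Set
#' `adjust_confounder = FALSE` for the unobserved-confounder protocol in
#' which estimators see `(Z, X, Y)` only. Deterministic given `cfg$seed`;
#' replicates use independent substreams and may be computed in any order.
#'
#' @param cfg A [sim_config()] object.
#' @param reps_override Optional replicate count used instead of
#'   `cfg$n_reps` (for desk-scale runs).
#' @param adjust_confounder Supply `U` to all estimators as a covariate
#'   (default `TRUE`).
#' @return A long data frame with one row per (replicate, IV method, Wald
#'   method): columns `rep_index`, `iv_method`, `wald_method`, `iv_estimate`,
#'   `wald_estimate`, `bias` (`NA` when either member of the pair was an
#'   invalid fit), plus an attribute `n_invalid` counting, per method, the
#'   replicates in which that estimator failed.
#' @export
run_cell <- function(cfg, reps_override = NULL, adjust_confounder = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  n_reps <- if (is.null(reps_override)) cfg$n_reps else as.integer(reps_override)
  stopifnot(n_reps >= 1L)
  est <- matrix(NA_real_, nrow = n_reps, ncol = 6,
                dimnames = list(NULL, c(.wald_methods, .iv_methods)))
  for (r in seq_len(n_reps)) {
    d <- draw_dataset(cfg, r - 1L)
    cov <- if (adjust_confounder) cbind(U = d$U) else NULL
    e <- .estimate_all_fast(d$Z, d$X, d$Y, cov)
    est[r, names(e)] <- e
  }
  grid <- expand.grid(iv_method = .iv_methods, wald_method = .wald_methods,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  blocks <- lapply(seq_len(nrow(grid)), function(k) {
    iv <- est[, grid$iv_method[k]]
    wa <- est[, grid$wald_method[k]]
    data.frame(rep_index = seq_len(n_reps) - 1L,
               iv_method = grid$iv_method[k],
               wald_method = grid$wald_method[k],
               iv_estimate = iv, wald_estimate = wa,
               bias = compute_bias(iv, wa))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  attr(out, "n_invalid") <- colSums(!is.finite(est))
  attr(out, "config") <- cfg
  out
}

#' Summarise per-replicate biases as median and quartiles
#'
#' For each (IV method, Wald method) pair, computes the median, first and
#' third quartiles of the bias over valid replicates, using linear
#' interpolation between order statistics ([stats::quantile()] type 7).
#' Pairs with no valid replicate are reported with `NA` summaries and
#' `n_valid = 0`, never as zero bias.
#'
#' @param records Long data frame from [run_cell()].
#' @return Data frame with columns `iv_method`, `wald_method`, `median`,
#'   `q1`, `q3`, `n_valid`.
#' @export
summarize_bias <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  grid <- unique(records[c("iv_method", "wald_method")])
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    b <- records$bias[records$iv_method == grid$iv_method[k] &
                      records$wald_method == grid$wald_method[k]]
    b <- b[is.finite(b)]
    if (length(b) == 0) {
      q <- c(NA_real_, NA_real_, NA_real_)
    } else {
      q <- unname(stats::quantile(b, c(0.25, 0.5, 0.75), type = 7))
    }
    data.frame(iv_method = grid$iv_method[k],
               wald_method = grid$wald_method[k],
               median = q[2], q1 = q[1], q3 = q[3], n_valid = length(b))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full bias study over one or more scenario grids
#'
#' Runs [run_cell()] and [summarize_bias()] for every cell of every grid and
#' stacks the results into the row layout of the study's summary tables: one
#' row per (scenario, cell parameters, IV method, Wald method).
#'
#' @param grids A `"scenario_grid"` or list of them (see
#'   [build_core_grid()], [build_sensitivity_grid()]).
#' @param reps_override Optional replicate count per cell, replacing each
#'   cell's `n_reps` (desk-scale runs).
#' @param out_dir Optional directory; when given, writes `summary.csv` (the
#'   tidy summary table), `replicates.csv` (long per-replicate biases, the
#'   boxplot data) and `manifest.json` (configurations, seeds and session
#'   info) into it.
#' @param keep_replicates Return the per-replicate long table as attribute
#'   `"replicates"` (default `FALSE`; it is always written when `out_dir` is
#'   given).
#' @inheritParams run_cell
#' @return Tidy data frame with columns `scenario`, `alpha1`, `beta1`, `cx`,
#'   `cy`, `n`, `pZ`, `alpha0`, `beta0`, `iv_method`, `wald_method`,
#'   `median`, `q1`, `q3`, `n_valid`.
#' @export
run_study <- function(grids, reps_override = NULL, out_dir = NULL,
                      keep_replicates = FALSE, adjust_confounder = TRUE) {
  if (inherits(grids, "scenario_grid")) grids <- list(grids)
  all_sum <- list()
  all_rep <- list()
  for (g in grids) {
    for (i in seq_along(g$cells)) {
      cfg <- g$cells[[i]]
      rec <- run_cell(cfg, reps_override, adjust_confounder)
      s <- summarize_bias(rec)
      meta <- data.frame(scenario = g$label, alpha1 = cfg$alpha1,
                         beta1 = cfg$beta1, cx = cfg$cx, cy = cfg$cy,
                         n = cfg$n, pZ = cfg$pZ, alpha0 = cfg$alpha0,
                         beta0 = cfg$beta0)
      all_sum[[length(all_sum) + 1L]] <- cbind(meta[rep(1, nrow(s)), ,
                                                    drop = FALSE], s)
      if (!is.null(out_dir) || keep_replicates) {
        all_rep[[length(all_rep) + 1L]] <-
          cbind(meta[rep(1, nrow(rec)), , drop = FALSE], rec)
      }
    }
  }
  out <- do.call(rbind, all_sum)
  rownames(out) <- NULL
  reps <- if (length(all_rep)) {
    r <- do.call(rbind, all_rep); rownames(r) <- NULL; r
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out, file.path(out_dir, "summary.csv"), row.names = FALSE)
    utils::write.csv(reps, file.path(out_dir, "replicates.csv"),
                     row.names = FALSE)
    manifest <- list(
      package = "binmr",
      version = as.character(utils::packageVersion("binmr")),
      r_version = as.character(getRversion()),
      created = format(Sys.time(), tz = "UTC", usetz = TRUE),
      reps_override = reps_override,
      adjust_confounder = adjust_confounder,
      grids = lapply(grids, function(g)
        list(label = g$label, cells = lapply(g$cells, unclass))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  if (keep_replicates) attr(out, "replicates") <- reps
  out
}
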