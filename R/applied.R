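# Applied cohort workflow: subject-table ingestion, SNP-exposure association
# screen, confounder-adjusted causal estimation per SNP, and a synthetic
# cohort generator emulating the structure of a prospective dog-cohort
# study (one binary SNP-derived instrument, binary activity exposure, binary
# cancer outcome, four binary confounders).

#' Read and validate a subject table from CSV
#'
#' The table holds one row per subject with 0/1-coded columns for the
#' instrument(s), exposure, outcome and confounders; missing cells are
#' allowed and retained.
#'
#' @param path CSV file path.
#' @param column_map Named list mapping roles to column names:
#'   `id` (optional), `instruments` (character vector, at least one),
#'   `exposure`, `outcome`, `confounders` (optional character vector).
#' @return An object of class `"subject_table"`: a list with the validated
#'   data frame (`data`), the role map (`map`) and `flagged_rows` (row
#'   numbers with missing exposure or outcome, retained but flagged).
#' @export
read_subject_table <- function(path, column_map) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  subject_table(d, column_map)
}

#' @rdname read_subject_table
#' @param data A data frame already in memory (the in-memory constructor
#'   behind [read_subject_table()]).
#' @export
subject_table <- function(data, column_map) {
  stopifnot(is.data.frame(data), is.list(column_map))
  need <- c("instruments", "exposure", "outcome")
  for (role in need) {
    if (is.null(column_map[[role]]))
      stop("column_map must define '", role, "'", call. = FALSE)
  }
  coded <- c(column_map$instruments, column_map$exposure, column_map$outcome,
             column_map$confounders)
  missing_cols <- setdiff(coded, names(data))
  if (length(missing_cols))
    stop("mapped columns absent from table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cl in coded) {
    v <- data[[cl]]
    bad <- which(!is.na(v) & !v %in% c(0, 1))
    if (length(bad))
      stop(sprintf("column '%s' is not 0/1 coded at row(s) %s", cl,
                   paste(utils::head(bad, 10), collapse = ", ")),
           call. = FALSE)
  }
  flagged <- which(is.na(data[[column_map$exposure]]) |
                   is.na(data[[column_map$outcome]]))
  structure(list(data = data, map = column_map, flagged_rows = flagged),
            class = "subject_table")
}

#' @export
print.subject_table <- function(x, ...) {
  cat(sprintf("Subject table: %d subjects, %d instrument column(s), %d confounder(s)\n",
              nrow(x$data), length(x$map$instruments),
              length(x$map$confounders)))
  if (length(x$flagged_rows))
    cat(sprintf("  %d row(s) flagged for missing exposure/outcome\n",
                length(x$flagged_rows)))
  invisible(x)
}

#' Write a subject table back to CSV
#'
#' @param table A `"subject_table"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_subject_table <- function(table, path) {
  stopifnot(inherits(table, "subject_table"))
  utils::write.csv(table$data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a PLINK additive-dosage export as binary instruments
#'
#' Parses a whitespace-delimited PLINK `.raw` file (the `--recode A` format:
#' header `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP
#' holding additive dosages 0/1/2 with `NA` for missing) and maps each
#' dosage column to a binary instrument.
#'
#' Genotype dichotomisation is not standardised; the default `"carrier"`
#' rule codes any carrier of the counted allele as 1 (dosage >= 1). The
#' alternatives are `"recessive"` (homozygote only, dosage == 2 -> 1) and
#' `"dominant"` (synonym of carrier, kept for familiarity). Choose
#' deliberately: the coding changes the instrument.
#'
#' @param path `.raw` file path.
#' @param coding Dichotomisation rule: `"carrier"` (default), `"dominant"`,
#'   or `"recessive"`.
#' @return A data frame fragment: `IID` plus one 0/1/NA column per SNP
#'   (original SNP column names preserved), ready to be merged into a
#'   subject table.
#' @export
read_plink_raw <- function(path, coding = c("carrier", "dominant",
                                            "recessive")) {
  coding <- match.arg(coding)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.table(path, header = TRUE, check.names = FALSE,
                         na.strings = c("NA", "-9"))
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (ncol(d) < 6L || !identical(names(d)[1:6], fixed))
    stop("malformed .raw header: expected FID IID PAT MAT SEX PHENOTYPE",
         call. = FALSE)
  snps <- names(d)[-(1:6)]
  out <- data.frame(IID = d$IID)
  for (s in snps) {
    dos <- d[[s]]
    if (any(!is.na(dos) & !dos %in% 0:2))
      stop(sprintf("SNP column '%s' holds non-dosage values", s),
           call. = FALSE)
    out[[s]] <- switch(coding,
      carrier = ,
      dominant = as.integer(dos >= 1),
      recessive = as.integer(dos == 2))
  }
  out
}

# ---- association screen -----------------------------------------------------

# Exact two-sided Fisher probability by enumeration is delegated to
# stats::fisher.test; the test suite checks it against a hypergeometric
# enumeration oracle.

#' Screen one SNP for association with the exposure
#'
#' Builds the 2x2 instrument-by-exposure count table on complete cases and
#' tests independence: Pearson's chi-square test (without continuity
#' correction) when every expected cell count is at least 5, otherwise
#' Fisher's exact test (the conventional operationalisation of the
#' chi-square assumptions).
#'
#' @param table A `"subject_table"`.
#' @param snp Name of the instrument column to screen.
#' @return An object of class `"association_result"`: list with `snp`,
#'   `test` (`"chi-square"` or `"fisher"`), `statistic` (chi-square only),
#'   `p_value` and the 2x2 `table` of counts.
#' @export
snp_screen <- function(table, snp) {
  stopifnot(inherits(table, "subject_table"))
  d <- table$data
  if (!snp %in% names(d)) stop("unknown SNP column: ", snp, call. = FALSE)
  g <- d[[snp]]
  x <- d[[table$map$exposure]]
  keep <- !is.na(g) & !is.na(x)
  tab <- base::table(factor(g[keep], levels = 0:1),
                     factor(x[keep], levels = 0:1))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate 2x2 table: a margin is zero", call. = FALSE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (all(expected >= 5)) {
    ct <- stats::chisq.test(tab, correct = FALSE)
    res <- list(snp = snp, test = "chi-square",
                statistic = unname(ct$statistic),
                p_value = unname(ct$p.value), table = unclass(tab))
  } else {
    ft <- stats::fisher.test(tab)
    res <- list(snp = snp, test = "fisher", statistic = NA_real_,
                p_value = unname(ft$p.value), table = unclass(tab))
  }
  structure(res, class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("SNP %s vs exposure: %s test, p = %.4g\n", x$snp, x$test,
              x$p_value))
  invisible(x)
}

#' Screen several SNPs and rank them by p-value
#'
#' Deterministic rank-by-p selection of top SNPs; an optional seeded random
#' draw from the top of the ranking is available for workflows that sample
#' among the leading hits.
#'
#' @param table A `"subject_table"`.
#' @param snps SNP columns to screen (default: all mapped instruments).
#' @param top Keep this many top-ranked SNPs (default all).
#' @param sample_from Optionally, sample `top` SNPs at random from the
#'   `sample_from` best-ranked ones, using `seed`.
#' @param seed Seed for the optional sampling step.
#' @return Data frame `snp`, `test`, `statistic`, `p_value`, ranked by
#'   ascending p-value.
#' @export
screen_snps <- function(table, snps = NULL, top = NULL, sample_from = NULL,
                        seed = 1L) {
  stopifnot(inherits(table, "subject_table"))
  if (is.null(snps)) snps <- table$map$instruments
  rows <- lapply(snps, function(s) {
    r <- snp_screen(table, s)
    data.frame(snp = r$snp, test = r$test, statistic = r$statistic,
               p_value = r$p_value)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$snp), ]
  rownames(out) <- NULL
  if (!is.null(sample_from) && !is.null(top)) {
    pool <- utils::head(out, sample_from)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    out <- pool[sort(sample.int(nrow(pool), min(top, nrow(pool)))), ]
    rownames(out) <- NULL
  } else if (!is.null(top)) {
    out <- utils::head(out, top)
  }
  out
}

# ---- per-SNP causal analysis ------------------------------------------------

#' Full causal analysis of one SNP instrument
#'
#' On the complete cases for the chosen SNP, exposure, outcome and
#' confounders, runs the three instrumental-variable estimators and the
#' three Wald-ratio estimators (confounders entering both stages of every
#' fit) and tabulates the 3x3 bias matrix `IV estimate - Wald estimate`.
#' Also reports the coefficient panel of the structural-equation fits: the
#' instrument-exposure slope and exposure-stage confounder coefficients, the
#' causal slope and outcome-stage confounder coefficients, each with
#' standard errors and 95% Wald confidence limits, plus the sample
#' prevalences and the complete-case count.
#'
#' @param table A `"subject_table"`.
#' @param snp Instrument column to analyse.
#' @param confounders Confounder columns (default: the mapped confounders).
#' @return An object of class `"snp_analysis"`: list with `snp`, `n`
#'   (complete cases), `estimates` (data frame of the six methods),
#'   `bias` (3x3 matrix, IV methods by Wald methods), `coefficients`
#'   (data frame `stage`, `term`, `estimate`, `se`, `lower`, `upper`),
#'   `pr_x`, `pr_y`.
#' @export
analyze_snp <- function(table, snp, confounders = NULL) {
  stopifnot(inherits(table, "subject_table"))
  d <- table$data
  if (!snp %in% names(d)) stop("unknown SNP column: ", snp, call. = FALSE)
  if (is.null(confounders)) confounders <- table$map$confounders
  cols <- c(snp, table$map$exposure, table$map$outcome, confounders)
  cc <- stats::complete.cases(d[cols])
  dd <- d[cc, cols]
  data3 <- list(Z = dd[[snp]], X = dd[[table$map$exposure]],
                Y = dd[[table$map$outcome]])
  cov <- if (length(confounders)) dd[confounders] else NULL
  wald <- list(wald_logistic = wald_logistic(data3, cov),
               wald_lpm = wald_lpm(data3, cov),
               wald_transformation = wald_transformation(data3, cov))
  iv <- list(sem = estimate_sem(data3, cov),
             tsps = estimate_tsps(data3, cov, se = FALSE),
             tsri = estimate_tsri(data3, cov, se = FALSE))
  getv <- function(e) if (e$valid) e$estimate else NA_real_
  est <- data.frame(method = c(names(iv), names(wald)),
                    estimate = c(vapply(iv, getv, numeric(1)),
                                 vapply(wald, getv, numeric(1))),
                    valid = c(vapply(iv, function(e) e$valid, logical(1)),
                              vapply(wald, function(e) e$valid, logical(1))))
  bias <- outer(vapply(iv, getv, numeric(1)), vapply(wald, getv, numeric(1)),
                compute_bias)
  dimnames(bias) <- list(names(iv), names(wald))
  sem <- iv$sem
  coef_panel <- NULL
  if (sem$valid) {
    panel_stage <- function(fit, stage) {
      ci <- stats::qnorm(0.975) * fit$standard_errors
      data.frame(stage = stage, term = names(fit$coefficients),
                 estimate = unname(fit$coefficients),
                 se = unname(fit$standard_errors),
                 lower = unname(fit$coefficients - ci),
                 upper = unname(fit$coefficients + ci))
    }
    coef_panel <- rbind(panel_stage(sem$first_stage, "exposure"),
                        panel_stage(sem$second_stage, "outcome"))
    rownames(coef_panel) <- NULL
  }
  structure(list(snp = snp, n = nrow(dd), estimates = est, bias = bias,
                 coefficients = coef_panel,
                 pr_x = mean(data3$X), pr_y = mean(data3$Y)),
            class = "snp_analysis")
}

#' @export
print.snp_analysis <- function(x, ...) {
  cat(sprintf("SNP %s: n = %d, prevalence(X) = %.3f, prevalence(Y) = %.3f\n",
              x$snp, x$n, x$pr_x, x$pr_y))
  print(x$estimates)
  cat("Bias matrix (IV - Wald):\n")
  print(round(x$bias, 3))
  invisible(x)
}

#' Tabulate several SNP analyses as tidy data frames
#'
#' @param analyses List of `"snp_analysis"` objects.
#' @return List of two data frames: `effects` (one row per SNP, method and
#'   Wald comparison, with estimate and bias) and `characteristics` (the
#'   per-SNP coefficient panels with `snp`, `n` and prevalences attached).
#' @export
tabulate_snp_analyses <- function(analyses) {
  eff <- do.call(rbind, lapply(analyses, function(a) {
    g <- expand.grid(iv_method = rownames(a$bias),
                     wald_method = colnames(a$bias),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    data.frame(snp = a$snp, g,
               iv_estimate = a$estimates$estimate[match(g$iv_method,
                                                        a$estimates$method)],
               wald_estimate = a$estimates$estimate[match(g$wald_method,
                                                          a$estimates$method)],
               bias = a$bias[cbind(g$iv_method, g$wald_method)])
  }))
  chars <- do.call(rbind, lapply(analyses, function(a) {
    if (is.null(a$coefficients)) return(NULL)
    cbind(data.frame(snp = a$snp, n = a$n, pr_x = a$pr_x, pr_y = a$pr_y),
          a$coefficients)
  }))
  rownames(eff) <- NULL
  if (!is.null(chars)) rownames(chars) <- NULL
  list(effects = eff, characteristics = chars)
}

# ---- synthetic cohort generator ---------------------------------------------

#' Profile for the synthetic cohort generator
#'
#' Defaults emulate the scale and structure of the applied cohort: about
#' 2,330 dogs, one causal SNP instrument of prevalence 0.2 with strength 0.7
#' on the log-odds scale, four binary confounders of prevalence 0.5 entering
#' both equations, exposure prevalence 0.18, outcome prevalence 0.091, and a
#' small positive causal effect (0.08 log-odds, the scale of the applied
#' estimates). Intercepts are calibrated so the realised prevalences match
#' the targets.
#'
#' @param n Cohort size.
#' @param n_snps Number of SNP columns (SNP 1 is the causal instrument; the
#'   others are noisy copies emulating correlated top hits, flip
#'   probability `ld_flip`).
#' @param p_instrument Instrument (carrier) prevalence.
#' @param alpha1 Instrument strength on the exposure (log-odds).
#' @param beta1 True causal effect of exposure on outcome (log-odds).
#' @param target_px,target_py Target marginal prevalences of exposure and
#'   outcome.
#' @param conf_x,conf_y Log-odds effects of the four binary confounders on
#'   exposure and outcome (defaults on the scale seen in the applied fits).
#' @param p_conf Confounder prevalences.
#' @param ld_flip Flip probability linking SNPs 2..n_snps to SNP 1.
#' @param missing_rate Per-cell missingness rate applied to SNP columns.
#' @return A list of class `"fixture_profile"`.
#' @export
fixture_profile <- function(n = 2330L, n_snps = 5L, p_instrument = 0.2,
                            alpha1 = 0.7, beta1 = 0.08,
                            target_px = 0.18, target_py = 0.091,
                            conf_x = c(-0.26, -0.11, -0.64, -0.23),
                            conf_y = c(-0.19, 0.07, 0.84, 0.40),
                            p_conf = rep(0.5, 4), ld_flip = 0.05,
                            missing_rate = 0.003) {
  stopifnot(length(conf_x) == length(conf_y),
            length(p_conf) == length(conf_x),
            n >= 2, n_snps >= 1, p_instrument > 0, p_instrument < 1,
            target_px > 0, target_px < 1, target_py > 0, target_py < 1)
  structure(list(n = as.integer(n), n_snps = as.integer(n_snps),
                 p_instrument = p_instrument, alpha1 = alpha1, beta1 = beta1,
                 target_px = target_px, target_py = target_py,
                 conf_x = conf_x, conf_y = conf_y, p_conf = p_conf,
                 ld_flip = ld_flip, missing_rate = missing_rate),
            class = "fixture_profile")
}

# Calibrate the two intercepts by bisection on the marginal prevalence,
# evaluated over a fixed large Monte-Carlo draw of (Z, confounders, U) so
# the marginal is a smooth deterministic function of the intercept.
.calibrate_intercepts <- function(profile, n_cal = 2e5, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.rep_seed(seed, 777L))
  Z <- stats::rbinom(n_cal, 1L, profile$p_instrument)
  U <- stats::rnorm(n_cal)
  C <- vapply(profile$p_conf, function(p) stats::rbinom(n_cal, 1L, p),
              integer(n_cal))
  lin_x <- profile$alpha1 * Z + drop(C %*% profile$conf_x) + 0 * U
  lin_y_conf <- drop(C %*% profile$conf_y) + 0 * U
  marg_x <- function(a0) mean(expit(a0 + lin_x))
  solve_icpt <- function(f, target) {
    lo <- -20; hi <- 20
    if ((f(lo) - target) * (f(hi) - target) > 0)
      stop("unattainable prevalence target: intercept search out of bounds",
           call. = FALSE)
    stats::uniroot(function(t) f(t) - target, c(lo, hi), tol = 1e-8)$root
  }
  alpha0 <- solve_icpt(marg_x, profile$target_px)
  px <- expit(alpha0 + lin_x)
  marg_y <- function(b0) {
    mean(px * expit(b0 + profile$beta1 + lin_y_conf) +
         (1 - px) * expit(b0 + lin_y_conf))
  }
  beta0 <- solve_icpt(marg_y, profile$target_py)
  c(alpha0 = alpha0, beta0 = beta0)
}

#' Generate a synthetic cohort table
#'
#' Extends the simulation model of [sim_config()] with binary confounders in
#' both logistic equations and emits a [subject_table()] shaped like the
#' applied cohort: `id`, SNP columns, exposure, outcome, confounders.
#' Intercepts are calibrated by bisection so the realised prevalences
#' approximate the profile's targets; SNPs beyond the first are noisy copies
#' of the causal instrument and sparse missingness is injected into the SNP
#' columns so per-SNP complete-case counts differ.
#'
#' @param profile A [fixture_profile()].
#' @param seed Integer seed; the same seed reproduces the identical table.
#' @return A `"subject_table"` whose column map names the SNP columns
#'   `snp1..snpK`, exposure `exposure`, outcome `outcome` and confounders
#'   `conf1..conf4` (or however many the profile defines).
#' @export
make_fixture <- function(profile = fixture_profile(), seed = 1L) {
  stopifnot(inherits(profile, "fixture_profile"))
  icpt <- .calibrate_intercepts(profile, seed = seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.rep_seed(seed, 0L))
  n <- profile$n
  k <- length(profile$conf_x)
  Z <- stats::rbinom(n, 1L, profile$p_instrument)
  C <- vapply(profile$p_conf, function(p) stats::rbinom(n, 1L, p), integer(n))
  X <- stats::rbinom(n, 1L, expit(icpt["alpha0"] + profile$alpha1 * Z +
                                  drop(C %*% profile$conf_x)))
  Y <- stats::rbinom(n, 1L, expit(icpt["beta0"] + profile$beta1 * X +
                                  drop(C %*% profile$conf_y)))
  snps <- matrix(NA_integer_, n, profile$n_snps)
  snps[, 1] <- Z
  if (profile$n_snps > 1) {
    for (j in 2:profile$n_snps) {
      flip <- stats::rbinom(n, 1L, profile$ld_flip)
      snps[, j] <- ifelse(flip == 1L, 1L - Z, Z)
    }
  }
  if (profile$missing_rate > 0) {
    for (j in seq_len(profile$n_snps)) {
      miss <- stats::rbinom(n, 1L, profile$missing_rate) == 1L
      snps[miss, j] <- NA_integer_
    }
  }
  d <- data.frame(id = sprintf("subj%05d", seq_len(n)))
  for (j in seq_len(profile$n_snps)) d[[paste0("snp", j)]] <- snps[, j]
  d$exposure <- X
  d$outcome <- Y
  for (j in seq_len(k)) d[[paste0("conf", j)]] <- C[, j]
  subject_table(d, list(id = "id",
                        instruments = paste0("snp", seq_len(profile$n_snps)),
                        exposure = "exposure", outcome = "outcome",
                        confounders = paste0("conf", seq_len(k))))
}
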