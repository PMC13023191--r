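test_that("subject tables validate coding and roundtrip through CSV", {
  prof <- fixture_profile(n = 300, missing_rate = 0.01)
  tab <- make_fixture(prof, seed = 5)
  expect_s3_class(tab, "subject_table")
  expect_equal(nrow(tab$data), 300)
  path <- tempfile(fileext = ".csv")
  write_subject_table(tab, path)
  back <- read_subject_table(path, tab$map)
  expect_equal(back$data$exposure, tab$data$exposure)
  expect_equal(back$data$snp1, tab$data$snp1)
  expect_equal(back$flagged_rows, tab$flagged_rows)
  # a non-binary value is rejected with its row number
  d <- tab$data
  d$outcome[17] <- 2
  expect_error(subject_table(d, tab$map), "17")
  # unmapped required column
  expect_error(subject_table(tab$data,
                             list(instruments = "nope", exposure = "exposure",
                                  outcome = "outcome")),
               "absent")
  expect_error(subject_table(tab$data, list(exposure = "exposure",
                                            outcome = "outcome")),
               "instruments")
})

test_that("PLINK additive dosages map to binary instruments", {
  path <- tempfile(fileext = ".raw")
  writeLines(c(
    "FID IID PAT MAT SEX PHENOTYPE snpA_G snpB_T",
    "f1 d1 0 0 1 -9 0 2",
    "f2 d2 0 0 2 -9 1 1",
    "f3 d3 0 0 1 -9 2 0",
    "f4 d4 0 0 2 -9 NA 2",
    "f5 d5 0 0 1 -9 1 NA"), path)
  frag <- read_plink_raw(path)
  expect_equal(ncol(frag) - 1L, 2L)  # SNP count = header count - 6
  expect_equal(frag$snpA_G, c(0L, 1L, 1L, NA, 1L))
  rec <- read_plink_raw(path, coding = "recessive")
  expect_equal(rec$snpA_G, c(0L, 0L, 1L, NA, 0L))
  expect_equal(rec$snpB_T, c(1L, 0L, 0L, 1L, NA))
  bad <- tempfile(fileext = ".raw")
  writeLines(c("FID ID PAT MAT SEX PHENOTYPE snpA", "f1 d1 0 0 1 -9 0"), bad)
  expect_error(read_plink_raw(bad), "header")
})

test_that("the association screen picks the test from expected counts", {
  mk <- function(g, x) {
    subject_table(data.frame(snp = g, exposure = x,
                             outcome = rep(c(0, 1), length.out = length(g))),
                  list(instruments = "snp", exposure = "exposure",
                       outcome = "outcome"))
  }
  # perfectly balanced 2x2: chi-square, statistic 0, p = 1
  g <- rep(c(0, 1), each = 40)
  x <- rep(c(0, 1, 0, 1), each = 20)
  r <- snp_screen(mk(g, x), "snp")
  expect_equal(r$test, "chi-square")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # sparse cell (min expected count 8*14/24 < 5): Fisher chosen, p matches
  # the enumeration oracle
  g2 <- c(rep(0, 8), rep(1, 16))
  x2 <- c(rep(0, 1), rep(1, 7), rep(0, 13), rep(1, 3))
  r2 <- snp_screen(mk(g2, x2), "snp")
  expect_equal(r2$test, "fisher")
  expect_equal(r2$p_value, oracle_fisher(r2$table), tolerance = 1e-9)
  # zero margin is degenerate
  expect_error(snp_screen(mk(rep(0, 20), rep(c(0, 1), 10)), "snp"),
               "margin")
})

test_that("Fisher p-values equal exact enumeration on random small tables", {
  set.seed(123)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 4) + c(1, 0, 0, 1), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ft <- stats::fisher.test(tab)
    expect_equal(ft$p.value, oracle_fisher(tab), tolerance = 1e-9)
  }
})

test_that("screening ranks SNPs by p-value deterministically", {
  tab <- make_fixture(fixture_profile(n = 1500), seed = 9)
  scr <- screen_snps(tab)
  expect_equal(nrow(scr), 5)
  expect_true(!is.unsorted(scr$p_value))
  top2 <- screen_snps(tab, top = 2)
  expect_equal(top2$snp, scr$snp[1:2])
  samp <- screen_snps(tab, top = 2, sample_from = 4, seed = 3)
  expect_equal(nrow(samp), 2)
  expect_identical(samp, screen_snps(tab, top = 2, sample_from = 4, seed = 3))
})

test_that("fixture generation is deterministic and hits prevalence targets", {
  prof <- fixture_profile(n = 2330)
  t1 <- make_fixture(prof, seed = 11)
  t2 <- make_fixture(prof, seed = 11)
  expect_identical(t1$data, t2$data)
  expect_false(identical(t1$data, make_fixture(prof, seed = 12)$data))
  # cohort-scale prevalences in the right neighbourhood even at n = 2330
  expect_lt(abs(mean(t1$data$exposure) - 0.18), 0.03)
  expect_lt(abs(mean(t1$data$outcome) - 0.091), 0.03)
  # unattainable target is a calibration error
  expect_error(make_fixture(fixture_profile(n = 500, target_py = 1e-12),
                            seed = 1),
               "unattainable|bounds")
})

test_that("per-SNP analysis uses complete cases and the shared kernels", {
  prof <- fixture_profile(n = 4000, missing_rate = 0.02)
  tab <- make_fixture(prof, seed = 21)
  a <- analyze_snp(tab, "snp2")
  # complete-case count is reproducible from the missingness mask
  cols <- c("snp2", "exposure", "outcome", paste0("conf", 1:4))
  expect_equal(a$n, sum(stats::complete.cases(tab$data[cols])))
  expect_lt(a$n, nrow(tab$data))
  # estimates equal the estimator functions run directly on the same columns
  cc <- stats::complete.cases(tab$data[cols])
  d3 <- list(Z = tab$data$snp2[cc], X = tab$data$exposure[cc],
             Y = tab$data$outcome[cc])
  cov <- tab$data[cc, paste0("conf", 1:4)]
  direct <- mr_estimates(d3, cov)
  for (m in direct$method) {
    expect_equal(a$estimates$estimate[a$estimates$method == m],
                 direct$estimate[direct$method == m], tolerance = 1e-10)
  }
  # bias matrix respects the sign convention
  est <- function(m) a$estimates$estimate[a$estimates$method == m]
  expect_equal(a$bias["sem", "wald_logistic"],
               est("sem") - est("wald_logistic"))
  expect_equal(a$bias["tsri", "wald_lpm"], est("tsri") - est("wald_lpm"))
  # coefficient panel carries both stages with confidence limits
  expect_true(all(c("exposure", "outcome") %in% a$coefficients$stage))
  expect_true(all(a$coefficients$lower <= a$coefficients$estimate))
  tabs <- tabulate_snp_analyses(list(a, analyze_snp(tab, "snp1")))
  expect_equal(nrow(tabs$effects), 18)
  expect_true(all(c("snp", "n", "pr_x", "pr_y") %in%
                  names(tabs$characteristics)))
})

test_that("null-effect cohorts with a strong instrument center on zero bias", {
  # At the cohort's low prevalences the transformation/LPM Wald ratios
  # amplify the logistic-ratio sampling noise by 1/(pr_x(1-pr_x)) ~ 6.8, so
  # zero-bias recovery is checked on the median over independent cohorts:
  # per-cohort pair noise is at most ~0.27 sd at n = 1e5, giving a median
  # 3-sigma band of ~0.32 over 10 cohorts.
  prof <- fixture_profile(n = 1e5, n_snps = 1, beta1 = 0,
                          conf_x = rep(0, 4), conf_y = rep(0, 4),
                          alpha1 = 0.7, missing_rate = 0)
  biases <- lapply(1:10, function(s) {
    a <- analyze_snp(make_fixture(prof, seed = 300 + s), "snp1",
                     confounders = character(0))
    expect_true(all(a$estimates$valid))
    a$bias
  })
  med <- apply(simplify2array(biases), c(1, 2), stats::median)
  expect_true(all(abs(med) < 0.35))
})
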