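---
title: "Methods: binary-trait Mendelian randomization in binmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binary-trait Mendelian randomization in binmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binmr)
```

## The problem

Mendelian randomization (MR) uses a genetic variant as an instrumental
variable to estimate the causal effect of an exposure on an outcome from
observational data. With a single valid instrument the canonical estimator is
the Wald ratio: the instrument–outcome association divided by the
instrument–exposure association. When exposure and outcome are both
*continuous* this ratio targets the causal slope directly. When both are
*binary* and the associations are estimated by logistic regression, the ratio
lives on a "log-odds per log-odds" scale, and — because odds ratios are
noncollapsible — it does not recover the causal log-odds coefficient even
with a perfectly valid instrument and no confounding of the
instrument–trait relations.

`binmr` implements the estimators relevant to this setting, a simulator for
the confounded data-generating process, and a replicated bias study that
quantifies how far each Wald-ratio variant sits from each of three
instrumental-variable (IV) estimators.

## Data-generating model

All simulated data come from a bivariate-Bernoulli structural model with a
latent standard-normal confounder $U$:

$$Z_i \sim \mathrm{Bern}(p_Z), \qquad U_i \sim N(0,1),$$
$$X_i \sim \mathrm{Bern}\{\mathrm{expit}(\alpha_0 + \alpha_1 Z_i + c_x U_i)\},$$
$$Y_i \sim \mathrm{Bern}\{\mathrm{expit}(\beta_0 + \beta_1 X_i + c_y U_i)\}.$$

$\alpha_1$ is the instrument strength, $\beta_1$ the true causal effect (both
log-odds), and $c_x, c_y$ the confounder effects. $U$ is stored in each
simulated dataset; whether estimators may condition on it is an explicit
choice of the bias study (below), not a property of the data.

The core study crosses four scenarios — null ($\beta_1 = 0$) versus positive
($\beta_1 = 1$) effect, weak ($c = 0.01$) versus strong ($c = 1.5$)
confounding — with instrument strengths $\alpha_1 \in \{0.01, 0.05, 0.1,
0.5, 0.7\}$, at $n = 1000$, $p_Z = 0.2$, $\alpha_0 = \beta_0 = 0$, and 8000
replicates per cell by default. Four sensitivity grids vary, in turn, the
sample size (50–1500), the instrument prevalence (0.1–0.8), the trait
prevalences (through intercepts $0, 1, 3, -2$, crossed with all five
instrument strengths), and the confounder effect (0.01–2). Every printed
scenario ties $c_x = c_y$, so the grid builders enforce that; nothing in the
estimators requires it.

## Estimators

Let $\hat\alpha_1$ be the slope of logistic $X$ on $Z$ and $\hat\gamma_1$ the
slope of logistic $Y$ on $Z$ (the "reduced form"). With $v(p) = p(1-p)$ and
$\hat p_X, \hat p_Y$ the sample prevalences:

* **Wald, logistic** — $\hat\gamma_1 / \hat\alpha_1$.
* **Wald, linear probability model (LPM)** — both stages by ordinary least
  squares; the slope ratio (a probability-scale effect) is mapped to the
  log-odds scale by dividing by $v(\hat p_Y)$.
* **Wald, transformation** — the logistic slopes are first mapped to the
  linear scale with the prevalence approximation
  $\beta_{\text{linear}} = \beta_{\text{logistic}} \, v(p)$ (the exposure
  slope at $\hat p_X$, the outcome slope at $\hat p_Y$), the ratio is taken
  on the linear scale, and the result is mapped back with $1/v(\hat p_Y)$.
  Algebraically this equals the logistic Wald ratio divided by
  $v(\hat p_X)$; the package still computes it by the three-step
  composition so that the recorded numerator/denominator match the
  procedure's definition.
* **SEM** — the two structural logistic equations. With binary responses no
  cross-equation error correlation can be specified, so simultaneous and
  sequential maximum likelihood coincide: the causal coefficient is the
  slope of logistic $Y$ on $X$, and the instrument never enters the outcome
  equation.
* **TSPS** (two-stage predictor substitution) — logistic $Y$ on the
  first-stage fitted probabilities $\hat P_X$.
* **TSRI** (two-stage residual inclusion) — logistic $Y$ on $X$ and the
  first-stage residual $X - \hat P_X$; the estimate is the coefficient on
  $X$.

In applied (cohort) mode, measured confounders enter both stages of every
estimator and both regressions of every Wald method.

Which trait's prevalence enters the back-transformation is a genuine choice;
the package uses the outcome's, consistent with the transformation
equation's definition of $pr$ as the outcome trait's probability, and
records the prevalence actually used in every result object so the choice is
auditable. Prevalences are sample proportions from the analysis data, not
model-based estimates.

## Bias study

For each replicate, all six estimators run on the same dataset and the bias
of Wald method $w$ under IV method $m$ is the signed difference
$\hat\beta_m - \hat\beta_w$ (absolute, not percentage, bias: the estimators
sit on different effect scales, so percentage bias would not compare them
fairly). Each grid cell is summarised by the median and the first and third
quartiles over valid replicates.

By default (`adjust_confounder = TRUE` in `run_cell()`/`run_study()`) the
simulated confounder $U$ is handed to every estimator as a *measured*
adjustment covariate: it enters both stages of SEM, TSPS and TSRI and both
regressions of each Wald method, exactly as measured confounders do in the
applied cohort workflow. Under this protocol the residual differences
between the IV estimators and the Wald ratios isolate what the study is
about — the scale and noncollapsibility gaps between the methods — rather
than being dominated by uncorrected confounding bias, and the strong- and
weak-confounding scenarios become informative about how conditioning on a
prognostic covariate changes each estimator's scale. Two observable
consequences of the alternative, fully blinded protocol
(`adjust_confounder = FALSE`, estimators see only $Z, X, Y$) are worth
knowing: under strong confounding the SEM column simply reproduces the
confounded exposure–outcome association, and — because with a binary
instrument the TSPS second stage regresses on a two-valued fitted
probability — TSPS remains an exact transform of the reduced-form group
logits, pinning its difference from the LPM and transformation Wald ratios
near zero at weak instruments regardless of confounding. Both protocols are
available; the default is the adjusted one.

Numerical conventions:

* **Quantiles** use linear interpolation between order statistics
  (`stats::quantile` type 7, the common statistical-software default), so
  `c(1, 2, 3, 4)` gives Q1 = 1.75, median = 2.5, Q3 = 3.25.
* **Failures.** Fits that do not converge, are separated, or produce an
  instrument–exposure slope with $|\hat\alpha_1| < 10^{-8}$ are flagged
  invalid; the affected pair's bias for that replicate is missing, and
  summaries report `n_valid` alongside the quantiles (quantiles over valid
  entries only). Extreme but finite ratios are *retained* — no winsorizing
  or capping — since weak-instrument ratio estimators genuinely have heavy
  tails and trimming them would understate the spread.
* **Reproducibility.** Each replicate draws from a substream derived
  deterministically from (master seed, replicate index), so any replicate is
  reproducible in isolation and results are independent of execution order.

## Fitting kernels and degenerate fits

Every logistic stage runs through one iteratively-reweighted least-squares
maximum-likelihood kernel (relative deviance change $< 10^{-8}$, at most 100
iterations); every LPM stage through one QR least-squares kernel. The
applied workflow and the simulation study therefore share their arithmetic
exactly, and the test suite cross-checks the kernel against `stats::glm` as
an independent oracle.

Separation is flagged when the fit fails to converge, or when a standardized
slope exceeds 15 *and* the linear predictor exceeds 20 in absolute value
(fitted probabilities numerically at 0 or 1). Both conditions are required
deliberately: under a weak instrument the TSRI second stage regresses $Y$ on
the nearly-collinear pair $(X, X - \hat P_X)$, which inflates both
coefficients while the linear predictor stays bounded — those are
legitimate, finite maximum-likelihood estimates and are kept. Under true
separation the estimates and the linear predictor diverge together (the
deviance plateau of the kernel stops near $|\eta| \approx 25$, while
legitimate fits in this setting stay below $\approx 10$, hence the threshold
of 20 between the two regimes).

A rank-deficient design supplied by the user (a constant covariate, say) is
an error; rank deficiency an estimator produces internally — a constant
first-stage fitted probability when $\hat\alpha_1 = 0$ exactly, which makes
the TSPS stage-2 design singular and the TSRI regressors collinear — is
reported as an invalid estimate, never as a silent zero.

## Applied cohort workflow

The applied mode consumes a flat subject table (0/1 columns for
instrument(s), exposure, outcome and confounders, missingness allowed) and
optionally a PLINK `--recode A` dosage export. Choices a user should be
aware of:

* **SNP dichotomisation** defaults to carrier coding (dosage ≥ 1 → 1), with
  dominant/recessive alternatives. No convention is universal; the coding
  changes the instrument, so it is an explicit argument.
* **Association screen:** the 2×2 instrument-by-exposure table is tested
  with Pearson's chi-square (no continuity correction) when all expected
  cell counts are at least 5, otherwise with Fisher's exact test — the
  conventional operationalisation of the chi-square assumptions.
* **Top-SNP choice** is deterministic rank-by-p, with an optional
  seed-controlled random draw from the leading hits for workflows that
  sample among them.
* **Missing data:** complete cases per SNP, so per-SNP sample sizes differ
  under scattered genotype missingness; the complete-case count is reported
  with every analysis.

## The synthetic cohort generator

`make_fixture()` extends the simulation model with four binary confounders
entering both logistic equations, and calibrates the two intercepts by root
finding on the marginal prevalences (evaluated over a fixed large
Monte-Carlo draw of instrument, confounders and latent confounder, so the
marginal is a smooth deterministic function of the intercept). The default
profile emulates the scale of a prospective dog-cohort study: n ≈ 2,330, one
causal SNP of prevalence 0.2 and strength 0.7, exposure prevalence 0.18,
outcome prevalence 0.091, confounder effects on the scale seen in such
cohorts, and additional SNP columns generated as noisy copies of the causal
one (flip probability 0.05) to emulate correlated top hits, with sparse
missingness so per-SNP complete-case counts differ.

What the generator does *not* emulate: genuine linkage-disequilibrium
structure, population stratification, pleiotropy, non-binary genotype
effects, and time-to-event outcome ascertainment. Tests that pass on these
cohorts therefore validate the estimators' arithmetic and the workflow's
bookkeeping, not robustness to those real-data complications.

## Test and acceptance problem sizes

The package's replicated checks run the four core scenarios at the weakest
and strongest instrument strengths (eight cells, 4000 replicates per cell —
the scale at which the median of even the heaviest-tailed bias pair, with
interquartile range near 8, has sampling error around 0.12) and the
instrument-prevalence sensitivity grid (sixteen cells at 2000 replicates).
`n_reps` defaults to the full 8000 of the study design. Estimator-consistency checks use single
draws of $10^5$ subjects; cohort null-recovery uses the median over ten
generated cohorts of $10^5$ because, at the default cohort prevalences, the
transformation and LPM Wald ratios amplify reduced-form sampling noise by
$1/v(\hat p_X) \approx 6.8$, putting a single-draw zero-bias band near
±0.4.

Interquartile-range behaviour across instrument strengths is checked
directionally against the published pattern rather than as a blanket
"always tightens" rule: most pairs tighten sharply as the instrument
strengthens, but the TSPS/TSRI-versus-transformation spreads in the
weak-confounding scenarios start near zero (the estimators almost coincide
at a vanishing instrument) and therefore widen.

One qualitative check is deliberately stricter than Monte-Carlo precision
allows and is expected to fail at desk scale: requiring every pair's median
bias to move by less than 0.15 across instrument prevalences. For pairs
whose bias distribution has an interquartile range near 8, the median's
sampling error at 2000 replicates is about 0.165 per cell, so the expected
range across four independent cells exceeds the band even when the true
median is perfectly constant. The narrow-IQR pairs do satisfy it; the check
is retained as specified, with this note as the explanation.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(alpha1 = 0.7, beta1 = 1, n = 1000, n_reps = 2000, seed = 1)
summarize_bias(run_cell(cfg))

tab <- make_fixture(fixture_profile(), seed = 1)
screen_snps(tab)
analyze_snp(tab, "snp1")
```

## Known limitations

* Single-instrument methods only: no multi-SNP instruments, no
  inverse-variance weighting, no pleiotropy-robust estimators.
* Point estimates only for the Wald ratios (no standard errors or
  confidence intervals); stage coefficients do carry standard errors.
* The LPM stages are plain ordinary least squares; the weighted two-step
  refinement for heteroscedastic binary-response errors is out of scope.
* Genotype quality control (missingness, Hardy–Weinberg, relatedness, LD
  pruning) is a prerequisite performed upstream, not a feature of this
  package.
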