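---
title: "Modelling polygenic prediction of cognitive level and decline: methods"
author: "cogslope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling polygenic prediction of cognitive level and decline: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Cognitive abilities decline in older age, and the declines are correlated
across domains: much of individual variation in cognitive ageing is captured
by a single general dimension. `cogslope` implements an analysis stack for
asking whether genome-wide polygenic scores (PGSs) — per-person sums of
risk-allele dosages weighted by GWAS effect sizes — predict (a) the *level*
of general cognitive ability in the eighth decade of life, (b) its *slope*
(rate of change) across roughly a decade of follow-up, and (c) *lifetime
cognitive change*, operationalized as late-life general ability adjusted for
a childhood cognitive test taken by the same people.

Because individual-level data of the motivating study design are not
public, the package is organized around a synthetic-cohort generator that
reproduces the study's data *structure* — 13 cognitive tests in 4 domains
measured at 4 waves about three years apart, monotone health-selected
dropout from 1091 at wave 1 to 550 at wave 4, small standardized polygenic
effects on the level, and a binary *APOE*-e4-like risk indicator with a
substantial slope effect — so that every stage of the pipeline is testable
end to end against known truth.

# The factors-of-curves model

For test $t$ observed at wave $w$ with time basis $\tau_w$ (years since
wave 1; default $\tau = (0, 2.98, 6.71, 9.78)$, derived from the mean ages
at the four waves), the first layer is a linear latent growth curve

$$ y_{itw} = I_{it} + \tau_w\, S_{it} + \varepsilon_{itw},\qquad
   \varepsilon_{itw} \sim N(0, \theta_t), $$

with the occasion residual variance $\theta_t$ constant over waves. The
latent intercepts ("levels") and slopes are then factor-analysed
hierarchically: each test's intercept loads on one of four domain level
factors (visuospatial, verbal memory, crystallized, processing speed), the
domain factors load on a general level factor $g$, and the same two-layer
structure holds for the slopes with a general slope factor $g_s$:

$$ I_{it} = \mu^I_t + \lambda^L_t\, L_{d(t),i} + u_{it}, \qquad
   L_{d,i} = \gamma^L_d\, g_i + e_{d,i}, $$

and analogously for $S_{it}$ with loadings $\lambda^S_t$, $\gamma^S_d$ on
$g_{s}$. The general factors may covary; each test's intercept and slope
residuals ($u_{it}$, $v_{it}$) may covary within test; no other residual
covariances are admitted. Squaring the product of a test's standardized
loading on its domain and the domain's standardized loading on the general
factor gives the proportion of that test's latent level (or slope) variance
explained by the general factor; `variance_decomposition()` reports the
per-test shares and their layer means.

## Identification

The general factor variances are fixed at 1. Each domain factor is scaled
by a *marker variable*: the first test of each domain has its loading on
the domain factor fixed at 1, with the domain residual variance free. An
alternative sometimes written down — leaving all hierarchical loadings
*and* all domain residual variances free with only the top-level variance
fixed — is not identified: rescaling a domain factor while inversely
rescaling its loadings leaves the likelihood unchanged. The marker
convention removes exactly this indeterminacy; standardized loadings and
variance shares are invariant to the choice.

With 13 tests × 4 waves = 52 observed variables there are
$52\cdot 55/2 = 1430$ observed moments and 113 free parameters
(per test: 2 factor means, 2 residual variances, 1 residual covariance, 1
occasion variance; 9 free level and 9 free slope test loadings; 4 + 4
domain loadings and 4 + 4 domain residual variances per layer; 1
general-factor covariance), so the baseline model has 1317 degrees of
freedom.

## Estimation: FIML

Missing data are handled by full-information maximum likelihood: rows are
grouped by missingness pattern, and each row contributes the
multivariate-normal log-density of its observed sub-vector under the
corresponding sub-mean and sub-covariance of the model-implied moments.
This is valid when missingness is *missing at random* (MAR) — dependent on
observed, not unobserved, values. The synthetic dropout mechanism selects
on the previous wave's *observed* composite, so MAR holds by construction
with respect to the full battery; note it does **not** hold with respect to
any single test analysed alone, which is why the MAR-robustness check
compares full-battery FIML with listwise deletion.

The model is written in RAM form (matrices $A$, $S$, $M$); the likelihood
and its analytic gradient are computed in compiled code
(`src/fiml.cpp`). Numerical choices that matter:

* **Column scaling.** Each test is analysed on its baseline-SD scale. The
  battery's raw SDs span a factor of ~200 (reaction time in seconds vs.
  memory sum scores), which otherwise leaves quasi-Newton optimization
  stuck far from the optimum. Standardized outputs are unaffected;
  raw-unit quantities (e.g. per-year raw change) are back-transformed.
* **Optimizer.** L-BFGS-B on log-transformed variances (floored at
  $10^{-6}$ on the scaled metric), restarted until the log-likelihood
  stops improving, followed by damped Newton steps using the
  finite-difference Hessian of the analytic gradient. The polish matters:
  without it the slope-variance directions — long, flat valleys —
  terminate early and standardized slope loadings are attenuated by
  ~0.06 even at $n = 20{,}000$. Convergence requires a projected gradient
  norm below $10^{-3}$ on the optimizer scale; multiple jittered starts
  (default 5) guard against local optima.
* **Standard errors** come from the inverse observed information
  (finite differences of the analytic gradient at the optimum).
* **Saturated model** for fit indices is estimated by an EM algorithm for
  the unstructured MVN under missingness; the independence baseline has a
  closed-form FIML solution. $\chi^2 = 2(\ell_{sat} - \ell_m)$;
  RMSEA uses $N$ in the denominator; CFI/TLI use the independence
  baseline; SRMR is computed from standardized covariance residuals
  between the FIML-saturated and implied covariances.
* **Degenerate inputs.** A singular pattern covariance yields a large
  negative penalty (never a silent `NaN`); noiseless data drive variances
  to the floor and are handled by bound projection.

## Factor scores and the two estimation routes

Genetic associations can be estimated two ways, and every result records
which was used:

* `method = "sem"`: the predictor (plus four ancestry components, and
  optionally the APOE indicator or the age-11 score) is an exogenous
  observed variable regressed onto $g$ and $g_s$ inside the model.
  Exogenous variables get a saturated moment block; complete cases are
  required for them (FIML covers the cognitive indicators). Reported
  betas are standardized with respect to the outcome always — using the
  model-implied total variance of the general factor — and with respect
  to the predictor only when it is continuous (binary predictors enter
  0/1).
* `method = "factor_score"`: regression-method factor scores
  $\hat\eta_i = \mu_\eta + \Sigma_{\eta y_o}\Sigma_{y_o}^{-1}(y_o - \mu_o)$
  are computed per missingness pattern from a base model without
  predictors, then ordinary least squares is run on the standardized
  scores. Regression scores are shrunken, so factor-score betas are
  attenuated by roughly the square root of the factor-score reliability
  relative to the in-SEM route; on well-behaved synthetic data the two
  routes agree within twice their standard errors. The SEM route falls
  back to this one automatically when no start converges, mirroring what
  analysts do when complex growth SEMs fail.

Mediation of the education-score effect on lifetime change by attained
years of education is estimated on the factor-score route: $a$ from the
mediator regression, $b$ and the direct path $c'$ from the outcome
regression (outcome = standardized general-level score, adjusted for the
age-11 score), indirect $= ab$, proportion mediated $= ab/(ab + c')$, with
a delta-method (Sobel) standard error for the indirect effect. Outcome-side
factor-score shrinkage multiplies $b$ and $c'$ equally and therefore leaves
the proportion mediated consistent. The proportion is flagged unstable when
$|ab + c'| < 10\,\mathrm{SE}$.

# The polygenic score engine

Scores are built from GWAS summary statistics by the standard
clumping-and-thresholding recipe: harmonize alleles against the target
genotypes (sign flips for swapped alleles, strand flips accepted,
strand-ambiguous A/T and C/G SNPs dropped — the harmonization policy is a
convention, stated here because the source literature rarely states one);
greedily clump by visiting SNPs in ascending p-value, retaining each
unremoved SNP as an index and removing SNPs within ±250 kb on the same
chromosome whose squared dosage correlation with it exceeds 0.25 (ties in
p broken by chromosome, position, id, making the result independent of
input order); then score as the dosage-weighted sum of effect sizes over
retained SNPs passing the association threshold ($p \le 1$ by default; a
stringent $p = 0.01$ rerun is wired in for the Alzheimer score, whose
large-effect locus is otherwise diluted by genome-wide noise). Missing
dosages are mean-imputed per SNP and logged.

# The synthetic cohort: what it emulates, and what it does not

All latent construction happens on standardized scales and is mapped to
raw units by each test's baseline SD. Defaults are the stated world:

* Battery of 13 tests with the published baseline means, SDs and mean
  annual raw changes (reaction time carried in seconds on the reversed,
  higher-is-better scale).
* Standardized hierarchical loadings 0.85 (test on domain) and 0.75
  (domain on general) for levels — the general factor explains
  $(0.85 \cdot 0.75)^2 \approx 41\%$ of test-level variance — and 0.91 /
  0.92 for slopes ($\approx 70\%$), matching the study's structure.
* The level factor carries 70% of baseline observed variance (occasion
  residual 30%), a typical reliability for these tests.
* Between-person slope SD = 0.06 baseline-SD per year. The sources do not
  print this quantity; 0.06 implies a ±0.6 SD fan-out over the 9.78-year
  follow-up, comparable in magnitude to the battery's mean annual changes
  (0.001–0.104 SD/yr), and was calibrated once so that the generator's
  asserted recovery property (standardized-loading RMSE < 0.05 at
  $n = 1091$ over 20 replicates) holds; it was not revisited afterwards.
* Level–slope factor correlation 0.30 (healthier baselines decline
  slightly less steeply).
* Predictor effects: the published standardized level, slope and age-11
  coefficients for the 14 PGSs and the binary APOE indicator (carrier
  frequency ~30%, point-biserial correlation ~0.12 with the Alzheimer
  score truth).
* The age-11 score is generated so that the standardized regression of
  the adult general level on it is exactly 0.814; the residual
  childhood–adulthood correlation is calibrated at spec-build time and an
  error is raised if the requested moments are jointly unattainable.
* Education mediation: years of education $= a\,x_{edu} + e_m$ with
  $a = 0.276$ (the published own-phenotype validation coefficient); the
  level factor loads on $e_m$ with a weight derived so the population
  proportion mediated equals 6.4%.
* Validation phenotypes: one per score, linear (or logistic with the
  published prevalences, or 3-level ordinal for smoking) in the score
  truth with the published coefficients, spanning the 0.001–13% range of
  variance explained.
* Dropout: monotone, exact retained counts (1091/866/697/550 scaled to
  $n$), with retention log-odds proportional to 0.8 × the previous wave's
  observed standardized composite. 0.8 produces completers roughly half a
  baseline SD healthier than dropouts, the selectivity longitudinal
  ageing studies report.
* Sex (50% female) shifts every test by 0.1 SD; age at entry
  ($SD = 0.83$ y) shifts scores along each test's own slope; both are
  removed by the pre-residualization step, as in the analysis pipeline.

`truth_moments()` returns the exact population mean and covariance of the
generated scores by moment algebra (a second, simulation-free route used to
test the generator), and every cohort carries its per-person latent truth
for recovery testing.

Deliberate simplifications — a green test does not establish realism
beyond them: trajectories are linear with independent occasion residuals
(no retest effects, no residual autocorrelation, no nonlinearity or latent
classes); score truths are mutually independent rather than weakly
correlated; ancestry components are pure noise (no stratification);
genotype LD is exchangeable within fixed blocks; no mortality process
distinct from score-dependent dropout.

# Design choices on genuinely open points

* **Identification** of the hierarchy by marker variables (above).
* **Occasion residual variances** constant over waves (the sources are
  silent; freeing them per wave is a one-line change in the builder).
* **FDR family**: Benjamini–Hochberg per outcome column across the 15
  predictors.
* **Smoking** (never/ex/current) analysed as 0/1/2 in a linear model,
  consistent with reporting a single standardized beta for it.
* **Parallel analysis** retains components whose correlation-matrix
  eigenvalues exceed the rank-wise mean of 100 simulated uncorrelated
  datasets (a quantile criterion is available); the retained count is the
  number of ranks exceeding the reference.
* **Williams's test** uses the Steiger-modified formula with
  $|R| = 1 - r_{12}^2 - r_{13}^2 - r_{23}^2 + 2 r_{12} r_{13} r_{23}$ and
  $\bar r = (r_{12} + r_{13})/2$.
* **Mediation SE** by delta method (bootstrap not implemented).
* **Complete cases for exogenous predictors**: extending FIML to the
  predictor block would add distributional assumptions about the scores.

# Known limitations

Factor-score associations are attenuated relative to in-SEM estimates (by
design of regression scores); in-SEM standard errors for standardized
betas hold the standardization factor fixed (the extra variability is
second-order at these sample sizes); the observed-information SEs assume a
correctly specified model; and the pipeline's computed scores are noisy
proxies of the generating score truths, so pipeline-level associations are
attenuated relative to the generating coefficients — exactly as real PGS
analyses are attenuated relative to the latent genetic value.

# A worked example

```{r example, eval = FALSE}
library(cogslope)

spec <- generative_spec(n = 1091)
cohort <- apply_dropout(simulate_cohort(spec, seed = 1), seed = 2)
scores <- residualize_scores(cohort, spec$battery$test)

fspec <- foc_model_spec(spec$battery, spec$time_basis)
fit <- fit_foc(fspec, scores, n_starts = 2)
fit_indices(fit, scores)
variance_decomposition(fit)

cohort$pgs <- attr(cohort, "truth")$x_education
single_predictor_association(fspec, residualize_scores(cohort,
                                                       spec$battery$test),
                             "pgs")
```
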