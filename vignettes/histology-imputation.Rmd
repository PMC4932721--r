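---
title: "Imputing missing lung-cancer histology and estimating incidence trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Imputing missing lung-cancer histology and estimating incidence trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histmi)
library(dplyr)
```

## The problem

Population-based cancer registries in low- and middle-income settings often
record a large fraction of lung cancers with *unknown* histology: patients
presenting at a late stage are treated palliatively and never receive the
biopsy that would subtype their tumour. In the Songkhla provincial registry
(southern Thailand, 1989–2013) — the setting this package emulates — about
29% of lung-cancer cases have unknown histology, and from the late 1990s a
further ~5% carry the coarse label *non-small-cell carcinoma, not otherwise
specified* (NSCC-NOS, ICD-O 8046/3), which covers squamous cell carcinoma
(SCC), adenocarcinoma (ADCA), large cell and other carcinomas when the
specimen cannot be subtyped.

Ignoring these cases biases histology-specific incidence trends, because the
probability of an unknown subtype depends on observable characteristics
(age, period, place of residence) that are themselves associated with
subtype. Since missingness plausibly depends on stage and performance status
but not on the subtype itself given those observables, the data are treated
as **missing at random (MAR)**: the probability that histology is missing
may depend on observed values but not additionally on the missing class.

`histmi` implements the full analysis pipeline: ICD-O morphology grouping,
two-step Bayesian polytomous-regression multiple imputation, pooled counts
and percentages with 95% probability intervals, age-standardized incidence
rates (ASR), and age–period–cohort (APC) drift estimation — together with a
synthetic registry generator with known ground truth, so every stage is
testable end to end without access to confidential unit records.

## Data model

A case record holds `sex`, `age_dx` (completed years), `year_dx`,
`religion`, `district` (16 named districts), an ICD-O morphology code, and
the derived six-class histology: SCC, ADCA, large cell carcinoma
(8012/3–8014/3), NSCC-NOS (8046/3), other known histology, and unknown
(8000/3–8011/3). The SCC (8050–8089) and ADCA (8140–8389 and related
families) ranges are not fixed by the registry convention above, so they are
shipped as an editable lookup table (`icdo_histology_table()`) that
`classify_morphology()` treats as a partition of all valid `/3` codes. For
post-imputation reporting the specific classes collapse to SCC / ADCA /
OTHER (large cell, small cell, sarcoma and all other specified types).

Malformed case rows are rejected with line numbers and reasons
(`registry_rejects()`), never repaired or silently dropped: registries audit
their rejects, and silent repair hides upstream data bugs.

## The imputation model

The conditional model is a polytomous (multinomial) logistic regression
with reference class $J$:

$$\log\left(\pi_j(X)/\pi_J(X)\right) = \alpha_j + \beta_j' X,
\qquad j = 1, \dots, J-1,$$

with design $X$ = sex, age at diagnosis (continuous, per year), year of
diagnosis (continuous, per year) and district of residence. The fit is by
maximum likelihood (`nnet::multinom`); the imputation is *proper*: each
round draws a coefficient vector from the multivariate-normal approximation
to the posterior — centred at the MLE with the estimated asymptotic
covariance — and then samples each incomplete case's class from the
resulting $\pi(X)$. Both sources of randomness matter: omitting the
coefficient draw understates between-round variability and yields
overconfident intervals.

### Two steps

1. **Unknown → five classes.** A model fitted to all cases with known
   histology (five classes, including NSCC-NOS) imputes every UNKNOWN case.
2. **NSCC-NOS → four specific classes.** A model fitted to cases with a
   specific histology imputes every NSCC-NOS case — originally coded or
   assigned in step 1. NSCC-NOS is treated as a coarse label over true
   specific types, which is exactly what this step assumes.

Each completed dataset is collapsed to SCC / ADCA / OTHER. The procedure is
repeated $M = 200$ times; counts and percentages are pooled as the mean over
rounds, with 95% probability intervals from the empirical 2.5th/97.5th
percentiles. Because histology is the only incomplete variable, the
chained-equations loop degenerates to a single conditional model per step:
the models are fitted once and only the posterior draw and class sampling
vary per round (with `step2_training = "include_step1"` the step-2 model is
instead refitted each round on step-1-completed data).

### Perfect prediction

Sparse class × covariate cells can separate the likelihood, sending
coefficients to infinity and poisoning the posterior draws. The fit
therefore augments the data with pseudo-observations: for every level of
every categorical predictor, one fractional-weight case per outcome class,
continuous predictors held at their mean. Each level's pseudo-weight is
proportional to its real case count, so the pull toward uniform class
probabilities is bounded by `augment_total` (default 1%) in *every* cell;
total augmentation never exceeds 1% of the sample. With augmentation
disabled, detected separation (|coefficient| > 15 on the logit scale) is a
hard error, never a silent divergence.

### District coding

The registry's 16 districts range from ~30 to ~800 cases. A saturated
16-level district factor in a five-class model leaves many near-empty
district × class cells; their coefficient posteriors are wide and skewed,
and the softmax's curvature then systematically inflates the rare classes in
the pooled imputations. The default therefore codes district as
*Muang-vs-other* (`district_coding = "muang"`) — the form in which the
registry's own published model reports the district effect — with the
saturated coding available as `"full"` for registries with better-filled
cells. This was a genuinely open design choice; the dichotomy was adopted
because at this registry's scale it removed a ~1-percentage-point bias in
the rarest collapsed class while leaving the large-sample behaviour
unchanged.

## Rates

Census populations (1990/2000/2010 in the emulated setting) are
interpolated to annual sex × age-group counts log-linearly between
consecutive censuses, $P(t) = P(t_1)\,(P(t_2)/P(t_1))^{(t-t_1)/(t_2-t_1)}$;
anchors are reproduced exactly and years outside the census span must be
covered by supplied projection rows — the package never extrapolates
silently. Age-standardized rates use the Segi world standard population as
modified by Doll (18 five-year groups, weights summing to 100,000):

$$\mathrm{ASR} = \frac{\sum_i w_i\, d_i/n_i}{\sum_i w_i} \times 10^5 .$$

ASR series are computed per sex, collapsed class and single calendar year;
for an imputation ensemble the ASR is computed within each completed dataset
and pooled by mean and percentiles, giving the "after imputation" curves
with probability-interval ribbons next to the "before" (known-histology)
curves.

## Age–period–cohort trends

Events and person-years on a Lexis grid (5-year age × 1-year period cells,
cohort $c = p - a$ at cell midpoints) are modelled as
$\log R(a,p) = f(a) + g(p) + h(c)$ with a Poisson likelihood and
person-years offset. The linear-trend component of $g$ and $h$ is not
separately identifiable, so the classical residual approach is used: an
age–period (AP-C) or age–cohort (AC-P) two-effect model with natural
splines is fitted first and the remaining effect is estimated from its
residuals by a natural-spline Poisson fit with the two-effect fitted values
as offset. The **drift** — the identifiable common annual trend — is
extracted from the age-drift model (spline age curve plus a *linear* period
slope), fitted before any spline can absorb curvature, and reported as
$100(e^{\delta}-1)$% per year with a Wald CI; by construction it is
identical under both variants, which the test suite asserts. On imputed
data the drift is fitted per completed dataset and pooled by mean and
percentiles, consistent with the count-pooling rule. Spline degrees of
freedom default to 5 (age), 4 (period), 4 (cohort) and are config-exposed.

## The synthetic generator

`generate_registry()` draws a registry whose *defaults are the study
conditions of the emulated setting*: 2,734 male and 1,110 female cases over
1989–2013; age at diagnosis from a normal truncated to [20, 99] years with
mean (SD) 64.5 (12.4) for men and 63.8 (14.4) for women; the observed
five-period case-count proportions via a piecewise-constant rate (matching
the registry's growth); observed district and religion margins; and a
four-class true-histology multinomial logit whose covariate effects point
the way the registry's fitted relative-risk ratios do (ADCA strongly more
likely in women, in the young and in recent years; large cell rarer outside
the old town; intercepts set so the male mix is roughly 30% SCC, 46% ADCA,
5% large cell, 19% other — consistent with the known-histology margins once
the ~100-case male large-cell row omitted from the published table is
restored).

Missingness masks the true class as UNKNOWN with an overall target rate of
28.9%. Under MAR (default) the masking log-odds depend on age and district
— observables plausibly standing in for stage and access to diagnosis — and
the intercept is calibrated so the expected masked fraction equals the
target; MCAR and NMAR (log-odds offsets per true class) are available for
robustness experiments. NSCC-NOS is generated as *post-hoc coarsening*, not
a seventh true class: from the onset year (1997, when the label appears in
the emulated registry) each unmasked specific diagnosis is relabelled
NSCC-NOS with probability 0.08, which yields the observed ~5% of all
diagnoses. The published narrative does not quantify how unknown-ness
depends on stage or performance status, so the masking coefficients are
exposed as free parameters rather than claimed as fidelity.

What the generator does **not** emulate: spatial structure beyond district
labels, survival/vital status, death-certificate-only ascertainment,
multiple primaries, secular changes in coding practice, or any
NMAR mechanism in its default. Passing tests therefore show that the
pipeline recovers truth *under MAR with a correctly specified class model at
this registry's scale* — not that any real registry's missingness is MAR.

## Numerical choices

- Continuous predictors are centred inside the fit; coefficients stay on
  the per-unit scale. Optimiser iterations capped at 500 (`multinom`) and
  100 (Poisson `glm`s); non-convergence is an error.
- The coefficient covariance is Cholesky-factored once per model; if not
  positive definite, a ridge of up to $10^{-6}\times$ the mean diagonal is
  tried before erroring.
- Percentile intervals use the default type-7 sample quantile.
- Age groups 0–4 … 85+ (18 groups); the open 85+ group takes midpoint 87.5
  on Lexis grids. Period midpoints are year + 0.5, and $c = p - a$ holds on
  every cell.
- Zero person-years with zero events contribute a zero rate to the ASR;
  zero person-years with events is an error.
- A master seed spawns named sub-streams per stage and per imputation round,
  so runs are byte-identical given the config, and rounds are independent
  of one another's stream positions. Failed rounds are retried with a fresh
  sub-stream up to 3 times, then raise a hard error with diagnostics.
- Poisson fits on sparse grids legitimately produce cells with fitted rates
  indistinguishable from zero; that specific warning is muffled, all others
  surface.

## Open choices, resolved

- *Step-2 training data*: originally-specific cases only (cleaner
  conditioning on data that were actually observed), with
  `"include_step1"` as a switch. The emulated study does not state which it
  used.
- *Year window*: the emulated registry period is described both as 24
  calendar years and as 1989–2013 (a 25-year span), and its figures start
  in 1990; the window is config-exposed with default 1989–2013.
- *Census coverage*: the registry starts one year before the first census,
  so the synthetic population ships 1989 (and post-2010 years) as
  projection rows; interpolation never extrapolates.
- *Drift on imputed data*: both a single fit on the observed known-histology
  series and ensemble pooling are provided, since published drift CIs could
  come from either.

## Problem sizes

The test suite exercises the pipeline at reduced scale (600–900 synthetic
cases, M = 4–8) for the structural and determinism checks, and at full
registry scale for the calibration study: 100 replicates of 3,844 cases with
~29% MAR-masked histology and ~5% NSCC-NOS coarsening, M = 200 rounds each,
asserting that pooled class proportions among masked cases are unbiased to
within one percentage point and that the 95% probability interval covers the
true masked SCC count at its nominal rate (90–99% of replicates). Drift
recovery is checked on simulated surfaces
$\lambda(a,p) = \lambda_0(a)\,1.05^{\,p-p_0}$ with large person-years.

## Limitations

- The posterior draw is the usual asymptotic-normal approximation at the
  MLE; with very sparse classes it can misstate tail uncertainty (mitigated
  by — and interacting with — the augmentation above).
- Rubin's-rules pooling of model *coefficients* is out of scope: counts and
  rates are pooled by quantiles, as the emulated analysis did.
- The step-1 model treats NSCC-NOS as an ordinary class with a linear year
  effect although the label only exists after an onset year; at this
  registry's scale the residual miscalibration is small, but registries
  with a longer pre-onset era may prefer to restrict step 1 to the
  post-onset period.
- No NMAR correction is implemented; NMAR appears only as a generator
  mechanism for sensitivity experiments.

## A short tour

```{r tour, eval = FALSE}
cfg <- registry_run_config(synthetic = synthetic_registry_config(),
                           M = 200, seed = 1)
report <- run_registry_analysis(cfg)
report$pooled          # imputed counts/percentages with 95% PIs, by sex
report$comparison      # known vs imputed chi-square, by sex
report$drift           # % per year, before/after imputation
plot_asr_trends(report$asr)
write_report_bundle(report, "songkhla_like_run")
```
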