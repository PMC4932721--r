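# histmi

Histology-specific cancer incidence trends from registries with missing
histology, by two-step multiple imputation.

## The problem

Cancer registries in many settings record a large share of lung cancers with
*unknown* histologic type — in the Songkhla provincial registry (Thailand,
1989–2013) that this package emulates, about 29% of cases, plus ~5% carrying
the coarse label *non-small-cell carcinoma NOS* (NSCC-NOS, ICD-O 8046/3)
from the late 1990s. Trends in the two major subtypes, squamous cell
carcinoma (SCC) and adenocarcinoma (ADCA), are biased if those cases are
ignored, because the chance of an unknown subtype depends on age, period and
place of residence. Treating histology as missing at random (MAR) given
those observables, `histmi` estimates subtype-specific counts, rates and
trends with uncertainty from the imputation.

## The method

The core is a Bayesian polytomous-regression multiple imputation. The
conditional model for histology class $j$ with reference class $J$ is

$$\log\!\left(\pi_j(X)/\pi_J(X)\right) = \alpha_j + \beta_j' X,$$

over $X$ = sex, age, year of diagnosis and district. Each imputation round
draws the coefficient vector from the asymptotic posterior (multivariate
normal at the MLE with its estimated covariance), then samples each
incomplete case's class from the resulting probabilities. Imputation runs in
two steps — UNKNOWN into the five known classes (including NSCC-NOS), then
every NSCC-NOS case into the four specific classes — and the completed data
collapse to SCC / ADCA / other. With $M = 200$ rounds, counts and
percentages are pooled as means with 95% probability intervals (PIs) from
the 2.5th/97.5th percentiles. Perfect prediction in sparse cells is handled
by fractional-weight data augmentation.

Downstream, the package computes age-standardized incidence rates against
the Segi/Doll world standard (with census populations interpolated
log-linearly to annual counts) and classical age–period–cohort Poisson
models with natural splines, reporting the drift (common annual trend) per
subtype and sex, before and after imputation. A synthetic registry generator
with known ground truth and configurable MCAR/MAR/NMAR missingness makes the
whole pipeline testable end to end.

## Worked example

```r
library(histmi)
library(dplyr)

reg <- generate_registry(synthetic_registry_config(), seed = 1)
ens <- two_step_impute(reg, M = 200, seed = 2)
pool_ensemble(ens, by = "sex")
#> # A tibble: 6 × 8
#>   sex    class count count_lo count_hi   pct pct_lo pct_hi
#>   <fct>  <fct> <dbl>    <dbl>    <dbl> <dbl>  <dbl>  <dbl>
#> 1 male   SCC   260.     231.      287   27.5  24.4    30.4
#> 2 male   ADCA  497.     468.      529.  52.6  49.5    56.0
#> 3 male   OTHER 188.     163.      218.  19.9  17.2    23.1
#> 4 female SCC    45.6     33.0      61   12.2   8.84   16.4
#> 5 female ADCA  277.     260.      297   74.3  69.7    79.6
#> 6 female OTHER  50.4     35        65   13.5   9.38   17.4
```

Each row is the pooled estimate for the originally unknown-histology group
(UNKNOWN plus NSCC-NOS) of one sex: of the masked male cases, an estimated
260 (95% PI 231–287) are squamous cell carcinomas, 27.5% of the group. The
imputed distribution is statistically indistinguishable from the observed
known-histology distribution:

```r
compare_known_vs_imputed(ens) |> select(sex, statistic, p_value)
#>   sex    statistic p_value
#> 1 male     0.00983   0.995
#> 2 female   0.137     0.934
```

Trends come from the rates and APC modules:

```r
pop <- interpolate_population(generate_population(synthetic_registry_config()),
                              1989:2013)
lex <- build_lexis(
  filter(reg, sex == "male",
         collapse_histology(histology, strict = FALSE) == "ADCA"),
  filter(pop, sex == "male"))
fit_apc(lex)
#> APC Poisson fit (AP-C), df age/period/cohort = 5/4/4
#> Drift: 8.05% per year (95% CI 6.95, 9.15)
```

so male adenocarcinoma incidence in this synthetic registry rises about 8%
per year (the generator's configured year effect plus its case-count
growth). `run_registry_analysis(registry_run_config(...))` chains all
stages — tabulations, imputation, before/after ASR series, drift table,
SCC/ADCA ratio — into one deterministic report bundle;
`plot_asr_trends()` draws the before (dashed) / after (solid) rate curves.
A thin command-line wrapper with `simulate` / `impute` / `rates` / `apc` /
`run` subcommands is included at `inst/scripts/histmi-cli.R`.

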