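# Helper: deterministic Lexis grid generated from a known rate surface
# lambda(a, p) = lambda0(a) * (1 + drift)^(p - p0), with large person-years.
sim_lexis <- function(annual_drift = 0.05, pyears = 2e6, years = 1989:2013,
                      poisson = FALSE) {
  ages <- age_group_midpoint(age_group_levels())
  lambda0 <- 1e-4 * exp((ages - 60) / 18)        # increasing age curve
  grid <- tidyr::expand_grid(age = ages, year = years) |>
    dplyr::mutate(
      period = year + 0.5,
      cohort = period - age,
      pyears = pyears,
      rate = rep(lambda0, each = length(years)) *
        (1 + annual_drift)^(period - mean(range(period))),
      events = if (poisson) rpois(dplyr::n(), pyears * rate)
               else round(pyears * rate)
    )
  grid
}

test_that("the Lexis grid conserves events and labels cohorts as p - a", {
  rec <- tiny_records(rep("ADCA", 10), sex = rep("male", 10),
                      year = rep(2000, 10))
  rec$age_dx <- rep(60L, 10)
  pop <- flat_population() |> dplyr::filter(sex == "male")
  lex <- build_lexis(rec, pop, years = 1989:2013)
  expect_equal(sum(lex$events), 10)
  cell <- lex |> dplyr::filter(events > 0)
  expect_equal(nrow(cell), 1)
  expect_equal(as.character(cell$age_group), "60-64")
  expect_equal(lex$cohort, lex$period - lex$age)   # c = p - a on every cell
  expect_lt(abs(cell$cohort - 1940), 3)            # within half a bin width
  expect_error(build_lexis(rec, pop[0, ], years = 1989:2013), "Empty")
  expect_error(build_lexis(rec, flat_population()), "both sexes")
})

test_that("rates constant in period and cohort give flat g and h and recover f", {
  lex <- sim_lexis(annual_drift = 0)
  fit <- fit_apc(lex, variant = "AP-C")
  expect_lt(abs(fit$drift_pct), 0.05)
  expect_true(all(abs(fit$effects$period_effect$rr - 1) < 1e-3))
  expect_true(all(abs(fit$effects$cohort_effect$rr - 1) < 5e-3))
  # age curve reproduces the generating rates (per 100,000)
  ages <- age_group_midpoint(age_group_levels())
  truth <- 1e-4 * exp((ages - 60) / 18) * 1e5
  expect_equal(fit$effects$age_effect$rate, truth, tolerance = 0.01)
  # Poisson ML with intercept: fitted events sum to observed events
  expect_equal(sum(fitted(fit$models$two_effect)), sum(lex$events),
               tolerance = 1e-6)
})

test_that("a 5%/yr log-linear trend is recovered as 5.0% drift", {
  lex <- sim_lexis(annual_drift = 0.05)
  ap <- fit_apc(lex, variant = "AP-C")
  ac <- fit_apc(lex, variant = "AC-P")
  expect_lt(abs(ap$drift_pct - 5), 0.1)
  expect_lt(abs(ap$drift_pct - ac$drift_pct) / abs(ap$drift_pct), 1e-6)
  expect_true(ap$drift_ci[1] < 5 & 5 < ap$drift_ci[2])
})

test_that("drift recovery holds across negative, null and positive trends", {
  set.seed(77)
  for (dr in c(-0.02, 0, 0.06)) {
    lex <- sim_lexis(annual_drift = dr, poisson = TRUE)
    fit <- fit_apc(lex)
    expect_lt(abs(fit$drift_pct - 100 * dr), 0.3, label = paste("drift", dr))
    expect_true(fit$drift_ci[1] <= 100 * dr + 0.3 &&
                  fit$drift_ci[2] >= 100 * dr - 0.3)
  }
})

test_that("drift is invariant to rescaling person-years", {
  lex <- sim_lexis(annual_drift = 0.03)
  f1 <- fit_apc(lex)
  f2 <- fit_apc(lex |> dplyr::mutate(pyears = pyears * 1000))
  expect_equal(f1$drift_pct, f2$drift_pct, tolerance = 1e-8)
})

test_that("spline df must stay below the number of distinct index values", {
  lex <- sim_lexis()
  expect_error(fit_apc(lex, df = c(age = 18, period = 4, cohort = 4)),
               "df\\$age")
  expect_error(fit_apc(lex[0, ]), "Empty")
})

test_that("tidy and glance expose effect curves and drift", {
  lex <- sim_lexis(annual_drift = 0.02)
  fit <- fit_apc(lex)
  td <- tidy(fit)
  expect_setequal(unique(td$effect), c("age", "period", "cohort"))
  gl <- glance(fit)
  expect_equal(gl$variant, "AP-C")
  expect_equal(gl$events, sum(lex$events))
  d <- drift(fit)
  expect_true(d$ci_lo < d$drift_pct & d$drift_pct < d$ci_hi)
})

test_that("ensemble drift pools per-dataset fits with a percentile interval", {
  reg <- generate_registry(small_config(), seed = 33)
  pop <- interpolate_population(flat_population(), 1989:2013)
  ens <- two_step_impute(reg, M = 6, seed = 4,
                         predictors = c("sex", "age_dx", "year_dx"))
  de <- drift_ensemble(ens, pop, sex = "male", class = "ADCA",
                       years = 1989:2013, df_age = 4)
  expect_equal(nrow(de), 1)
  expect_true(de$pi_lo <= de$drift_pct & de$drift_pct <= de$pi_hi)
})
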