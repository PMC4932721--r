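test_that("generation is byte-identical for a fixed config and seed", {
  cfg <- small_config()
  a <- generate_registry(cfg, seed = 77)
  b <- generate_registry(cfg, seed = 77)
  expect_identical(a, b)
  c <- generate_registry(cfg, seed = 78)
  expect_false(identical(a$histology, c$histology))
})

test_that("zero missingness produces no UNKNOWN records", {
  cfg <- small_config(missingness = list(mechanism = "MCAR", rate = 0))
  reg <- generate_registry(cfg, seed = 2)
  expect_equal(sum(reg$histology == "UNKNOWN"), 0)
  expect_false(any(reg$masked))
})

test_that("MCAR masking hits the configured rate at large n", {
  cfg <- synthetic_registry_config(
    n_male = 70000L, n_female = 30000L,
    missingness = list(mechanism = "MCAR", rate = 0.289))
  reg <- generate_registry(cfg, seed = 12)
  expect_lt(abs(mean(reg$histology == "UNKNOWN") - 0.289), 0.01)
})

test_that("a degenerate class model puts every unmasked case in one class", {
  cm <- synthetic_registry_config()$class_model
  cm$coefficients["ADCA", "intercept"] <- 30
  cfg <- small_config(class_model = cm,
                      missingness = list(mechanism = "MCAR", rate = 0.2),
                      nscc = list(onset_year = 1997L, rate = 0))
  reg <- generate_registry(cfg, seed = 8)
  expect_true(all(reg$true_class == "ADCA"))
  expect_true(all(reg$histology[!reg$masked] == "ADCA"))
})

test_that("observed class equals true class unless masked or coarsened", {
  reg <- generate_registry(small_config(), seed = 21)
  clean <- !reg$masked & !reg$coarsened
  expect_equal(as.character(reg$histology[clean]),
               as.character(reg$true_class[clean]))
  expect_true(all(reg$histology[reg$masked] == "UNKNOWN"))
  expect_true(all(reg$histology[reg$coarsened & !reg$masked] == "NSCC_NOS"))
  expect_true(all(reg$year_dx >= 1989 & reg$year_dx <= 2013))
  expect_true(all(reg$age_dx >= 20 & reg$age_dx <= 99))
})

test_that("NSCC-NOS coarsening starts only at the onset year", {
  reg <- generate_registry(synthetic_registry_config(), seed = 14)
  expect_equal(sum(reg$histology == "NSCC_NOS" & reg$year_dx < 1997), 0)
  late <- reg$year_dx >= 1997
  frac <- mean(reg$histology[late] == "NSCC_NOS")
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.09)
})

test_that("under MAR, true class given covariates is the same in masked and unmasked strata", {
  cfg <- synthetic_registry_config(
    n_male = 40000L, n_female = 0L,
    missingness = list(mechanism = "MAR", rate = 0.35,
                       coef = c(age = 0.05, year = 0,
                                other_district = 0.5)))
  reg <- generate_registry(cfg, seed = 31)
  # Within narrow covariate strata the masking indicator is independent of
  # the true class; aggregate the per-stratum chi-square statistics.
  strata <- reg |>
    mutate(age_band = cut(age_dx, c(20, 55, 65, 75, 99),
                          include.lowest = TRUE),
           muang = district == "Muang Songkhla") |>
    group_by(age_band, muang) |>
    filter(n() > 500) |>
    group_split()
  stat <- 0; df <- 0
  for (s in strata) {
    tab <- table(s$true_class, s$masked)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (ncol(tab) < 2 || nrow(tab) < 2) next
    ct <- suppressWarnings(chisq.test(tab))
    stat <- stat + unname(ct$statistic)
    df <- df + unname(ct$parameter)
  }
  expect_gt(df, 0)
  expect_gt(pchisq(stat, df, lower.tail = FALSE), 0.001)
})

test_that("degenerate configs are refused", {
  expect_error(synthetic_registry_config(n_male = 0, n_female = 0), "Zero")
  expect_error(synthetic_registry_config(year_range = c(2000, 1999)),
               "year range")
  expect_error(synthetic_registry_config(
    period_probs = list(male = c(1, 1, 1, 1, 1) / 4,
                        female = rep(0.2, 5))), "sum to 1")
  expect_error(synthetic_registry_config(
    missingness = list(mechanism = "SOMETIMES", rate = 0.1)), "mechanism")
  expect_error(synthetic_registry_config(
    missingness = list(mechanism = "MAR", rate = 1.2)), "rate")
})

test_that("population table has positive counts and three census anchors", {
  pop <- generate_population(synthetic_registry_config())
  expect_true(all(pop$count > 0))
  anchors <- pop |> filter(source == "census") |> distinct(year)
  expect_equal(sort(anchors$year), c(1990, 2000, 2010))
  expect_equal(nrow(pop), 2 * 18 * 7)  # 3 censuses + 4 projection years
  # deterministic
  expect_identical(pop, generate_population(synthetic_registry_config()))
})

test_that("truth file excludes observed columns and registry file excludes truth", {
  reg <- generate_registry(small_config(), seed = 4)
  obs <- withr::local_tempfile(fileext = ".csv")
  tru <- withr::local_tempfile(fileext = ".csv")
  write_registry(reg, obs)
  write_truth(reg, tru)
  expect_false(any(c("true_class", "masked") %in%
                     names(readr::read_csv(obs, show_col_types = FALSE))))
  expect_true(all(c("case_id", "true_class", "masked", "coarsened") %in%
                    names(readr::read_csv(tru, show_col_types = FALSE))))
})
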