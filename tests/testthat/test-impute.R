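test_that("complete input passes through: M identical datasets, zero-width PIs", {
  rec <- tiny_records(rep(c("SCC", "ADCA", "LARGE_CELL", "OTHER_KNOWN"), 15))
  ens <- two_step_impute(rec, M = 4, seed = 1, predictors = "sex")
  expect_equal(ens$M, 4)
  expect_true(all(ens$completed == ens$completed[, 1]))
  pooled <- pool_ensemble(ens, by = NULL, among = "all")
  expect_equal(pooled$count_lo, pooled$count)
  expect_equal(pooled$count_hi, pooled$count)
  expect_equal(as.character(collapse_histology(rec$histology)),
               collapsed_levels()[ens$completed[, 1]])
})

test_that("every completed dataset resolves all cases and conserves the total", {
  reg <- generate_registry(small_config(), seed = 17)
  ens <- two_step_impute(reg, M = 6, seed = 5,
                         predictors = c("sex", "age_dx", "year_dx"))
  expect_false(anyNA(ens$completed))          # no UNKNOWN/NSCC left anywhere
  counts <- apply(ens$completed, 2, tabulate, nbins = 3)
  expect_true(all(colSums(counts) == nrow(reg)))
  # pooled percentages sum to 100 within every stratum
  pooled <- pool_ensemble(ens, by = "sex", among = "imputed")
  sums <- pooled |> group_by(sex) |> summarise(s = sum(pct))
  expect_equal(sums$s, rep(100, 2), tolerance = 1e-9)
})

test_that("without NSCC-NOS anywhere, step 2 is the identity", {
  h <- rep(c("SCC", "ADCA", "OTHER_KNOWN", "UNKNOWN"), 30)
  rec <- tiny_records(h)
  ens <- two_step_impute(rec, M = 3, seed = 2, predictors = "sex")
  expect_null(ens$models$step2)
  expect_false(any(is.na(ens$completed)))
})

test_that("M < 2 is refused", {
  rec <- tiny_records(rep(c("SCC", "ADCA", "UNKNOWN"), 10))
  expect_error(two_step_impute(rec, M = 1, seed = 1, predictors = "sex"),
               "M must be at least 2")
})

test_that("pooling is the mean over rounds with percentile intervals", {
  rec <- tiny_records(rep("UNKNOWN", 30))
  # round 1: 10 SCC / 20 ADCA; round 2: 20 SCC / 10 ADCA
  completed <- cbind(rep(c("SCC", "ADCA"), c(10, 20)),
                     rep(c("SCC", "ADCA"), c(20, 10)))
  ens <- fake_ensemble(rec, completed, masked = rep(TRUE, 30))
  pooled <- pool_ensemble(ens, by = NULL, among = "imputed")
  expect_equal(pooled$count[pooled$class == "SCC"], 15)
  expect_equal(pooled$count[pooled$class == "ADCA"], 15)
  expect_equal(pooled$count_lo[pooled$class == "SCC"], 10.25) # type-7 quantile
  expect_equal(pooled$pct[pooled$class == "SCC"], 50)
  expect_error(pool_ensemble(ens, by = "starsign"), "starsign")
})

test_that("imputed distribution proportional to known gives chi-square 0, p 1", {
  rec <- tiny_records(c(rep("SCC", 50), rep("ADCA", 30), rep("OTHER_KNOWN", 20),
                        rep("UNKNOWN", 10)))
  masked <- rec$histology == "UNKNOWN"
  done <- c(rep("SCC", 50), rep("ADCA", 30), rep("OTHER", 20),
            rep("SCC", 5), rep("ADCA", 3), rep("OTHER", 2))
  ens <- fake_ensemble(rec, cbind(done, done), masked = masked)
  cmp <- compare_known_vs_imputed(ens, by = NULL)
  expect_equal(cmp$statistic, 0, tolerance = 1e-12)
  expect_equal(cmp$p_value, 1)
})

test_that("the chi-square comparison matches hand arithmetic", {
  rec <- tiny_records(c(rep("SCC", 40), rep("ADCA", 40), rep("OTHER_KNOWN", 20),
                        rep("UNKNOWN", 50)))
  masked <- rec$histology == "UNKNOWN"
  done <- c(rep("SCC", 40), rep("ADCA", 40), rep("OTHER", 20),
            rep("SCC", 30), rep("ADCA", 10), rep("OTHER", 10))
  ens <- fake_ensemble(rec, cbind(done, done), masked = masked)
  cmp <- compare_known_vs_imputed(ens, by = NULL)
  # brute-force Pearson statistic on the 2 x 3 table
  tab <- rbind(c(40, 40, 20), c(30, 10, 10))
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  expect_equal(cmp$statistic, stat, tolerance = 1e-12)
  expect_equal(cmp$p_value, pchisq(stat, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("an empty stratum is flagged as not applicable", {
  rec <- tiny_records(rep(c("SCC", "ADCA"), 10), sex = rep("male", 20))
  done <- rep(c("SCC", "ADCA"), 10)
  ens <- fake_ensemble(rec, cbind(done, done),
                       masked = rep(FALSE, 20))
  cmp <- compare_known_vs_imputed(ens, by = "sex")
  expect_true(all(!is.na(cmp$note)))  # no masked cases at all -> flagged
})

test_that("probability intervals widen as the missing fraction grows", {
  width_at <- function(rate) {
    cfg <- synthetic_registry_config(
      n_male = 2000L, n_female = 0L,
      missingness = list(mechanism = "MCAR", rate = rate),
      nscc = list(onset_year = 1997L, rate = 0))
    reg <- generate_registry(cfg, seed = 40)
    ens <- two_step_impute(reg, M = 60, seed = 41,
                           predictors = c("age_dx", "year_dx"))
    pooled <- pool_ensemble(ens, by = NULL, among = "all")
    sum(pooled$count_hi - pooled$count_lo)
  }
  expect_lt(width_at(0.12), width_at(0.45))
})

test_that("rounds are reproducible from the master seed", {
  reg <- generate_registry(small_config(), seed = 23)
  e1 <- two_step_impute(reg, M = 4, seed = 9, predictors = c("sex", "age_dx"))
  e2 <- two_step_impute(reg, M = 4, seed = 9, predictors = c("sex", "age_dx"))
  expect_identical(e1$completed, e2$completed)
  e3 <- two_step_impute(reg, M = 4, seed = 10, predictors = c("sex", "age_dx"))
  expect_false(identical(e1$completed, e3$completed))
})

test_that("step-2 training switch accepts step-1 completions", {
  reg <- generate_registry(small_config(), seed = 29)
  ens <- two_step_impute(reg, M = 3, seed = 2,
                         predictors = c("sex", "age_dx"),
                         step2_training = "include_step1")
  expect_false(anyNA(ens$completed))
  expect_null(ens$models$step2)  # refitted per round, not cached
})
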