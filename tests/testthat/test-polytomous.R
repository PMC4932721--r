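test_that("intercept-only fit reproduces observed class frequencies", {
  rec <- tiny_records(c(rep("SCC", 50), rep("ADCA", 30), rep("OTHER_KNOWN", 20)))
  rec$histology <- droplevels(rec$histology)
  fit <- fit_polytomous(rec, "histology", predictors = NULL,
                        reference = "SCC")
  p <- predict_class_probs(fit, rec[1:3, ])
  expect_equal(dim(p), c(3, 3))
  expect_equal(unname(p[1, ]), c(0.5, 0.3, 0.2), tolerance = 1e-4)
  expect_equal(unname(rowSums(p)), rep(1, 3))
})

test_that("imputation frequencies follow the model probabilities at large n", {
  set.seed(101)
  rec <- tiny_records(sample(c("SCC", "ADCA", "OTHER_KNOWN"), 10000,
                             replace = TRUE, prob = c(0.5, 0.3, 0.2)))
  rec$histology <- droplevels(rec$histology)
  fit <- fit_polytomous(rec, "histology", predictors = NULL)
  new <- tiny_records(rep("UNKNOWN", 100000))
  set.seed(11)
  imp <- draw_and_impute(fit, new)
  freq <- as.numeric(table(imp) / length(imp))
  target <- as.numeric(table(rec$histology)[levels(imp)] / nrow(rec))
  expect_true(all(abs(freq - target) < 0.01))
})

test_that("generating coefficients are recovered within 3 SE at n = 20,000", {
  cfg <- synthetic_registry_config(
    n_male = 13000L, n_female = 7000L,
    missingness = list(mechanism = "MCAR", rate = 0),
    nscc = list(onset_year = 1997L, rate = 0))
  reg <- generate_registry(cfg, seed = 55)
  reg$histology <- droplevels(reg$histology)
  fit <- fit_polytomous(reg, "histology", reference = "SCC",
                        predictors = c("sex", "age_dx", "year_dx",
                                       "district"))
  est <- tidy(fit)
  truth <- cfg$class_model$coefficients
  for (cl in rownames(truth)) {
    for (tm in c("sexfemale", "age_dx", "year_dx")) {
      row <- est[est$class == cl & est$term == tm, ]
      true_val <- switch(tm, sexfemale = truth[cl, "female"],
                         age_dx = truth[cl, "age"],
                         year_dx = truth[cl, "year"])
      expect_lt(abs(row$estimate - true_val) / row$std.error, 3,
                label = paste(cl, tm))
    }
  }
})

test_that("relative-risk ratios point the way the registry's fitted model does", {
  reg <- generate_registry(synthetic_registry_config(), seed = 6)
  obs <- dplyr::filter(reg, histology != "UNKNOWN", histology != "NSCC_NOS") |>
    dplyr::mutate(histology = droplevels(histology))
  fit <- fit_polytomous(obs, "histology", reference = "SCC",
                        predictors = c("sex", "age_dx", "year_dx"))
  est <- tidy(fit)
  pick <- function(cl, tm) est$rrr[est$class == cl & est$term == tm]
  expect_gt(pick("ADCA", "sexfemale"), 1)   # ADCA more likely in women
  expect_lt(pick("ADCA", "age_dx"), 1)      # ...in the young
  expect_gt(pick("ADCA", "year_dx"), 1)     # ...in recent years
})

test_that("perfect prediction is handled by augmentation and flagged without it", {
  # one district holds only ADCA cases: its dummy separates the classes
  h <- c(rep("ADCA", 30), rep(c("SCC", "ADCA"), 45))
  rec <- tiny_records(h)
  rec$histology <- droplevels(rec$histology)
  rec$district <- factor(c(rep("Krasae Sin", 30),
                           rep(c("Hat Yai", "Muang Songkhla"), 45)))
  fit <- fit_polytomous(rec, "histology", predictors = "district",
                        reference = "SCC", augment = TRUE)
  expect_true(all(is.finite(fit$mu)))
  expect_lt(max(abs(fit$mu)), 15)
  set.seed(3)
  imp <- draw_and_impute(fit, rec[rec$district == "Krasae Sin", ][1:20, ])
  expect_gt(mean(imp == "ADCA"), 0.7)
  expect_error(
    fit_polytomous(rec, "histology", predictors = "district",
                   reference = "SCC", augment = FALSE, maxit = 2000),
    "perfect prediction")
})

test_that("a class absent from the training data is an error naming it", {
  rec <- tiny_records(rep(c("SCC", "ADCA"), 20))
  rec$histology <- factor(rec$histology, levels = histology_levels())
  expect_error(
    fit_polytomous(rec, "histology", predictors = "sex"),
    "LARGE_CELL")
})

test_that("posterior coefficient draws vary but are reproducible", {
  rec <- tiny_records(rep(c("SCC", "ADCA", "OTHER_KNOWN"), 60))
  rec$histology <- droplevels(rec$histology)
  fit <- fit_polytomous(rec, "histology", predictors = c("sex", "age_dx"))
  set.seed(42); b1 <- draw_coefficients(fit)
  set.seed(42); b2 <- draw_coefficients(fit)
  set.seed(43); b3 <- draw_coefficients(fit)
  expect_identical(b1, b2)
  expect_false(identical(b1, b3))
  expect_false(identical(b1, fit$mu))
  new <- tiny_records(rep("UNKNOWN", 50))
  set.seed(7); i1 <- draw_and_impute(fit, new)
  set.seed(7); i2 <- draw_and_impute(fit, new)
  expect_identical(i1, i2)
})

test_that("draws honour the asymptotic covariance scale", {
  rec <- tiny_records(rep(c("SCC", "ADCA"), 300))
  rec$histology <- droplevels(rec$histology)
  fit <- fit_polytomous(rec, "histology", predictors = NULL)
  set.seed(9)
  draws <- replicate(400, draw_coefficients(fit)[1])
  expect_equal(mean(draws), unname(fit$mu[1]), tolerance = 0.05)
  expect_equal(sd(draws), sqrt(fit$vcov[1, 1]), tolerance = 0.15)
})
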