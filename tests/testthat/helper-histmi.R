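suppressMessages(library(dplyr))

# Small deterministic case table: n rows with the given histology labels,
# covariates cycled from fixed pools.
tiny_records <- function(histology,
                         sex = rep(c("male", "female"), length.out = n),
                         year = rep(1989:2013, length.out = n)) {
  n <- length(histology)
  tibble::tibble(
    sex = factor(sex, levels = c("male", "female")),
    age_dx = rep(c(45L, 55L, 60L, 65L, 70L, 75L), length.out = n),
    year_dx = as.integer(year),
    religion = factor(rep(c("buddhist_other", "muslim"), length.out = n),
                      levels = c("buddhist_other", "muslim")),
    district = factor(rep(c("Muang Songkhla", "Hat Yai", "Sadao"),
                          length.out = n)),
    morphology = "8000/3",
    histology = factor(histology, levels = histology_levels())
  )
}

# Scaled-down synthetic config for fast tests.
small_config <- function(...) {
  synthetic_registry_config(n_male = 600L, n_female = 300L, ...)
}

# Build an ensemble object by hand from a completed-class matrix, to test
# pooling and comparison arithmetic in isolation.
fake_ensemble <- function(records, completed_chr, masked) {
  lev <- collapsed_levels()
  completed <- apply(completed_chr, 2, function(x) match(x, lev))
  structure(list(
    records = tibble::as_tibble(records),
    completed = matrix(completed, nrow = nrow(records)),
    levels = lev, M = ncol(completed_chr), seed = 0L,
    masked = masked, originally_unknown = masked,
    originally_nscc = rep(FALSE, nrow(records)),
    models = list(), predictors = character(),
    step2_training = "observed"
  ), class = "histmi_ensemble")
}

# Flat-rate population table with three census anchors, for rate tests.
flat_population <- function(count = 10000, years = 1989:2013) {
  anchors <- c(1990L, 2000L, 2010L)
  proj <- setdiff(years, seq(min(anchors), max(anchors)))
  tidyr::expand_grid(
    sex = factor(c("male", "female"), levels = c("male", "female")),
    age_group = factor(age_group_levels(), levels = age_group_levels()),
    year = c(anchors, proj)
  ) |>
    mutate(count = count,
           source = ifelse(year %in% anchors, "census", "projection"))
}

read_fixture <- function(name) {
  readr::read_csv(system.file("extdata", name, package = "histmi"),
                  show_col_types = FALSE)
}
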