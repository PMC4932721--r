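# Synthetic cancer-registry generator with known ground truth.
#
# Emulates a Songkhla-like provincial registry, 1989-2013: two sexes, sixteen
# districts, six observed histology classes, ~29% unknown histology, and
# NSCC-NOS coarsening appearing from the late 1990s. The generator keeps the
# true specific class alongside the observed (masked/coarsened) class so the
# imputation, rate and APC stages can be validated against ground truth.

SPECIFIC_LEVELS <- c("SCC", "ADCA", "LARGE_CELL", "OTHER_KNOWN")

DISTRICT_TABLE <- tibble::tibble(
  district = c("Muang Songkhla", "Sathing Phra", "Chana", "Na Thawi",
               "Thepha", "Saba Yoi", "Ranot", "Krasae Sin", "Rattaphum",
               "Sadao", "Hat Yai", "Na Mom", "Khuan Niang", "Bang Klam",
               "Singhanakhon", "Khlong Hoi Khong"),
  male = c(455, 101, 194, 135, 116, 64, 150, 30, 113, 265, 782, 47, 58, 45,
           141, 38),
  female = c(161, 56, 77, 41, 42, 21, 71, 14, 46, 79, 355, 23, 37, 17, 55, 15)
)

# Default per-sex probabilities of the five 5-year diagnosis periods,
# reflecting the registry's observed growth in case counts.
PERIOD_COUNTS <- list(
  male = c(272, 336, 434, 794, 898),
  female = c(92, 130, 178, 257, 453)
)

# True-class multinomial logit (reference SCC) over the four specific
# classes. Covariates: female indicator, age centred at 64, diagnosis year
# centred at 2001, non-Muang district indicator. Signs follow the fitted
# relative-risk ratios of the real registry: adenocarcinoma strongly more
# likely in women, in the young, and in recent years.
DEFAULT_CLASS_MODEL <- list(
  classes = SPECIFIC_LEVELS,
  reference = "SCC",
  coefficients = rbind(
    ADCA        = c(intercept = 0.45,  female = 1.37, age = -0.020,
                    year = 0.068, other_district = -0.02),
    LARGE_CELL  = c(intercept = -1.79, female = 0.63, age = 0,
                    year = -0.022, other_district = -0.48),
    OTHER_KNOWN = c(intercept = -0.51, female = 0.41, age = -0.020,
                    year = 0.020, other_district = 0)
  )
)

#' Configuration for the synthetic registry generator
#'
#' Returns the study conditions the generator emulates: case totals of 2,734
#' men and 1,110 women over 1989-2013, age at diagnosis 64.5 (SD 12.4) and
#' 63.8 (SD 14.4) years, district and religion mixes matching the registry's
#' published margins, a four-class true-histology multinomial logit whose
#' covariate effects point the way the registry's fitted relative-risk ratios
#' do, an overall 28.9% unknown-histology rate that under MAR depends on
#' observed covariates only, and NSCC-NOS coarsening of ~8% of unmasked
#' specific diagnoses from 1997 onwards (≈5% of all diagnoses, matching the
#' period tables). Any element can be overridden.
#'
#' @param n_male,n_female Number of cases per sex.
#' @param year_range Inclusive diagnosis-year window.
#' @param period_probs Named list (`male`, `female`) of probabilities over the
#'   five 5-year periods of `year_range`.
#' @param age_mean,age_sd Named vectors (`male`, `female`); age is drawn from
#'   a normal truncated to `age_limits` and rounded to completed years.
#' @param age_limits Truncation bounds for age at diagnosis.
#' @param p_muslim Named vector of Muslim proportion per sex.
#' @param district_probs Tibble with columns `district`, `male`, `female`
#'   (weights; normalised internally).
#' @param class_model True-class multinomial logit: list with `classes`,
#'   `reference`, and a coefficient matrix (rows = non-reference classes,
#'   columns `intercept`, `female`, `age`, `year`, `other_district`; age and
#'   year enter centred at 64 and 2001).
#' @param missingness List: `mechanism` one of `"MCAR"`, `"MAR"`, `"NMAR"`;
#'   `rate`, the target overall unknown fraction; `coef`, log-odds
#'   coefficients on `age` (centred), `year` (centred) and `other_district`
#'   used by MAR/NMAR; `class_coef`, named log-odds offsets per true class
#'   (NMAR only). The intercept is calibrated so the expected masked fraction
#'   equals `rate`.
#' @param nscc List: `onset_year` (no coarsening before it) and `rate`, the
#'   probability that an unmasked specific diagnosis from `onset_year` on is
#'   recorded as NSCC-NOS.
#' @param population Population-table settings: list with `base_total` (named
#'   per-sex person counts at year 2000), `growth` (annual log-growth),
#'   `ageing` (extra annual log-growth per year of age-group midpoint above
#'   40, scaled by 1/45), `census_years`, `projection_years`.
#' @return A validated `histmi_synth_config` list.
#' @export
synthetic_registry_config <- function(
    n_male = 2734L,
    n_female = 1110L,
    year_range = c(1989L, 2013L),
    period_probs = lapply(PERIOD_COUNTS, function(x) x / sum(x)),
    age_mean = c(male = 64.5, female = 63.8),
    age_sd = c(male = 12.4, female = 14.4),
    age_limits = c(20, 99),
    p_muslim = c(male = 406 / 2734, female = 106 / 1110),
    district_probs = DISTRICT_TABLE,
    class_model = DEFAULT_CLASS_MODEL,
    missingness = list(mechanism = "MAR", rate = 0.289,
                       coef = c(age = 0.02, year = 0, other_district = 0.25),
                       class_coef = NULL),
    nscc = list(onset_year = 1997L, rate = 0.08),
    population = list(base_total = c(male = 600000, female = 620000),
                      growth = 0.012, ageing = 0.015,
                      census_years = c(1990L, 2000L, 2010L),
                      projection_years = c(1989L, 2011L, 2012L, 2013L))) {
  cfg <- list(n_male = as.integer(n_male), n_female = as.integer(n_female),
              year_range = as.integer(year_range),
              period_probs = period_probs, age_mean = age_mean,
              age_sd = age_sd, age_limits = age_limits, p_muslim = p_muslim,
              district_probs = district_probs, class_model = class_model,
              missingness = missingness, nscc = nscc,
              population = population)
  validate_synth_config(cfg)
  structure(cfg, class = "histmi_synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_male + cfg$n_female <= 0) abort("Zero cases configured.")
  if (cfg$n_male < 0 || cfg$n_female < 0) abort("Negative case count.")
  if (cfg$year_range[2] < cfg$year_range[1]) abort("Empty year range.")
  for (s in SEX_LEVELS) {
    p <- cfg$period_probs[[s]]
    if (abs(sum(p) - 1) > 1e-9 || any(p < 0)) {
      abort(paste0("period_probs$", s, " must be non-negative and sum to 1."))
    }
  }
  dp <- cfg$district_probs
  require_columns(dp, c("district", "male", "female"), "district_probs")
  if (any(dp$male < 0) || any(dp$female < 0)) {
    abort("District weights must be non-negative.")
  }
  mech <- cfg$missingness$mechanism
  if (!mech %in% c("MCAR", "MAR", "NMAR")) {
    abort("missingness$mechanism must be one of MCAR, MAR, NMAR.")
  }
  rate <- cfg$missingness$rate
  if (rate < 0 || rate >= 1) abort("missingness$rate must be in [0, 1).")
  if (!is.null(cfg$nscc) && (cfg$nscc$rate < 0 || cfg$nscc$rate > 1)) {
    abort("nscc$rate must be in [0, 1].")
  }
  if (any(cfg$population$base_total <= 0)) {
    abort("Population base totals must be positive.")
  }
  invisible(cfg)
}

# Normal truncated to [lo, hi] via inverse-CDF sampling.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

# Design columns used by the true-class and missingness linear predictors.
synth_design <- function(d) {
  cbind(intercept = 1,
        female = as.numeric(d$sex == "female"),
        age = d$age_dx - 64,
        year = d$year_dx - 2001,
        other_district = as.numeric(d$district != "Muang Songkhla"))
}

# Solve the masking-model intercept so that the in-sample expected masked
# fraction equals the target rate.
calibrate_intercept <- function(lp, rate) {
  if (rate == 0) return(-Inf)
  f <- function(a) mean(plogis(a + lp)) - rate
  uniroot(f, c(-30, 30))$root
}

#' Generate a synthetic registry with known ground truth
#'
#' Draws cases under the study conditions in `config` and returns a truth
#' bundle: the observed case columns (as [read_registry()] would produce)
#' plus `true_class`, `masked` and `coarsened`. The observed `histology`
#' equals `true_class` wherever the case is neither masked (UNKNOWN) nor
#' coarsened (NSCC_NOS). Output is reproducible: the same config and seed
#' give identical tibbles.
#'
#' @param config A [synthetic_registry_config()].
#' @param seed Integer random seed.
#' @return Tibble with one row per case and the generating `config` and
#'   `seed` stored as attributes.
#' @export
#' @examples
#' reg <- generate_registry(synthetic_registry_config(n_male = 300,
#'                                                    n_female = 120), seed = 7)
#' table(reg$histology)
generate_registry <- function(config, seed) {
  validate_synth_config(config)
  set.seed(as.integer(seed))
  n <- c(male = config$n_male, female = config$n_female)

  per_sex <- lapply(SEX_LEVELS, function(s) {
    ns <- n[[s]]
    if (ns == 0) return(NULL)
    yr <- config$year_range
    breaks <- round(seq(yr[1], yr[2] + 1, length.out = 6))
    period <- sample.int(5, ns, replace = TRUE, prob = config$period_probs[[s]])
    width <- breaks[period + 1] - breaks[period]
    year <- as.integer(breaks[period] + floor(runif(ns) * width))
    age <- as.integer(round(rtruncnorm(ns, config$age_mean[[s]],
                                       config$age_sd[[s]],
                                       config$age_limits[1],
                                       config$age_limits[2])))
    age <- pmin(pmax(age, config$age_limits[1]), config$age_limits[2])
    religion <- ifelse(runif(ns) < config$p_muslim[[s]], "muslim",
                       "buddhist_other")
    w <- config$district_probs[[s]]
    district <- sample(config$district_probs$district, ns, replace = TRUE,
                       prob = w / sum(w))
    tibble(sex = s, age_dx = age, year_dx = year,
           religion = religion, district = district)
  })
  d <- bind_rows(per_sex)
  d$sex <- factor(d$sex, levels = SEX_LEVELS)
  d$religion <- factor(d$religion, levels = RELIGION_LEVELS)
  d$district <- factor(d$district, levels = config$district_probs$district)

  # True specific class from the configured multinomial logit.
  cm <- config$class_model
  X <- synth_design(d)
  eta <- X %*% t(cm$coefficients[, colnames(X), drop = FALSE])
  probs <- softmax_ref(eta)
  classes <- c(cm$reference, rownames(cm$coefficients))
  d$true_class <- factor(classes[sample_categorical(probs)],
                         levels = SPECIFIC_LEVELS)

  # Masking (unknown histology).
  mis <- config$missingness
  lp <- switch(mis$mechanism,
    MCAR = rep(0, nrow(d)),
    MAR = drop(X[, names(mis$coef), drop = FALSE] %*% mis$coef),
    NMAR = {
      base <- drop(X[, names(mis$coef), drop = FALSE] %*% mis$coef)
      cls <- mis$class_coef %||% setNames(rep(0, 4), SPECIFIC_LEVELS)
      base + unname(cls[as.character(d$true_class)])
    })
  a <- calibrate_intercept(lp, mis$rate)
  d$masked <- runif(nrow(d)) < plogis(a + lp)

  # NSCC-NOS coarsening of unmasked specific diagnoses from the onset year.
  d$coarsened <- !d$masked &
    d$year_dx >= config$nscc$onset_year &
    runif(nrow(d)) < config$nscc$rate

  d$histology <- factor(
    ifelse(d$masked, "UNKNOWN",
           ifelse(d$coarsened, "NSCC_NOS", as.character(d$true_class))),
    levels = HISTOLOGY_LEVELS)
  rep_code <- c(SCC = "8070/3", ADCA = "8140/3", LARGE_CELL = "8012/3",
                NSCC_NOS = "8046/3", OTHER_KNOWN = "8041/3",
                UNKNOWN = "8000/3")
  d$morphology <- unname(rep_code[as.character(d$histology)])
  d <- d |>
    mutate(case_id = dplyr::row_number()) |>
    select("case_id", "sex", "age_dx", "year_dx", "religion", "district",
           "morphology", "histology", "true_class", "masked", "coarsened")
  attr(d, "config") <- config
  attr(d, "seed") <- as.integer(seed)
  class(d) <- c("histmi_truth", class(d))
  d
}

#' Write the ground-truth columns of a synthetic registry
#'
#' Saves `case_id`, `true_class`, `masked`, `coarsened` to a separate file so
#' the observed case file written by [write_registry()] never contains truth.
#'
#' @param truth A truth bundle from [generate_registry()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  require_columns(truth, c("case_id", "true_class", "masked", "coarsened"),
                  "truth bundle")
  readr::write_csv(
    tibble(case_id = truth$case_id,
           true_class = as.character(truth$true_class),
           masked = truth$masked, coarsened = truth$coarsened),
    path)
  invisible(path)
}

#' Generate a synthetic census/projection population table
#'
#' Builds per-sex, 18-age-group person counts at the configured census years
#' plus annual projection rows outside the census span (so the registry's
#' first year and the years after the last census are covered without
#' extrapolation). The population grows log-linearly, with older age groups
#' growing faster than younger ones so that the age structure ages over the
#' study period. Deterministic: no random component.
#'
#' @param config A [synthetic_registry_config()].
#' @return Tibble with columns `sex`, `age_group`, `year`, `count`, `source`
#'   (`"census"` or `"projection"`).
#' @export
#' @examples
#' pop <- generate_population(synthetic_registry_config())
#' dplyr::count(pop, source)
generate_population <- function(config) {
  validate_synth_config(config)
  pcfg <- config$population
  share <- c(10, 10, 10, 10, 9, 8, 8, 7, 6, 5, 4, 3.5, 3, 2.5, 2, 1.5, 1, 1)
  share <- share / sum(share)
  mids <- age_group_midpoint(age_group_levels())
  years <- tibble(
    year = c(pcfg$census_years, pcfg$projection_years),
    source = rep(c("census", "projection"),
                 c(length(pcfg$census_years), length(pcfg$projection_years)))
  )
  out <- tidyr::expand_grid(
    sex = factor(SEX_LEVELS, levels = SEX_LEVELS),
    tibble(age_group = factor(age_group_levels(),
                              levels = age_group_levels()),
           share = share, mid = mids),
    years
  ) |>
    mutate(
      g = pcfg$growth + pcfg$ageing * (.data$mid - 40) / 45,
      count = round(pcfg$base_total[as.character(.data$sex)] * .data$share *
                      exp(.data$g * (.data$year - 2000))),
      count = pmax(.data$count, 1)
    ) |>
    select("sex", "age_group", "year", "count", "source") |>
    arrange(.data$sex, .data$age_group, .data$year)
  if (any(out$count <= 0)) abort("Generated non-positive population count.")
  out
}
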