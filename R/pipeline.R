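# End-to-end orchestration: generate/load -> classify -> impute -> rates ->
# APC -> report.

#' Five-year period labels
#'
#' Splits a year window into five inclusive intervals labelled as registries
#' print them ("1989-1993" means 1989..1993 inclusive).
#'
#' @param year Integer vector of diagnosis years.
#' @param year_range Window, default `c(1989, 2013)`.
#' @return Factor of period labels.
#' @export
#' @examples
#' year_to_period(c(1989, 1993, 1994, 2013))
year_to_period <- function(year, year_range = c(1989, 2013)) {
  breaks <- round(seq(year_range[1], year_range[2] + 1, length.out = 6))
  labels <- paste(breaks[-6], breaks[-1] - 1, sep = "-")
  if (any(year < year_range[1] | year > year_range[2], na.rm = TRUE)) {
    abort("Years outside the configured window.")
  }
  cut(year, breaks = breaks, labels = labels, right = FALSE,
      include.lowest = TRUE)
}

#' Histology-by-period tabulation
#'
#' The period-trend table: per sex and 5-year period, counts of each
#' six-class histology with row-wise percentages (each sex-period row sums
#' to 100).
#'
#' @param records Case tibble.
#' @param year_range Window for the period labels.
#' @return Tibble `sex`, `period`, `histology`, `n`, `pct`.
#' @export
histology_by_period <- function(records, year_range = c(1989, 2013)) {
  stop_if_empty(records, "case table")
  records |>
    mutate(period = year_to_period(.data$year_dx, year_range)) |>
    count(.data$sex, .data$period, .data$histology) |>
    tidyr::complete(.data$sex, .data$period, .data$histology,
                    fill = list(n = 0L)) |>
    group_by(.data$sex, .data$period) |>
    mutate(pct = if (sum(n) > 0) 100 * .data$n / sum(.data$n) else NA_real_) |>
    ungroup()
}

#' Known-histology distribution with normal-approximation CI
#'
#' The "known histology" columns of the post-imputation report: counts and
#' percentages of the collapsed classes among cases with an originally
#' specific histology, with a 95% CI on each percentage from its standard
#' error.
#'
#' @param records Case tibble with six-class `histology`.
#' @param by Stratifier, default `"sex"`.
#' @return Tibble with `n`, `pct`, `pct_lo`, `pct_hi` per stratum x class.
#' @export
known_histology_table <- function(records, by = "sex") {
  specific <- records |>
    filter(!.data$histology %in% c("UNKNOWN", "NSCC_NOS")) |>
    mutate(class = collapse_histology(.data$histology))
  stop_if_empty(specific, "known-histology subset")
  specific |>
    count(across(all_of(by)), .data$class) |>
    tidyr::complete(!!!rlang::syms(by), .data$class, fill = list(n = 0L)) |>
    group_by(across(all_of(by))) |>
    mutate(
      total = sum(.data$n),
      pct = 100 * .data$n / .data$total,
      se = sqrt(.data$pct * (100 - .data$pct) / .data$total),
      pct_lo = pmax(.data$pct - qnorm(0.975) * .data$se, 0),
      pct_hi = pmin(.data$pct + qnorm(0.975) * .data$se, 100)
    ) |>
    ungroup() |>
    select(all_of(by), "class", "n", "total", "pct", "pct_lo", "pct_hi")
}

#' SCC/ADCA ratio over a period, with probability interval
#'
#' Ratio of pooled SCC to pooled ADCA estimated case counts over a calendar
#' period, per sex, pooled over the imputation rounds (mean and percentile
#' 95% PI of the per-round ratios). If an annual population is supplied, an
#' ASR-based variant (ratio of the mean ASRs over the period's years) is
#' reported as well.
#'
#' @param ensemble A `histmi_ensemble`.
#' @param period Inclusive year window, default `c(2009, 2013)`.
#' @param population Optional annual population from
#'   [interpolate_population()] for the ASR-based variant.
#' @param standard Standard population for the ASR variant.
#' @return Tibble `sex`, `method` (`"counts"`/`"asr"`), `ratio`, `pi_lo`,
#'   `pi_hi`, `note` (flags an undefined ratio when ADCA is zero).
#' @export
report_scc_adca_ratio <- function(ensemble, period = c(2009, 2013),
                                  population = NULL,
                                  standard = segi_world_standard()) {
  rec <- ensemble$records
  in_period <- rec$year_dx >= period[1] & rec$year_dx <= period[2]
  out <- purrr::map_dfr(SEX_LEVELS, function(s) {
    sel <- in_period & rec$sex == s
    ratios <- vapply(seq_len(ensemble$M), function(m) {
      cls <- ensemble$levels[ensemble$completed[sel, m]]
      n_scc <- sum(cls == "SCC")
      n_adca <- sum(cls == "ADCA")
      if (n_adca == 0) NA_real_ else n_scc / n_adca
    }, numeric(1))
    if (all(is.na(ratios))) {
      tibble(sex = s, method = "counts", ratio = NA_real_, pi_lo = NA_real_,
             pi_hi = NA_real_, note = "undefined: zero ADCA count")
    } else {
      tibble(sex = s, method = "counts", ratio = mean(ratios, na.rm = TRUE),
             pi_lo = quantile(ratios, 0.025, na.rm = TRUE, names = FALSE),
             pi_hi = quantile(ratios, 0.975, na.rm = TRUE, names = FALSE),
             note = NA_character_)
    }
  })
  if (!is.null(population)) {
    series <- asr_ensemble(ensemble, population,
                           standard = standard,
                           years = seq(period[1], period[2]),
                           classes = c("SCC", "ADCA"))
    asr_ratio <- series |>
      group_by(.data$sex) |>
      summarise(
        ratio = mean(.data$asr[.data$class == "SCC"]) /
          mean(.data$asr[.data$class == "ADCA"]),
        .groups = "drop") |>
      mutate(method = "asr", pi_lo = NA_real_, pi_hi = NA_real_,
             note = NA_character_) |>
      select("sex", "method", "ratio", "pi_lo", "pi_hi", "note")
    out <- bind_rows(out, asr_ratio)
  }
  out
}

#' Configuration of a full registry analysis run
#'
#' @param synthetic A [synthetic_registry_config()] (default), or `NULL` to
#'   read files instead.
#' @param case_file,population_file Input paths when `synthetic` is `NULL`.
#'   The population file needs columns `sex`, `age_group`, `year`, `count`,
#'   `source`.
#' @param M Imputation rounds.
#' @param seed Master seed; every stage derives its sub-stream from it.
#' @param predictors Imputation-model predictors.
#' @param district_coding,step2_training Passed to [two_step_impute()].
#' @param year_range Analysis window.
#' @param classes Collapsed classes for the rate/trend outputs.
#' @param apc_df APC spline degrees of freedom.
#' @param ratio_period Window for the SCC/ADCA ratio report.
#' @return A `histmi_run_config` list.
#' @export
registry_run_config <- function(synthetic = synthetic_registry_config(),
                                case_file = NULL, population_file = NULL,
                                M = 200, seed = 1,
                                predictors = c("sex", "age_dx", "year_dx",
                                               "district"),
                                district_coding = "muang",
                                step2_training = "observed",
                                year_range = c(1989, 2013),
                                classes = c("SCC", "ADCA"),
                                apc_df = c(age = 5, period = 4, cohort = 4),
                                ratio_period = c(2009, 2013)) {
  if (is.null(synthetic) &&
      (is.null(case_file) || is.null(population_file))) {
    abort("Provide either a synthetic config or case and population files.")
  }
  structure(list(synthetic = synthetic, case_file = case_file,
                 population_file = population_file, M = M, seed = seed,
                 predictors = predictors, district_coding = district_coding,
                 step2_training = step2_training,
                 year_range = year_range, classes = classes,
                 apc_df = apc_df, ratio_period = ratio_period),
            class = "histmi_run_config")
}

stage_msg <- function(quiet, ...) {
  if (!quiet) inform(paste0("[histmi] ", sprintf(...)))
}

#' Run the full registry analysis
#'
#' Orchestrates every stage: obtain cases and population (synthetic or from
#' files), tabulate, run the two-step multiple imputation, interpolate the
#' population, compute before/after ASR and case-count series, fit the APC
#' drift per sex and class (a single fit on the observed known-histology
#' series, and percentile-pooled over the completed datasets), and assemble
#' the SCC/ADCA ratio and a reproducibility manifest. The entire run is
#' deterministic given the config and its seed.
#'
#' @param config A [registry_run_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A `histmi_report` list: `records`, `population`, `tabulations`,
#'   `ensemble`, `pooled`, `known_table`, `comparison`, `asr`,
#'   `case_counts`, `drift`, `ratio`, `manifest`.
#' @export
run_registry_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "histmi_run_config"))
  seeds <- spawn_seeds(config$seed, 2)
  t0 <- Sys.time()

  if (!is.null(config$synthetic)) {
    stage_msg(quiet, "generating synthetic registry (seed %d)", seeds[1])
    records <- generate_registry(config$synthetic, seed = seeds[1])
    pop_raw <- generate_population(config$synthetic)
  } else {
    stage_msg(quiet, "reading %s", config$case_file)
    records <- read_registry(config$case_file,
                             year_range = config$year_range)
    pop_raw <- readr::read_csv(config$population_file,
                               col_types = readr::cols(), progress = FALSE)
    require_columns(pop_raw, c("sex", "age_group", "year", "count"),
                    "population file")
    pop_raw$sex <- factor(pop_raw$sex, levels = SEX_LEVELS)
    pop_raw$age_group <- factor(pop_raw$age_group,
                                levels = age_group_levels())
  }
  stage_msg(quiet, "%d cases (%d unknown, %d NSCC-NOS)", nrow(records),
            sum(records$histology == "UNKNOWN"),
            sum(records$histology == "NSCC_NOS"))

  tabulations <- list(
    histology_by_sex = tabulate_cases(records, "histology"),
    age_by_sex = tabulate_cases(records, "age_dx"),
    religion_by_sex = tabulate_cases(records, "religion"),
    district_by_sex = tabulate_cases(records, "district"),
    period_by_sex = tabulate_cases(
      records |> mutate(period = year_to_period(.data$year_dx,
                                                config$year_range)),
      "period"),
    histology_by_period = histology_by_period(records, config$year_range)
  )

  stage_msg(quiet, "two-step imputation: M = %d (seed %d)", config$M,
            seeds[2])
  ensemble <- two_step_impute(records, M = config$M, seed = seeds[2],
                              predictors = config$predictors,
                              district_coding = config$district_coding,
                              step2_training = config$step2_training)
  pooled <- pool_ensemble(ensemble, by = "sex", among = "imputed")
  known_table <- known_histology_table(records)
  comparison <- compare_known_vs_imputed(ensemble)

  stage_msg(quiet, "interpolating population")
  years <- seq(config$year_range[1], config$year_range[2])
  population <- interpolate_population(pop_raw, years)

  stage_msg(quiet, "age-standardized rate series")
  asr_before <- asr_series(records, population, years = years,
                           classes = config$classes) |>
    mutate(stage = "before")
  asr_after <- asr_ensemble(ensemble, population, years = years,
                            classes = config$classes) |>
    mutate(stage = "after")
  asr_tbl <- bind_rows(asr_before, asr_after) |>
    select("stage", "sex", "class", "year", "events", "asr",
           dplyr::any_of(c("asr_lo", "asr_hi")))
  case_counts <- asr_tbl |> select("stage", "sex", "class", "year", "events")

  stage_msg(quiet, "APC drift per sex x class")
  drift_tbl <- purrr::map_dfr(SEX_LEVELS, function(s) {
    pop_s <- population |> filter(.data$sex == s)
    purrr::map_dfr(config$classes, function(cl) {
      cl_obs <- collapse_histology(ensemble$records$histology,
                                   strict = FALSE)
      known <- ensemble$records[ensemble$records$sex == s &
                                  !is.na(cl_obs) & cl_obs == cl, ,
                                drop = FALSE]
      before <- tryCatch({
        fit <- fit_apc(build_lexis(known, pop_s, years = years),
                       df = config$apc_df)
        drift(fit) |> mutate(sex = s, class = cl, stage = "before") |>
          select("stage", "sex", "class", "drift_pct", ci_lo = "ci_lo",
                 ci_hi = "ci_hi")
      }, error = function(e) {
        tibble(stage = "before", sex = s, class = cl, drift_pct = NA_real_,
               ci_lo = NA_real_, ci_hi = NA_real_)
      })
      after <- drift_ensemble(ensemble, population, sex = s, class = cl,
                              years = years,
                              df_age = config$apc_df[["age"]]) |>
        mutate(stage = "after") |>
        select("stage", "sex", "class", "drift_pct", ci_lo = "pi_lo",
               ci_hi = "pi_hi")
      bind_rows(before, after)
    })
  })

  ratio <- report_scc_adca_ratio(ensemble, period = config$ratio_period,
                                 population = population)

  manifest <- list(
    package = "histmi",
    version = as.character(utils::packageVersion("histmi")),
    seed = config$seed, M = config$M,
    predictors = config$predictors,
    district_coding = config$district_coding,
    step2_training = config$step2_training,
    year_range = config$year_range, classes = config$classes,
    apc_df = as.list(config$apc_df), ratio_period = config$ratio_period,
    n_cases = nrow(records),
    n_unknown = sum(records$histology == "UNKNOWN"),
    n_nscc = sum(records$histology == "NSCC_NOS"),
    synthetic = !is.null(config$synthetic)
  )
  stage_msg(quiet, "done in %.1f s", as.numeric(Sys.time() - t0, units = "secs"))

  structure(list(records = records, population = population,
                 tabulations = tabulations, ensemble = ensemble,
                 pooled = pooled, known_table = known_table,
                 comparison = comparison, asr = asr_tbl,
                 case_counts = case_counts, drift = drift_tbl,
                 ratio = ratio, manifest = manifest),
            class = "histmi_report")
}

#' @export
print.histmi_report <- function(x, ...) {
  cat(sprintf("histmi report: %d cases, M = %d rounds\n",
              x$manifest$n_cases, x$manifest$M))
  cat("Pooled imputed distribution (by sex):\n")
  print(as_tibble(x$pooled), n = Inf)
  cat("Drift (% per year):\n")
  print(as_tibble(x$drift), n = Inf)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes every tabular output as CSV plus a JSON manifest. Outputs are
#' byte-identical across runs with the same config and inputs (no
#' timestamps).
#'
#' @param report A `histmi_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) {
    readr::write_csv(as_tibble(x) |>
                       mutate(across(dplyr::where(is.list), ~ vapply(
                         .x, function(v) paste(format(v), collapse = ";"),
                         character(1)))),
                     file.path(dir, paste0(name, ".csv")))
  }
  w(report$tabulations$histology_by_sex, "histology_by_sex")
  w(report$tabulations$histology_by_period, "histology_by_period")
  w(report$pooled, "imputed_distribution")
  w(report$known_table, "known_distribution")
  w(report$comparison |> select(-dplyr::any_of(c("known_counts",
                                                 "imputed_counts"))),
    "known_vs_imputed_test")
  w(report$asr, "asr_series")
  w(report$case_counts, "case_counts")
  w(report$drift, "drift")
  w(report$ratio, "scc_adca_ratio")
  w(report$population, "population_annual")
  jsonlite::write_json(report$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
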