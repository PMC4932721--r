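# Population interpolation and age-standardized incidence rates.

#' Segi/Doll world standard population
#'
#' The conventional world standard population (Segi 1960, as modified by Doll
#' 1966): 18 five-year age-group weights summing to 100,000, used for direct
#' age standardization of incidence rates.
#'
#' @return Tibble with columns `age_group` and `weight`.
#' @export
#' @examples
#' sum(segi_world_standard()$weight)  # 100000
segi_world_standard <- function() {
  tibble(
    age_group = factor(age_group_levels(), levels = age_group_levels()),
    weight = c(12000, 10000, 9000, 9000, 8000, 8000, 6000, 6000, 6000,
               6000, 5000, 4000, 4000, 3000, 2000, 1000, 500, 500)
  )
}

#' Interpolate a census population to annual counts
#'
#' Builds a complete sex x age-group x year population table over
#' `years` from census anchors, using a log-linear (constant-growth)
#' function between consecutive censuses:
#' `P(t) = P(t1) * (P(t2)/P(t1))^((t - t1)/(t2 - t1))`. Anchor years are
#' reproduced exactly. Years outside the census span are never extrapolated:
#' they must be covered by projection rows (`source != "census"`) in the
#' input, else an error is raised.
#'
#' @param population Tibble with columns `sex`, `age_group`, `year`, `count`
#'   and `source` (`"census"` marks anchors; anything else is a projection),
#'   e.g. from [generate_population()]. A missing `source` column treats all
#'   rows as anchors.
#' @param years Integer vector of target years (default: the full range of
#'   years present).
#' @return Tibble `sex`, `age_group`, `year`, `count`, `source` with
#'   `source` one of `"census"`, `"interpolated"`, `"projection"`.
#' @export
#' @examples
#' pop <- generate_population(synthetic_registry_config())
#' annual <- interpolate_population(pop, 1989:2013)
interpolate_population <- function(population, years = NULL) {
  require_columns(population, c("sex", "age_group", "year", "count"),
                  "population")
  if (!"source" %in% names(population)) population$source <- "census"
  if (any(population$count <= 0)) abort("Population counts must be positive.")
  years <- sort(unique(as.integer(
    years %||% seq(min(population$year), max(population$year)))))

  population |>
    group_by(.data$sex, .data$age_group) |>
    dplyr::group_modify(function(d, key) {
      anchors <- d |> filter(.data$source == "census") |> arrange(.data$year)
      if (nrow(anchors) < 2) {
        abort("Need at least two census anchors per sex x age group.")
      }
      proj <- d |> filter(.data$source != "census")
      purrr::map_dfr(years, function(t) {
        if (t %in% anchors$year) {
          return(tibble(year = t,
                        count = anchors$count[anchors$year == t][1],
                        source = "census"))
        }
        if (t > min(anchors$year) && t < max(anchors$year)) {
          i <- max(which(anchors$year < t))
          t1 <- anchors$year[i]; t2 <- anchors$year[i + 1]
          p1 <- anchors$count[i]; p2 <- anchors$count[i + 1]
          return(tibble(year = t,
                        count = p1 * (p2 / p1)^((t - t1) / (t2 - t1)),
                        source = "interpolated"))
        }
        hit <- proj$year == t
        if (any(hit)) {
          return(tibble(year = t, count = proj$count[hit][1],
                        source = "projection"))
        }
        abort(paste0("Year ", t, " is outside the census span for ",
                     paste(unlist(key), collapse = "/"),
                     " and no projection row was supplied."))
      })
    }) |>
    ungroup() |>
    select("sex", "age_group", "year", "count", "source") |>
    arrange(.data$sex, .data$age_group, .data$year)
}

#' Directly age-standardized rate
#'
#' `ASR = sum(w_i * d_i / n_i) / sum(w_i) * 100000` over age groups `i`, with
#' weights from a standard population. The ASR is invariant to proportional
#' rescaling of the weights. Groups with zero cases and zero person-years
#' contribute a zero rate; zero person-years with non-zero cases is an error.
#'
#' @param events Case counts per age group.
#' @param person_years Population person-years per age group, aligned with
#'   `events`.
#' @param weights Standard-population weights, aligned with `events`
#'   (default: the Segi/Doll weights, requiring 18 groups).
#' @return The ASR per 100,000 person-years (scalar).
#' @export
#' @examples
#' asr(events = c(1, 2), person_years = c(1000, 1000),
#'     weights = c(60000, 40000))  # 140
asr <- function(events, person_years, weights = segi_world_standard()$weight) {
  if (length(events) != length(person_years) ||
      length(events) != length(weights)) {
    abort("events, person_years and weights must have equal length.")
  }
  bad <- person_years <= 0 & events > 0
  if (any(bad)) {
    abort("Zero person-years in an age group with non-zero cases.")
  }
  rate <- ifelse(person_years > 0, events / person_years, 0)
  sum(weights * rate) / sum(weights) * 1e5
}

#' Age-standardized rate series from observed cases
#'
#' Computes the ASR per sex, class and calendar year from a case tibble —
#' the "before imputation" curves, which use only cases whose observed
#' histology maps to the requested collapsed class.
#'
#' @param records Case tibble with `sex`, `age_dx`, `year_dx`, `histology`.
#' @param population Annual population from [interpolate_population()].
#' @param standard Standard population tibble (default Segi/Doll).
#' @param years Calendar years to cover (default: all years in `population`).
#' @param classes Collapsed classes to report (default SCC and ADCA).
#' @return Tibble `sex`, `class`, `year`, `events`, `asr`.
#' @export
asr_series <- function(records, population, standard = segi_world_standard(),
                       years = NULL, classes = c("SCC", "ADCA")) {
  require_columns(records, c("sex", "age_dx", "year_dx", "histology"),
                  "records")
  years <- years %||% sort(unique(population$year))
  cases <- records |>
    mutate(class = collapse_histology(.data$histology, strict = FALSE),
           age_group = age_to_group(.data$age_dx),
           year = .data$year_dx) |>
    filter(!is.na(.data$class), .data$class %in% classes,
           .data$year %in% years) |>
    mutate(class = factor(.data$class, levels = classes))
  grid <- tidyr::expand_grid(
    sex = factor(SEX_LEVELS, levels = SEX_LEVELS),
    class = factor(classes, levels = classes),
    year = years)
  filled <- cases |>
    count(.data$sex, .data$class, .data$year, .data$age_group) |>
    tidyr::complete(grid, age_group = factor(age_group_levels(),
                                             levels = age_group_levels()),
                    fill = list(n = 0L))
  filled |>
    left_join(population |> select("sex", "age_group", "year", py = "count"),
              by = c("sex", "age_group", "year")) |>
    left_join(standard, by = "age_group") |>
    group_by(.data$sex, .data$class, .data$year) |>
    summarise(events = sum(.data$n), asr = asr(.data$n, .data$py, .data$weight),
              .groups = "drop")
}

#' Age-standardized rate series over an imputation ensemble
#'
#' Computes the ASR per sex, class and year within every completed dataset,
#' then pools by mean and 2.5th/97.5th percentiles — the "after imputation"
#' curves with their 95% probability intervals.
#'
#' @inheritParams asr_series
#' @param ensemble A `histmi_ensemble` from [two_step_impute()].
#' @return Tibble `sex`, `class`, `year`, `events` (mean), `asr`, `asr_lo`,
#'   `asr_hi`.
#' @export
asr_ensemble <- function(ensemble, population,
                         standard = segi_world_standard(), years = NULL,
                         classes = c("SCC", "ADCA")) {
  if (ensemble$M < 2) abort("Ensemble must have M >= 2 rounds.")
  years <- years %||% sort(unique(population$year))
  rec <- ensemble$records |>
    mutate(age_group = age_to_group(.data$age_dx), year = .data$year_dx)
  keep_years <- rec$year %in% years

  per_round <- purrr::map_dfr(seq_len(ensemble$M), function(m) {
    cls <- factor(ensemble$levels[ensemble$completed[, m]],
                  levels = ensemble$levels)
    d <- rec[keep_years & cls %in% classes, , drop = FALSE]
    d$class <- factor(as.character(cls[keep_years & cls %in% classes]),
                      levels = classes)
    grid <- tidyr::expand_grid(
      sex = factor(SEX_LEVELS, levels = SEX_LEVELS),
      class = factor(classes, levels = classes), year = years)
    d |>
      count(.data$sex, .data$class, .data$year, .data$age_group) |>
      tidyr::complete(grid, age_group = factor(age_group_levels(),
                                               levels = age_group_levels()),
                      fill = list(n = 0L)) |>
      left_join(population |> select("sex", "age_group", "year",
                                     py = "count"),
                by = c("sex", "age_group", "year")) |>
      left_join(standard, by = "age_group") |>
      group_by(.data$sex, .data$class, .data$year) |>
      summarise(events = sum(.data$n),
                asr = asr(.data$n, .data$py, .data$weight),
                .groups = "drop") |>
      mutate(.round = m)
  })
  per_round |>
    group_by(.data$sex, .data$class, .data$year) |>
    summarise(events = mean(.data$events),
              asr_lo = quantile(.data$asr, 0.025, names = FALSE),
              asr_hi = quantile(.data$asr, 0.975, names = FALSE),
              asr = mean(.data$asr), .groups = "drop") |>
    select("sex", "class", "year", "events", "asr", "asr_lo", "asr_hi")
}
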