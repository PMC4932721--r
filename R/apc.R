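# Age-period-cohort Poisson modelling with natural splines.
#
# The model is log R(a, p) = f(a) + g(p) + h(c) with c = p - a, fitted to
# events and person-years on a Lexis grid. Because f, g, h are only
# identified up to a shared linear trend, the classical residual approach is
# used: an age-period (or age-cohort) model is fitted first and the third
# effect is then estimated from its residuals with a natural spline. The
# drift — the identifiable common log-linear time slope — is extracted from
# the age-drift model (natural-spline age curve plus a linear period term),
# fitted before any residual spline can absorb curvature, and is therefore
# the same number under both identification variants.

#' Tabulate cases and person-years on a Lexis grid
#'
#' Bins one case series (a single sex and class, already filtered by the
#' caller) into age-group x calendar-year cells, attaches person-years from
#' an annual population table, and labels every cell with its birth cohort
#' `c = p - a` (period and age taken at their cell midpoints).
#'
#' @param records Case tibble with `age_dx` and `year_dx`.
#' @param population Annual population for the matching sex: tibble with
#'   `age_group`, `year`, `count` (filter a table from
#'   [interpolate_population()] to one sex first).
#' @param years Calendar-year window (default: years present in
#'   `population`).
#' @return Tibble with one row per cell: `age_group`, `age` (midpoint),
#'   `period` (year midpoint), `cohort`, `events`, `pyears`.
#' @export
build_lexis <- function(records, population, years = NULL) {
  require_columns(records, c("age_dx", "year_dx"), "records")
  require_columns(population, c("age_group", "year", "count"), "population")
  if ("sex" %in% names(population) &&
      length(unique(population$sex)) > 1) {
    abort("`population` spans both sexes; filter to one sex first.")
  }
  years <- sort(years %||% unique(population$year))
  grid <- population |>
    filter(.data$year %in% years) |>
    select("age_group", "year", pyears = "count")
  if (nrow(grid) == 0) abort("Empty Lexis grid: no population cells in window.")
  ev <- records |>
    filter(.data$year_dx %in% years) |>
    mutate(age_group = age_to_group(.data$age_dx)) |>
    count(.data$age_group, year = .data$year_dx, name = "events")
  grid |>
    left_join(ev, by = c("age_group", "year")) |>
    mutate(events = dplyr::coalesce(.data$events, 0L),
           age = age_group_midpoint(.data$age_group),
           period = .data$year + 0.5,
           cohort = .data$period - .data$age) |>
    select("age_group", "age", "period", "cohort", "events", "pyears") |>
    arrange(.data$age, .data$period)
}

#' Fit an age-period-cohort Poisson model
#'
#' Fits the classical APC decomposition to a Lexis grid by maximum
#' likelihood with `log(pyears)` as exposure offset. Two models are kept:
#' the age-drift model (natural-spline age curve plus a linear period slope),
#' whose slope is the drift, and the chosen two-effect model — age-period
#' for variant `"AP-C"`, age-cohort for `"AC-P"` — whose residuals then
#' identify the remaining effect through a natural spline.
#'
#' @param lexis Grid from [build_lexis()].
#' @param df Spline degrees of freedom: named vector/list with `age`,
#'   `period`, `cohort` (defaults 5, 4, 4).
#' @param variant `"AP-C"` (default) or `"AC-P"`.
#' @return An object of class `histmi_apc`: drift with 95% CI, effect curves
#'   (`age_effect` as rates per 100,000 at the reference period,
#'   `period_effect` and `cohort_effect` as rate ratios), the fitted `glm`s,
#'   and the grid.
#' @export
#' @examples
#' cfg <- synthetic_registry_config(n_male = 1500, n_female = 600)
#' reg <- generate_registry(cfg, seed = 5)
#' pop <- interpolate_population(generate_population(cfg), 1989:2013)
#' lex <- build_lexis(dplyr::filter(reg, sex == "male"),
#'                    dplyr::filter(pop, sex == "male"))
#' fit <- fit_apc(lex, df = c(age = 4, period = 3, cohort = 3))
#' drift(fit)
fit_apc <- function(lexis, df = c(age = 5, period = 4, cohort = 4),
                    variant = c("AP-C", "AC-P")) {
  variant <- match.arg(variant)
  require_columns(lexis, c("age", "period", "cohort", "events", "pyears"),
                  "lexis")
  lex <- lexis |> filter(.data$pyears > 0)
  stop_if_empty(lex, "Lexis grid")
  df <- as.list(df)
  for (v in c("age", "period", "cohort")) {
    if (df[[v]] >= dplyr::n_distinct(lex[[v]])) {
      abort(paste0("df$", v, " (", df[[v]], ") must be smaller than the ",
                   "number of distinct ", v, " values (",
                   dplyr::n_distinct(lex[[v]]), ")."))
    }
  }
  p0 <- median(unique(lex$period))
  d <- lex |> mutate(lpy = log(.data$pyears), pc = .data$period - p0)

  drift_fit <- quiet_sparse_glm(
    glm(events ~ splines::ns(age, df = df$age) + pc,
        family = poisson(), data = d, offset = lpy,
        control = stats::glm.control(maxit = 100)))
  if (!drift_fit$converged) abort("Age-drift model did not converge.")
  delta <- coef(drift_fit)[["pc"]]
  se <- sqrt(diag(vcov(drift_fit)))[["pc"]]

  second <- if (variant == "AP-C") "period" else "cohort"
  third <- if (variant == "AP-C") "cohort" else "period"
  form2 <- stats::as.formula(paste0(
    "events ~ splines::ns(age, df = ", df$age, ") + splines::ns(", second,
    ", df = ", df[[second]], ")"))
  fit2 <- quiet_sparse_glm(glm(form2, family = poisson(), data = d,
                               offset = lpy,
                               control = stats::glm.control(maxit = 100)))
  if (!fit2$converged) abort("Two-effect model did not converge.")

  # Residual identification of the third effect: a natural-spline Poisson
  # fit with the two-effect fitted values as offset.
  d$lfit2 <- log(fitted(fit2))
  form3 <- stats::as.formula(paste0(
    "events ~ splines::ns(", third, ", df = ", df[[third]], ")"))
  fit3 <- quiet_sparse_glm(glm(form3, family = poisson(), data = d,
                               offset = lfit2,
                               control = stats::glm.control(maxit = 100)))
  if (!fit3$converged) abort("Residual model did not converge.")

  # Effect curves. Age curve: rate per 100,000 at the reference period
  # (second effect at its median observed value).
  ref2 <- median(unique(d[[second]]))
  ages <- sort(unique(d$age))
  nd_age <- tibble(age = ages, lpy = 0)
  nd_age[[second]] <- ref2
  age_effect <- tibble(
    age = ages,
    rate = unname(1e5 * exp(predict(fit2, newdata = nd_age))))
  vals2 <- sort(unique(d[[second]]))
  nd2 <- tibble(age = median(ages), lpy = 0)
  nd2 <- nd2[rep(1, length(vals2)), ]
  nd2[[second]] <- vals2
  eta2 <- unname(predict(fit2, newdata = nd2))
  ref_row <- which(vals2 == ref2)[1]
  second_effect <- tibble(value = vals2, rr = exp(eta2 - eta2[ref_row]))
  vals3 <- sort(unique(d[[third]]))
  nd3 <- tibble(lfit2 = 0)
  nd3 <- nd3[rep(1, length(vals3)), , drop = FALSE]
  nd3[[third]] <- vals3
  eta3 <- unname(predict(fit3, newdata = nd3))
  third_effect <- tibble(value = vals3, rr = exp(eta3 - mean(eta3)))

  effects <- list(age_effect = age_effect)
  effects[[paste0(second, "_effect")]] <- second_effect
  effects[[paste0(third, "_effect")]] <- third_effect

  structure(list(
    variant = variant, df = df, lexis = lex, reference_period = p0,
    drift_log = delta, drift_se = se,
    drift_pct = 100 * (exp(delta) - 1),
    drift_ci = 100 * (exp(delta + c(-1, 1) * qnorm(0.975) * se) - 1),
    effects = effects,
    models = list(drift = drift_fit, two_effect = fit2, residual = fit3),
    deviance = fit2$deviance
  ), class = "histmi_apc")
}

#' Drift of an APC fit
#'
#' The identifiable common log-linear time slope shared by period and
#' cohort, reported as annual percent change with a Wald 95% CI computed on
#' the log scale and transformed.
#'
#' @param fit A `histmi_apc` object.
#' @return One-row tibble: `drift_pct`, `ci_lo`, `ci_hi`, `log_slope`, `se`.
#' @export
drift <- function(fit) {
  stopifnot(inherits(fit, "histmi_apc"))
  tibble(drift_pct = fit$drift_pct, ci_lo = fit$drift_ci[1],
         ci_hi = fit$drift_ci[2], log_slope = fit$drift_log,
         se = fit$drift_se)
}

#' Pooled drift over an imputation ensemble
#'
#' Fits the age-drift model to every completed dataset of the ensemble (for
#' one sex and collapsed class) and pools the annual-percent-change drift by
#' mean and 2.5th/97.5th percentiles, consistently with the count-pooling
#' rule.
#'
#' @param ensemble A `histmi_ensemble`.
#' @param population Annual population from [interpolate_population()].
#' @param sex,class The series to fit.
#' @param years Calendar-year window.
#' @param df_age Age-spline degrees of freedom.
#' @return One-row tibble: `sex`, `class`, `drift_pct`, `pi_lo`, `pi_hi`.
#' @export
drift_ensemble <- function(ensemble, population, sex, class, years = NULL,
                           df_age = 5) {
  pop <- population |> filter(.data$sex == !!sex)
  years <- sort(years %||% unique(pop$year))
  sel_sex <- ensemble$records$sex == sex
  drifts <- vapply(seq_len(ensemble$M), function(m) {
    cls <- ensemble$levels[ensemble$completed[, m]]
    rec <- ensemble$records[sel_sex & cls == class, , drop = FALSE]
    lex <- build_lexis(rec, pop, years = years)
    d <- lex |> filter(.data$pyears > 0) |>
      mutate(pc = .data$period - median(unique(.data$period)),
             lpy = log(.data$pyears))
    fit <- quiet_sparse_glm(
      glm(events ~ splines::ns(age, df = df_age) + pc,
          family = poisson(), data = d, offset = lpy,
          control = stats::glm.control(maxit = 100)))
    coef(fit)[["pc"]]
  }, numeric(1))
  tibble(sex = sex, class = class,
         drift_pct = mean(100 * (exp(drifts) - 1)),
         pi_lo = quantile(100 * (exp(drifts) - 1), 0.025, names = FALSE),
         pi_hi = quantile(100 * (exp(drifts) - 1), 0.975, names = FALSE))
}

#' @export
print.histmi_apc <- function(x, ...) {
  cat(sprintf("APC Poisson fit (%s), df age/period/cohort = %s/%s/%s\n",
              x$variant, x$df$age, x$df$period, x$df$cohort))
  cat(sprintf("Drift: %.2f%% per year (95%% CI %.2f, %.2f)\n",
              x$drift_pct, x$drift_ci[1], x$drift_ci[2]))
  invisible(x)
}

#' @describeIn fit_apc Tidy the effect curves: one row per effect x value,
#'   with the age curve as a rate per 100,000 and period/cohort as rate
#'   ratios.
#' @param x A `histmi_apc` fit.
#' @param ... Unused.
#' @export
tidy.histmi_apc <- function(x, ...) {
  bind_rows(
    x$effects$age_effect |>
      mutate(effect = "age", value = .data$age, estimate = .data$rate) |>
      select("effect", "value", "estimate"),
    purrr::map_dfr(c("period", "cohort"), function(e) {
      eff <- x$effects[[paste0(e, "_effect")]]
      if (is.null(eff)) return(NULL)
      tibble(effect = e, value = eff$value, estimate = eff$rr)
    })
  )
}

#' @describeIn fit_apc One-row fit summary with drift and deviance.
#' @export
glance.histmi_apc <- function(x, ...) {
  tibble(variant = x$variant, drift_pct = x$drift_pct,
         ci_lo = x$drift_ci[1], ci_hi = x$drift_ci[2],
         deviance = x$deviance, n_cells = nrow(x$lexis),
         events = sum(x$lexis$events))
}
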