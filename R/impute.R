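# Two-step multiple imputation of histology class and percentile pooling.
#
# Step 1 imputes UNKNOWN cases into the five known categories (including
# NSCC-NOS) from a polytomous model fitted to all cases with known histology.
# Step 2 imputes every NSCC-NOS case — originally coded or assigned in step 1
# — into the four specific categories from a model fitted to cases with a
# specific class. The completed six-class data are collapsed to SCC / ADCA /
# OTHER for reporting. The whole procedure is repeated M times; counts and
# percentages are pooled as the mean over rounds with 95% probability
# intervals from the empirical 2.5th/97.5th percentiles.

#' Two-step multiple imputation of histology
#'
#' Runs `M` rounds of the two-step Bayesian polytomous-regression imputation.
#' Because histology is the only incomplete variable, the conditional models
#' are fitted once (to the observed data) and each round differs only in the
#' posterior coefficient draw and the categorical sampling; with
#' `step2_training = "include_step1"` the step-2 model is instead refitted
#' each round on the specific-class cases as completed by step 1.
#'
#' @param records Case tibble with a six-class `histology` column (e.g. from
#'   [read_registry()] or [generate_registry()]).
#' @param M Number of imputation rounds (default 200; at least 2, or no
#'   interval is estimable).
#' @param seed Master seed; per-round sub-streams are derived from it.
#' @param predictors Predictor set for both conditional models.
#' @param district_coding How a `district` predictor enters the models:
#'   `"muang"` (default) dichotomises it as `reference_district` versus all
#'   others — the form in which the registry's own fitted model reports the
#'   district effect, and much better identified when many districts hold
#'   only a handful of cases per class — or `"full"`, the saturated
#'   district factor.
#' @param reference_district District treated as the reference ("old town")
#'   under `district_coding = "muang"`.
#' @param reference Reference class (default `"SCC"`).
#' @param step2_training `"observed"` (default): step 2 trains on cases with
#'   an originally specific class; `"include_step1"`: also on step-1-imputed
#'   specific cases, refitting each round.
#' @param augment,augment_total Perfect-prediction augmentation, passed to
#'   [fit_polytomous()].
#' @param max_retries Rounds failing (e.g. a non-finite draw) are retried
#'   with a fresh sub-stream up to this many times before a hard error.
#' @return An object of class `histmi_ensemble`: the input records, an
#'   `n x M` matrix of completed collapsed classes, the fitted step models,
#'   and bookkeeping (`masked` marks the originally unknown-histology group,
#'   i.e. UNKNOWN plus NSCC-NOS).
#' @export
#' @examples
#' reg <- generate_registry(synthetic_registry_config(n_male = 400,
#'                                                    n_female = 200), seed = 3)
#' ens <- two_step_impute(reg, M = 5, seed = 42,
#'                        predictors = c("sex", "age_dx"))
#' pool_ensemble(ens, by = "sex")
two_step_impute <- function(records, M = 200, seed = 1,
                            predictors = c("sex", "age_dx", "year_dx",
                                           "district"),
                            district_coding = c("muang", "full"),
                            reference_district = "Muang Songkhla",
                            reference = "SCC",
                            step2_training = c("observed", "include_step1"),
                            augment = TRUE, augment_total = 0.01,
                            max_retries = 3) {
  stop_if_empty(records, "case table")
  require_columns(records, c("histology", predictors), "records")
  if (M < 2) abort("M must be at least 2: no interval is estimable from one round.")
  step2_training <- match.arg(step2_training)
  district_coding <- match.arg(district_coding)
  if ("district" %in% predictors && district_coding == "muang") {
    if (!reference_district %in% as.character(records$district)) {
      abort(paste0("reference_district '", reference_district,
                   "' not present; use district_coding = 'full' or set ",
                   "reference_district."))
    }
    records$.district_bin <- factor(
      ifelse(as.character(records$district) == reference_district,
             "reference", "other"), levels = c("reference", "other"))
    predictors[predictors == "district"] <- ".district_bin"
  }

  h <- factor(as.character(records$histology), levels = HISTOLOGY_LEVELS)
  if (anyNA(h)) abort("records$histology contains values outside the six-class scheme.")
  is_unknown <- h == "UNKNOWN"
  is_nscc <- h == "NSCC_NOS"
  is_specific <- !is_unknown & !is_nscc

  fit_step <- function(rows, levels_wanted) {
    d <- records[rows, , drop = FALSE]
    d$.histology <- droplevels(factor(as.character(h[rows]),
                                      levels = levels_wanted))
    ref <- if (reference %in% levels(d$.histology)) reference else NULL
    fit_polytomous(d, ".histology", predictors = predictors, reference = ref,
                   augment = augment, augment_total = augment_total)
  }

  model1 <- if (any(is_unknown)) {
    fit_step(which(!is_unknown), setdiff(HISTOLOGY_LEVELS, "UNKNOWN"))
  } else NULL
  need_step2 <- any(is_nscc) ||
    (!is.null(model1) && "NSCC_NOS" %in% model1$classes)
  model2 <- if (need_step2 && step2_training == "observed") {
    fit_step(which(is_specific), SPECIFIC_LEVELS)
  } else NULL

  round_seeds <- spawn_seeds(seed, M)
  n <- nrow(records)
  completed <- matrix(NA_integer_, nrow = n, ncol = M)

  for (m in seq_len(M)) {
    res <- NULL
    for (attempt in seq_len(max_retries)) {
      res <- tryCatch({
        set.seed(round_seeds[m] + (attempt - 1L) * 7919L)
        h_m <- as.character(h)
        if (any(is_unknown)) {
          h_m[is_unknown] <- as.character(
            draw_and_impute(model1, records[is_unknown, , drop = FALSE]))
        }
        nscc_now <- h_m == "NSCC_NOS"
        if (any(nscc_now)) {
          m2 <- if (step2_training == "include_step1") {
            d2 <- records[!nscc_now, , drop = FALSE]
            d2$.histology <- factor(h_m[!nscc_now], levels = SPECIFIC_LEVELS)
            ref2 <- if (reference %in% as.character(d2$.histology)) reference else NULL
            fit_polytomous(d2, ".histology", predictors = predictors,
                           reference = ref2, augment = augment,
                           augment_total = augment_total)
          } else model2
          h_m[nscc_now] <- as.character(
            draw_and_impute(m2, records[nscc_now, , drop = FALSE]))
        }
        as.integer(collapse_histology(h_m))
      }, error = function(e) e)
      if (!inherits(res, "error")) break
    }
    if (inherits(res, "error")) {
      abort(paste0("Imputation round ", m, " failed after ", max_retries,
                   " attempts: ", conditionMessage(res)))
    }
    completed[, m] <- res
  }

  structure(list(
    records = as_tibble(records), completed = completed,
    levels = COLLAPSED_LEVELS, M = as.integer(M), seed = as.integer(seed),
    masked = is_unknown | is_nscc, originally_unknown = is_unknown,
    originally_nscc = is_nscc,
    models = list(step1 = model1, step2 = model2),
    predictors = predictors, step2_training = step2_training
  ), class = "histmi_ensemble")
}

#' @export
print.histmi_ensemble <- function(x, ...) {
  cat(sprintf(paste0("Imputation ensemble: %d cases, M = %d rounds ",
                     "(%d UNKNOWN, %d NSCC-NOS imputed)\n"),
              nrow(x$records), x$M, sum(x$originally_unknown),
              sum(x$originally_nscc)))
  invisible(x)
}

#' Completed datasets of an ensemble
#'
#' @param ensemble A `histmi_ensemble`.
#' @param rounds Which rounds to return (default all).
#' @return Long tibble: the input records repeated per round with columns
#'   `.round` and `.class` (the completed collapsed class).
#' @export
completed_datasets <- function(ensemble, rounds = seq_len(ensemble$M)) {
  purrr::map_dfr(rounds, function(m) {
    d <- ensemble$records
    d$.round <- m
    d$.class <- factor(ensemble$levels[ensemble$completed[, m]],
                       levels = ensemble$levels)
    d
  })
}

ensemble_subset_index <- function(ensemble, among) {
  switch(among,
    imputed = which(ensemble$masked),
    known = which(!ensemble$masked),
    all = seq_len(nrow(ensemble$records)),
    abort("`among` must be one of 'imputed', 'known', 'all'."))
}

#' Pool counts and percentages over an imputation ensemble
#'
#' For each stratum and collapsed class, computes the class count in every
#' completed dataset and pools: point estimate = mean over the M rounds, 95%
#' probability interval = empirical 2.5th/97.5th percentiles. Percentages are
#' computed within stratum and round before pooling, so they sum to 100 in
#' every round.
#'
#' @param ensemble A `histmi_ensemble`.
#' @param by Character vector of stratifying record columns (e.g. `"sex"`);
#'   `NULL` for overall.
#' @param among Which cases to tabulate: `"imputed"` (the originally
#'   unknown-histology group: UNKNOWN + NSCC-NOS — the group the published
#'   imputed tables describe), `"known"`, or `"all"`.
#' @return Tibble with one row per stratum x class: `count`, `count_lo`,
#'   `count_hi`, `pct`, `pct_lo`, `pct_hi`.
#' @export
pool_ensemble <- function(ensemble, by = "sex", among = "imputed") {
  if (!is.null(by)) {
    bad <- setdiff(by, names(ensemble$records))
    if (length(bad) > 0) {
      abort(paste0("Stratifier(s) not present in the records: ",
                   paste(bad, collapse = ", ")))
    }
  }
  idx <- ensemble_subset_index(ensemble, among)
  if (length(idx) == 0) {
    empty <- tibble(class = factor(character(), levels = ensemble$levels),
                    count = numeric(), count_lo = numeric(),
                    count_hi = numeric(), pct = numeric(),
                    pct_lo = numeric(), pct_hi = numeric())
    if (!is.null(by)) {
      for (v in rev(by)) {
        empty <- bind_cols(tibble(!!v := ensemble$records[[v]][0]), empty)
      }
    }
    return(empty)
  }
  strata <- if (is.null(by)) {
    tibble(.stratum = rep(1L, length(idx)))
  } else {
    d <- ensemble$records[idx, by, drop = FALSE]
    d$.stratum <- as.integer(interaction(d, drop = FALSE, lex.order = TRUE))
    d
  }
  K <- length(ensemble$levels)
  sub <- ensemble$completed[idx, , drop = FALSE]
  levs <- sort(unique(strata$.stratum))

  per_round <- purrr::map_dfr(seq_len(ensemble$M), function(m) {
    cnt <- table(factor(strata$.stratum, levels = levs),
                 factor(sub[, m], levels = seq_len(K)))
    out <- as_tibble(as.data.frame(cnt, stringsAsFactors = FALSE))
    names(out) <- c(".stratum", ".class_idx", "n")
    out$.stratum <- as.integer(out$.stratum)
    out$.round <- m
    out
  })
  per_round <- per_round |>
    group_by(.data$.round, .data$.stratum) |>
    mutate(pct = if (sum(.data$n) > 0) 100 * .data$n / sum(.data$n)
           else NA_real_) |>
    ungroup()

  pooled <- per_round |>
    group_by(.data$.stratum, .data$.class_idx) |>
    summarise(
      count_lo = quantile(.data$n, 0.025, names = FALSE),
      count_hi = quantile(.data$n, 0.975, names = FALSE),
      count = mean(.data$n),
      pct_lo = quantile(.data$pct, 0.025, names = FALSE),
      pct_hi = quantile(.data$pct, 0.975, names = FALSE),
      pct = mean(.data$pct),
      .groups = "drop"
    ) |>
    mutate(class = factor(ensemble$levels[as.integer(.data$.class_idx)],
                          levels = ensemble$levels))
  if (!is.null(by)) {
    key <- strata |> distinct(across(all_of(c(by, ".stratum"))))
    pooled <- left_join(pooled, key, by = ".stratum")
  }
  pooled |>
    select(all_of(if (is.null(by)) character() else by), "class", "count",
           "count_lo", "count_hi", "pct", "pct_lo", "pct_hi") |>
    arrange(across(all_of(if (is.null(by)) "class" else c(by, "class"))))
}

#' Compare known-histology and pooled imputed class distributions
#'
#' Chi-square test of homogeneity, per stratum, between the collapsed class
#' distribution of cases with an originally specific histology and the pooled
#' (mean over rounds) imputed distribution of the originally unknown group —
#' the check the published imputed tables report. Distributions exactly
#' proportional give statistic 0, p = 1.
#'
#' @param ensemble A `histmi_ensemble`.
#' @param by Stratifier (default `"sex"`); `NULL` for overall.
#' @return Tibble with one row per stratum: `statistic`, `p_value`, the two
#'   sets of class counts (list-columns), and a `note` flagging empty strata.
#' @export
compare_known_vs_imputed <- function(ensemble, by = "sex") {
  known <- pool_ensemble(ensemble, by = by, among = "known")
  imput <- pool_ensemble(ensemble, by = by, among = "imputed")
  groups <- if (is.null(by)) tibble(.dummy = 1) else
    distinct(ensemble$records[, by, drop = FALSE])
  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    pick <- function(tab) {
      if (is.null(by)) return(tab)
      sel <- rep(TRUE, nrow(tab))
      for (v in by) sel <- sel & tab[[v]] == groups[[v]][i]
      tab[sel, , drop = FALSE]
    }
    K <- length(ensemble$levels)
    k <- pick(known)$count
    u <- pick(imput)$count
    if (length(k) == 0) k <- rep(0, K)
    if (length(u) == 0) u <- rep(0, K)
    res <- tibble(statistic = NA_real_, p_value = NA_real_,
                  note = NA_character_)
    if (sum(k) == 0 || sum(u) == 0) {
      res$note <- "not applicable: empty stratum"
    } else {
      keep <- k + u > 0
      ct <- suppressWarnings(chisq.test(rbind(k[keep], u[keep]),
                                        correct = FALSE))
      res$statistic <- unname(ct$statistic)
      res$p_value <- ct$p.value
    }
    res$known_counts <- list(setNames(k, ensemble$levels))
    res$imputed_counts <- list(setNames(u, ensemble$levels))
    bind_cols(if (is.null(by)) NULL else groups[i, , drop = FALSE], res)
  })
}

#' @describeIn two_step_impute Tidy the pooled ensemble (equivalent to
#'   [pool_ensemble()] by sex among the imputed group).
#' @param x A `histmi_ensemble`.
#' @param ... Passed to [pool_ensemble()].
#' @export
tidy.histmi_ensemble <- function(x, ...) {
  pool_ensemble(x, ...)
}

#' @describeIn two_step_impute One-row ensemble summary.
#' @export
glance.histmi_ensemble <- function(x, ...) {
  tibble(n = nrow(x$records), M = x$M,
         n_unknown = sum(x$originally_unknown),
         n_nscc = sum(x$originally_nscc),
         seed = x$seed, step2_training = x$step2_training)
}
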