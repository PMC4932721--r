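# Case-file input/output and descriptive tabulations.

SEX_LEVELS <- c("male", "female")
RELIGION_LEVELS <- c("buddhist_other", "muslim")

REGISTRY_FILE_COLUMNS <- c("sex", "age", "year", "religion", "district",
                           "morphology")

#' Read a unit-record cancer-registry case file
#'
#' Reads a delimited text file with one row per case and columns `sex`,
#' `age`, `year`, `religion`, `district`, `morphology`, validates every row,
#' and derives the six-class histology from the ICD-O morphology code.
#' Malformed rows are never silently dropped: they are collected, with their
#' line numbers and the reason, in the `rejects` attribute of the result
#' (retrievable with [registry_rejects()]).
#'
#' @param path Path to the case file.
#' @param delim Field delimiter (default `","`).
#' @param year_range Accepted diagnosis-year window, default `c(1989, 2013)`.
#' @param morphology_table ICD-O lookup passed to [classify_morphology()].
#' @return A tibble of validated cases with columns `sex`, `age_dx`,
#'   `year_dx`, `religion`, `district`, `morphology`, `histology`.
#' @export
read_registry <- function(path, delim = ",", year_range = c(1989, 2013),
                          morphology_table = icdo_histology_table()) {
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  missing <- setdiff(REGISTRY_FILE_COLUMNS, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Case file ", path, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  n <- nrow(raw)
  reason <- rep(NA_character_, n)
  note <- function(bad, why) {
    reason[bad & is.na(reason)] <<- why
  }

  sex <- trimws(tolower(raw$sex))
  note(!sex %in% SEX_LEVELS, "invalid sex")
  age <- suppressWarnings(as.numeric(raw$age))
  note(is.na(age) | age < 0 | age > 120 | age != floor(age), "invalid age")
  year <- suppressWarnings(as.numeric(raw$year))
  note(is.na(year) | year != floor(year) |
         year < year_range[1] | year > year_range[2],
       "year outside registry period")
  religion <- trimws(tolower(raw$religion))
  note(!religion %in% RELIGION_LEVELS, "invalid religion")
  district <- trimws(raw$district)
  note(is.na(district) | district == "", "missing district")
  morph <- trimws(raw$morphology)
  morph_ok <- grepl("^[0-9]{4}/3$", morph) & !is.na(morph)
  note(!morph_ok, "malformed morphology code")

  keep <- is.na(reason)
  cases <- tibble(
    sex = factor(sex[keep], levels = SEX_LEVELS),
    age_dx = as.integer(age[keep]),
    year_dx = as.integer(year[keep]),
    religion = factor(religion[keep], levels = RELIGION_LEVELS),
    district = factor(district[keep]),
    morphology = morph[keep]
  )
  cases$histology <- classify_morphology(cases$morphology, morphology_table)
  rejects <- tibble(
    line = which(!keep) + 1L,  # +1 for the header line
    reason = reason[!keep]
  )
  if (nrow(rejects) > 0) {
    warn(paste0(nrow(rejects), " row(s) of ", n, " rejected while reading ",
                path, "; see registry_rejects()."))
  }
  attr(cases, "rejects") <- rejects
  cases
}

#' @rdname read_registry
#' @param records A tibble returned by [read_registry()].
#' @export
registry_rejects <- function(records) {
  attr(records, "rejects") %||% tibble(line = integer(), reason = character())
}

#' Write a case file in the registry dialect
#'
#' Writes the observed columns (`sex`, `age`, `year`, `religion`, `district`,
#' `morphology`) so that [read_registry()] round-trips all fields. Truth
#' columns from the synthetic generator are intentionally not written; use
#' [write_truth()] for those.
#'
#' @param records Case tibble with the columns produced by [read_registry()]
#'   or [generate_registry()].
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path, delim = ",") {
  require_columns(records, c("sex", "age_dx", "year_dx", "religion",
                             "district", "morphology"), "records")
  out <- tibble(
    sex = as.character(records$sex),
    age = records$age_dx,
    year = records$year_dx,
    religion = as.character(records$religion),
    district = as.character(records$district),
    morphology = records$morphology
  )
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Descriptive tabulation of registry cases
#'
#' Cross-tabulates one case characteristic against another (by default sex),
#' in the layout registries publish: counts with column-wise percentages and
#' a chi-square test of homogeneity. When `row_var` is `age_dx` the table
#' reports mean and standard deviation per column and a Wilcoxon rank-sum
#' test instead.
#'
#' @param records Case tibble.
#' @param row_var Name of the characteristic tabulated down the rows.
#' @param col_var Name of the column variable (default `"sex"`).
#' @return For categorical `row_var`, a tibble with one row per
#'   `col_var` level x `row_var` level holding `n` and `pct` (column
#'   percentage), of class `histmi_tabulation`; the test is stored in the
#'   `test` attribute and shown by `print()`. For `age_dx`, a tibble of
#'   per-column mean/sd with a Wilcoxon test attribute.
#' @export
#' @examples
#' reg <- generate_registry(synthetic_registry_config(n_male = 200,
#'                                                    n_female = 100), seed = 1)
#' tabulate_cases(reg, "histology")
tabulate_cases <- function(records, row_var, col_var = "sex") {
  stop_if_empty(records, "case table")
  require_columns(records, c(row_var, col_var), "records")

  if (row_var == "age_dx") {
    out <- records |>
      group_by(across(all_of(col_var))) |>
      summarise(n = n(), mean = mean(.data$age_dx), sd = sd(.data$age_dx),
                .groups = "drop")
    groups <- split(records$age_dx, records[[col_var]], drop = TRUE)
    test <- if (length(groups) == 2) {
      wt <- suppressWarnings(wilcox.test(groups[[1]], groups[[2]]))
      list(method = "Wilcoxon rank sum test",
           statistic = unname(wt$statistic), p_value = wt$p.value)
    } else {
      list(method = "Wilcoxon rank sum test", statistic = NA_real_,
           p_value = NA_real_, note = "requires exactly two columns")
    }
    attr(out, "test") <- test
    class(out) <- c("histmi_tabulation", class(out))
    return(out)
  }

  counts <- records |>
    count(across(all_of(c(col_var, row_var)))) |>
    tidyr::complete(!!rlang::sym(col_var), !!rlang::sym(row_var),
                    fill = list(n = 0L)) |>
    group_by(across(all_of(col_var))) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup() |>
    filter(!is.na(.data$pct))

  tab <- tapply(counts$n, list(counts[[row_var]], counts[[col_var]]), sum)
  tab <- tab[rowSums(tab, na.rm = TRUE) > 0, , drop = FALSE]
  test <- if (nrow(tab) < 2 || ncol(tab) < 2) {
    list(method = "Chi-square test", statistic = NA_real_,
         p_value = NA_real_, note = "not applicable (single row or column)")
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    list(method = "Chi-square test", statistic = unname(ct$statistic),
         p_value = ct$p.value, df = unname(ct$parameter))
  }
  attr(counts, "test") <- test
  class(counts) <- c("histmi_tabulation", class(counts))
  counts
}

#' @export
print.histmi_tabulation <- function(x, ...) {
  NextMethod()
  test <- attr(x, "test")
  if (!is.null(test)) {
    p <- if (is.na(test$p_value)) test$note %||% "NA" else
      format.pval(test$p_value, digits = 3)
    cat(sprintf("%s: statistic = %s, p = %s\n", test$method,
                format(test$statistic, digits = 4), p))
  }
  invisible(x)
}

#' @rdname tabulate_cases
#' @param tabulation A `histmi_tabulation`.
#' @export
tabulation_test <- function(tabulation) {
  attr(tabulation, "test")
}
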