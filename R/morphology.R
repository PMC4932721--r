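# ICD-O morphology grouping into the six registry histology classes.

HISTOLOGY_LEVELS <- c("SCC", "ADCA", "LARGE_CELL", "NSCC_NOS", "OTHER_KNOWN",
                      "UNKNOWN")
COLLAPSED_LEVELS <- c("SCC", "ADCA", "OTHER")

#' Histology class levels
#'
#' `histology_levels()` returns the six-class scheme used by the registry
#' (squamous cell carcinoma, adenocarcinoma, large cell carcinoma,
#' non-small-cell carcinoma NOS, other known histology, unknown histology);
#' `collapsed_levels()` returns the three-class reporting scheme used after
#' imputation.
#'
#' @return Character vector of class labels.
#' @export
histology_levels <- function() HISTOLOGY_LEVELS

#' @rdname histology_levels
#' @export
collapsed_levels <- function() COLLAPSED_LEVELS

#' ICD-O-3 morphology lookup table
#'
#' The code ranges that define the six histology classes. Unknown histology is
#' 8000/3-8011/3, large cell carcinoma 8012/3-8014/3 and NSCC-NOS 8046/3 as
#' used by the registry; the squamous (8050-8089) and adenocarcinoma
#' (8140-8389 plus the cystic/mucinous 8440-8490, acinar 8550-8551 and
#' 8570-8576 families) ranges follow ICD-O-3 coding convention. Any other
#' valid malignant code is "other known histology". The table is ordinary
#' data, so a registry with local coding practice can edit it and pass the
#' result to [classify_morphology()].
#'
#' @return A tibble with columns `from`, `to` (inclusive 4-digit code bounds)
#'   and `class`.
#' @export
#' @examples
#' icdo_histology_table()
icdo_histology_table <- function() {
  tibble(
    from  = c(8000L, 8012L, 8046L, 8050L, 8140L, 8440L, 8550L, 8570L),
    to    = c(8011L, 8014L, 8046L, 8089L, 8389L, 8490L, 8551L, 8576L),
    class = c("UNKNOWN", "LARGE_CELL", "NSCC_NOS", "SCC", "ADCA", "ADCA",
              "ADCA", "ADCA")
  )
}

#' Classify ICD-O morphology codes into histology classes
#'
#' Maps morphology/behaviour code strings of the form `"NNNN/3"` to the
#' six-class histology scheme. The mapping is a partition: every valid
#' malignant code receives exactly one class, with codes outside the ranges in
#' `table` assigned to `OTHER_KNOWN`.
#'
#' @param code Character vector of ICD-O morphology codes, e.g. `"8046/3"`.
#' @param table Lookup table of code ranges; defaults to
#'   [icdo_histology_table()].
#' @return Factor with levels [histology_levels()].
#' @export
#' @examples
#' classify_morphology(c("8046/3", "8000/3", "8070/3", "8140/3"))
classify_morphology <- function(code, table = icdo_histology_table()) {
  code <- as.character(code)
  ok <- grepl("^[0-9]{4}/[0-9]$", code)
  if (any(!ok | is.na(code))) {
    bad <- unique(code[!ok | is.na(code)])
    abort(paste0("Malformed ICD-O morphology code(s): ",
                 paste(utils::head(bad, 5), collapse = ", "),
                 ". Expected the form NNNN/B, e.g. \"8046/3\"."))
  }
  behaviour <- substr(code, 6, 6)
  if (any(behaviour != "3")) {
    bad <- unique(code[behaviour != "3"])
    abort(paste0("Non-malignant behaviour digit in code(s): ",
                 paste(utils::head(bad, 5), collapse = ", "),
                 ". Only behaviour /3 is accepted."))
  }
  num <- as.integer(substr(code, 1, 4))
  out <- rep("OTHER_KNOWN", length(code))
  for (i in seq_len(nrow(table))) {
    hit <- num >= table$from[i] & num <= table$to[i]
    out[hit] <- table$class[i]
  }
  factor(out, levels = HISTOLOGY_LEVELS)
}

#' Collapse histology classes for post-imputation reporting
#'
#' Maps the specific classes to the three-class reporting scheme: SCC and
#' ADCA are kept, large cell carcinoma and other known histology become
#' `OTHER`. `UNKNOWN` and `NSCC_NOS` have no collapsed form: by default they
#' raise an error (they should have been imputed away first); with
#' `strict = FALSE` they become `NA`.
#'
#' @param histology Factor or character vector in the six-class scheme.
#' @param strict Error on `UNKNOWN`/`NSCC_NOS` input (default) rather than
#'   returning `NA`.
#' @return Factor with levels [collapsed_levels()].
#' @export
#' @examples
#' collapse_histology(c("SCC", "LARGE_CELL", "OTHER_KNOWN"))
collapse_histology <- function(histology, strict = TRUE) {
  histology <- as.character(histology)
  bad <- setdiff(unique(histology), HISTOLOGY_LEVELS)
  if (length(bad) > 0) {
    abort(paste0("Unrecognised histology class(es): ",
                 paste(bad, collapse = ", ")))
  }
  unresolved <- histology %in% c("UNKNOWN", "NSCC_NOS")
  if (strict && any(unresolved)) {
    abort(paste0(sum(unresolved), " case(s) are UNKNOWN or NSCC_NOS; ",
                 "impute them before collapsing, or use strict = FALSE."))
  }
  out <- dplyr::case_match(
    histology,
    "SCC" ~ "SCC",
    "ADCA" ~ "ADCA",
    c("LARGE_CELL", "OTHER_KNOWN") ~ "OTHER",
    .default = NA_character_
  )
  factor(out, levels = COLLAPSED_LEVELS)
}
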