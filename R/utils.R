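# Internal helpers shared across modules.

#' Five-year age groups used throughout the package
#'
#' The conventional eighteen 5-year age groups 0-4, 5-9, ..., 80-84, 85+ used
#' by the Segi/Doll world standard and by the population tables this package
#' consumes.
#'
#' @return Character vector of the 18 age-group labels, youngest first.
#' @export
#' @examples
#' age_group_levels()
age_group_levels <- function() {
  c(paste(seq(0, 80, by = 5), seq(4, 84, by = 5), sep = "-"), "85+")
}

#' Assign ages to 5-year age groups
#'
#' @param age Numeric vector of ages in completed years.
#' @return Factor with levels [age_group_levels()].
#' @export
#' @examples
#' age_to_group(c(0, 37, 85, 99))
age_to_group <- function(age) {
  if (any(!is.finite(age) | age < 0)) {
    abort("`age` must be finite and non-negative.")
  }
  idx <- pmin(floor(age / 5) + 1L, 18L)
  factor(age_group_levels()[idx], levels = age_group_levels())
}

#' Midpoint of a 5-year age-group label
#'
#' The representative age of each group used on Lexis grids; the open-ended
#' `"85+"` group is treated as 85-89 (midpoint 87.5).
#'
#' @param group Character or factor vector of [age_group_levels()] labels.
#' @return Numeric vector of midpoints.
#' @export
#' @examples
#' age_group_midpoint(c("60-64", "85+"))
age_group_midpoint <- function(group) {
  lower <- 5 * (match(as.character(group), age_group_levels()) - 1L)
  lower + 2.5
}

# Row-wise softmax with an implicit reference column of zeros appended first.
# eta: n x (K-1) matrix of linear predictors for the non-reference classes.
# Returns n x K matrix of probabilities, reference class in column 1.
softmax_ref <- function(eta) {
  eta_full <- cbind(0, eta)
  m <- apply(eta_full, 1L, max)
  ex <- exp(eta_full - m)
  ex / rowSums(ex)
}

# One draw per row from the categorical distribution given by probability
# matrix `p` (rows sum to 1). Returns integer column indices.
sample_categorical <- function(p) {
  cp <- t(apply(p, 1L, cumsum))
  u <- runif(nrow(p))
  max.col(u < cp, ties.method = "first")
}

# Cholesky factor with a small ridge fallback; errors if the matrix cannot be
# made positive definite with a negligible ridge.
chol_psd <- function(v, label = "covariance matrix") {
  ridge <- c(0, 10^(-10:-6)) * mean(diag(v))
  for (r in ridge) {
    out <- tryCatch(chol(v + diag(r, nrow(v))), error = function(e) NULL)
    if (!is.null(out)) return(out)
  }
  abort(paste0("The ", label, " is not positive semi-definite, even after ",
               "adding a negligible ridge."))
}

# Derive `n` reproducible sub-seeds (< 2^31) from a master seed without
# disturbing the caller's RNG stream beyond the call itself.
spawn_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Empirical 2.5/97.5 percentile interval.
percentile_interval <- function(x) {
  q <- quantile(x, c(0.025, 0.975), names = FALSE, type = 7)
  list(lo = q[1], hi = q[2])
}

# Poisson fits on sparse Lexis grids routinely produce cells with fitted
# rates indistinguishable from zero (no events, few person-years); that
# warning is expected there, so muffle it and let everything else through.
quiet_sparse_glm <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fitted rates numerically 0", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

stop_if_empty <- function(data, what = "input") {
  if (nrow(data) == 0) abort(paste0("Empty ", what, "."))
  invisible(data)
}

require_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(paste0(what, " is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(data)
}
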