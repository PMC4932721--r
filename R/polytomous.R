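# Polytomous (multinomial logistic) regression with posterior coefficient
# draws — the conditional model behind the imputation of histology class.
#
# The model is log(pi_j(X) / pi_J(X)) = alpha_j + beta_j' X for non-reference
# classes j = 1..J-1. The maximum-likelihood fit and its asymptotic
# coefficient covariance come from nnet::multinom; the "Bayesian" part of the
# imputation is a multivariate-normal draw of the coefficient vector around
# the MLE with that covariance, followed by categorical sampling from the
# resulting class probabilities — so each imputation carries both parameter
# and sampling uncertainty.

#' Fit a polytomous regression model for histology class
#'
#' Fits a multinomial logit of `outcome` on `predictors` by maximum
#' likelihood, storing the coefficient vector, its asymptotic covariance and
#' everything needed to draw coefficients and predict class probabilities on
#' new cases. Continuous predictors are centred internally for numerical
#' stability; reported coefficients stay on the per-unit scale.
#'
#' To avoid the bias that perfect prediction (separation) causes in
#' imputation models, the fit can augment the data with a small set of
#' pseudo-observations: for every level of every categorical predictor, one
#' fractional-weight case per outcome class (continuous predictors at their
#' mean). Each level's pseudo-weight is proportional to the number of real
#' cases carrying that level, so the pull toward uniform class probabilities
#' is at most `augment_total` in every cell — large or small — and total
#' augmentation weight is at most `augment_total` of the real sample. The
#' MLE is perturbed negligibly unless a cell is empty, which is exactly when
#' the pseudo-cases keep the coefficients finite.
#'
#' @param data Case tibble containing `outcome` and `predictors`.
#' @param outcome Name of the class column (factor or character). Every
#'   factor level must occur in the data — a class that cannot be learned
#'   cannot be imputed into — so drop unused levels first.
#' @param predictors Character vector of predictor columns; default
#'   `c("sex", "age_dx", "year_dx", "district")`.
#' @param reference Reference class; default the first level of the outcome.
#' @param augment Apply the perfect-prediction augmentation (default `TRUE`).
#' @param augment_total Pseudo-observation weight as a fraction of the real
#'   cases in each categorical cell (default 0.01); also bounds the total
#'   augmentation as a fraction of the sample.
#' @param maxit Maximum optimiser iterations.
#' @return An object of class `histmi_polytomous`.
#' @export
#' @examples
#' reg <- generate_registry(synthetic_registry_config(n_male = 400,
#'                                                    n_female = 200), seed = 2)
#' obs <- dplyr::filter(reg, histology != "UNKNOWN")
#' fit <- fit_polytomous(obs, "histology",
#'                       predictors = c("sex", "age_dx"), reference = "SCC")
#' head(predict_class_probs(fit, obs))
fit_polytomous <- function(data, outcome = "histology",
                           predictors = c("sex", "age_dx", "year_dx",
                                          "district"),
                           reference = NULL, augment = TRUE,
                           augment_total = 0.01, maxit = 500) {
  stop_if_empty(data, "training data")
  predictors <- predictors %||% character()
  require_columns(data, c(outcome, predictors), "training data")
  y <- data[[outcome]]
  y <- if (is.factor(y)) y else factor(y)
  counts <- table(y)
  if (any(counts == 0)) {
    abort(paste0("Class(es) absent from training data: ",
                 paste(names(counts)[counts == 0], collapse = ", ")))
  }
  if (nlevels(y) < 2) abort("Need at least 2 observed classes to fit.")
  reference <- reference %||% levels(y)[1]
  if (!reference %in% levels(y)) {
    abort(paste0("Reference class ", reference, " not among observed classes."))
  }
  y <- stats::relevel(y, ref = reference)

  df <- as_tibble(data[, predictors, drop = FALSE])
  is_num <- vapply(df, is.numeric, logical(1))
  centers <- vapply(df[is_num], mean, numeric(1))
  for (v in names(centers)) df[[v]] <- df[[v]] - centers[[v]]
  for (v in names(df)[!is_num]) df[[v]] <- droplevels(factor(df[[v]]))
  xlev <- lapply(df[!is_num], levels)

  n <- nrow(df)
  w <- rep(1, n)
  if (augment && length(xlev) > 0) {
    aug <- augmentation_rows(df, xlev, levels(y))
    # Weight each pseudo-observation in proportion to how many real cases
    # carry its categorical level, so the relative pull toward uniform class
    # probabilities is the same (at most `augment_total`) in small and large
    # cells alike.
    K <- nlevels(y)
    w_aug <- vapply(seq_len(nrow(aug)), function(i) {
      lv <- aug$.level_var[i]
      n_l <- sum(df[[lv]] == aug[[lv]][i])
      augment_total * max(n_l, 1) / (K * length(xlev))
    }, numeric(1))
    df <- bind_rows(df, aug[, names(df), drop = FALSE])
    y <- factor(c(as.character(y), as.character(aug$.class)),
                levels = levels(y))
    w <- c(w, w_aug)
  }

  fit_df <- df
  fit_df$.class <- y
  fit_df$.w <- w
  form <- if (length(predictors) == 0) {
    stats::as.formula(".class ~ 1")
  } else {
    stats::reformulate(predictors, response = ".class")
  }
  fit <- nnet::multinom(form, data = fit_df, weights = fit_df$.w,
                        trace = FALSE, maxit = maxit, Hess = TRUE,
                        model = FALSE)
  if (!is.null(fit$convergence) && fit$convergence != 0) {
    abort("Polytomous model failed to converge; increase maxit.")
  }

  v <- vcov(fit)
  cf <- coef(fit)
  if (is.null(dim(cf))) {  # two-class case: coef() drops to a vector
    cf <- matrix(cf, nrow = 1,
                 dimnames = list(levels(y)[2], names(cf)))
  }
  mu <- coef_vector_in_vcov_order(cf, rownames(v))
  if (!augment && max(abs(mu)) > 15) {
    abort(paste0("Coefficients diverging (|coef| > 15): likely perfect ",
                 "prediction. Re-fit with augment = TRUE."))
  }
  structure(list(
    fit = fit, formula = form, terms = delete.response(terms(fit)),
    predictors = predictors, reference = reference,
    classes = levels(y), centers = centers, xlev = xlev,
    mu = mu, vcov = v, chol = chol_psd(v, "coefficient covariance"),
    n = n, augment = augment,
    augment_weight = if (augment && length(xlev) > 0) augment_total else 0
  ), class = "histmi_polytomous")
}

# One pseudo-observation per (categorical level, class), continuous
# predictors at their centre (0 after centring), other categoricals at their
# modal level.
augmentation_rows <- function(df, xlev, classes) {
  modal <- lapply(names(xlev), function(v) {
    tab <- table(df[[v]])
    names(tab)[which.max(tab)]
  })
  names(modal) <- names(xlev)
  base <- df[1, , drop = FALSE]
  for (v in names(df)) {
    base[[v]] <- if (v %in% names(xlev)) {
      factor(modal[[v]], levels = xlev[[v]])
    } else 0
  }
  rows <- purrr::map_dfr(names(xlev), function(v) {
    purrr::map_dfr(xlev[[v]], function(l) {
      r <- base
      r[[v]] <- factor(l, levels = xlev[[v]])
      r$.level_var <- v
      r
    })
  })
  tidyr::expand_grid(rows, .class = classes)
}

# nnet names vcov rows "<class>:<term>" (or just "<term>" for two classes);
# reorder the coefficient matrix to match.
coef_vector_in_vcov_order <- function(cf, vnames) {
  long <- as.vector(t(cf))
  names(long) <- as.vector(t(outer(rownames(cf), colnames(cf), paste,
                                   sep = ":")))
  if (all(vnames %in% colnames(cf))) {  # two-class fit, unprefixed names
    names(long) <- colnames(cf)
  }
  if (!all(vnames %in% names(long))) {
    abort("Internal error: cannot align coefficients with their covariance.")
  }
  long[vnames]
}

#' Predicted class probabilities from a polytomous model
#'
#' @param model A `histmi_polytomous` fit.
#' @param newdata Case tibble with the model's predictor columns.
#' @param beta Optional coefficient vector (in the model's internal order,
#'   e.g. from [draw_coefficients()]); default the MLE.
#' @return Numeric matrix, one row per case, one column per class (columns
#'   named by class; they sum to 1).
#' @export
predict_class_probs <- function(model, newdata, beta = NULL) {
  beta <- beta %||% model$mu
  if (length(model$predictors) == 0) {
    df <- tibble(.rows = nrow(newdata))
  } else {
    df <- as_tibble(newdata[, model$predictors, drop = FALSE])
  }
  for (v in names(model$centers)) df[[v]] <- df[[v]] - model$centers[[v]]
  for (v in names(model$xlev)) {
    df[[v]] <- factor(as.character(df[[v]]), levels = model$xlev[[v]])
    if (anyNA(df[[v]])) {
      abort(paste0("newdata has levels of ", v,
                   " unseen in the training data."))
    }
  }
  X <- model.matrix(model$terms, data = df, xlev = model$xlev)
  K <- length(model$classes)
  if (is.null(names(beta))) names(beta) <- names(model$mu)
  B <- matrix(0, nrow = K - 1, ncol = ncol(X),
              dimnames = list(model$classes[-1], colnames(X)))
  if (K == 2 && all(colnames(X) %in% names(beta))) {
    B[1, ] <- beta[colnames(X)]
  } else {
    for (j in model$classes[-1]) {
      B[j, ] <- beta[paste(j, colnames(X), sep = ":")]
    }
  }
  if (anyNA(B)) abort("Internal error: coefficient names do not match design.")
  eta <- X %*% t(B)
  p <- softmax_ref(eta)
  colnames(p) <- model$classes
  p
}

#' Draw a coefficient vector from the approximate posterior
#'
#' Samples from the multivariate normal centred at the MLE with the estimated
#' asymptotic covariance — the standard proper-imputation approximation to
#' the Bayesian posterior of the polytomous model.
#'
#' @param model A `histmi_polytomous` fit.
#' @return Named numeric coefficient vector, usable as `beta` in
#'   [predict_class_probs()].
#' @export
draw_coefficients <- function(model) {
  z <- rnorm(length(model$mu))
  drop(model$mu + crossprod(model$chol, z))
}

#' Impute classes from a polytomous model
#'
#' Performs one imputation round: draw a coefficient vector from the
#' approximate posterior (unless `draw = FALSE`), compute each case's class
#' probabilities under it, and sample one class per case — the "probability
#' distribution of the groups among those with known histology plus a degree
#' of random error".
#'
#' @param model A `histmi_polytomous` fit.
#' @param cases Tibble of cases to impute (must carry the model's
#'   predictors).
#' @param draw Draw coefficients from the posterior (default) or impute at
#'   the MLE, leaving only categorical sampling noise.
#' @return Factor of imputed classes, `length(nrow(cases))`, with the
#'   model's class levels.
#' @export
draw_and_impute <- function(model, cases, draw = TRUE) {
  if (nrow(cases) == 0) {
    return(factor(character(), levels = model$classes))
  }
  beta <- if (draw) draw_coefficients(model) else model$mu
  p <- predict_class_probs(model, cases, beta = beta)
  factor(model$classes[sample_categorical(p)], levels = model$classes)
}

#' @export
print.histmi_polytomous <- function(x, ...) {
  cat("Polytomous regression:", deparse(x$formula), "\n")
  cat("Classes:", paste(x$classes, collapse = ", "),
      sprintf("(reference %s); n = %d%s\n", x$reference, x$n,
              if (x$augment_weight > 0)
                sprintf("; augmentation weight %.3g", x$augment_weight)
              else ""))
  invisible(x)
}

#' @describeIn fit_polytomous Tidy the fitted coefficients: one row per
#'   non-reference class x term, with the relative-risk ratio
#'   (`exp(estimate)`), standard error and Wald p-value.
#' @param x A `histmi_polytomous` fit.
#' @param ... Unused.
#' @export
tidy.histmi_polytomous <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  parts <- strsplit(names(x$mu), ":", fixed = TRUE)
  has_class <- lengths(parts) > 1
  cls <- if (all(has_class)) vapply(parts, `[[`, "", 1) else x$classes[2]
  term <- if (all(has_class)) {
    vapply(parts, function(p) paste(p[-1], collapse = ":"), "")
  } else names(x$mu)
  tibble(class = cls, term = term, estimate = unname(x$mu),
         rrr = exp(unname(x$mu)), std.error = unname(se),
         statistic = unname(x$mu / se),
         p.value = 2 * pnorm(-abs(unname(x$mu / se))))
}

#' @describeIn fit_polytomous One-row model summary.
#' @export
glance.histmi_polytomous <- function(x, ...) {
  tibble(n = x$n, n_classes = length(x$classes),
         reference = x$reference, deviance = x$fit$deviance,
         edf = x$fit$edf, AIC = x$fit$AIC)
}
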