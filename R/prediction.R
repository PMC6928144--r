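#' Dichotomize age at a threshold
#'
#' Age enters the outcome model as a group indicator (1 for subjects at or
#' above the cut, 0 below) rather than a continuous covariate; the default
#' cut of 70 years separates the poorer-outcome older group.
#'
#' @param age Positive ages in years.
#' @param cut Threshold in years (subjects with `age >= cut` are coded 1).
#' @return Integer vector of 0/1 indicators.
#' @export
dichotomize_age <- function(age, cut = 70) {
  if (any(age <= 0)) {
    abort("Ages must be positive.", class = "cstload_domain_error")
  }
  as.integer(age >= cut)
}

#' Adjusted R-squared and shrinkage
#'
#' `1 - (1 - R^2)(n - 1)/(n - k - 1)`; the drop `R^2 - adjusted` is the
#' shrinkage used as a cross-validation index (small shrinkage suggests the
#' fit generalizes beyond the sample).
#'
#' @param r_squared R^2 in `[0, 1]` (vectorized).
#' @param n Number of observations; must exceed `k + 1`.
#' @param k Number of predictors.
#' @return Adjusted R-squared (can be negative for weak fits).
#' @export
adjusted_r2 <- function(r_squared, n, k) {
  if (any(n <= k + 1)) {
    abort("Need n > k + 1 for adjusted R^2.", class = "cstload_df_error")
  }
  1 - (1 - r_squared) * (n - 1) / (n - k - 1)
}

fit_ols <- function(data, outcome, predictors) {
  f <- stats::reformulate(if (length(predictors)) predictors else "1",
                          response = outcome)
  lm(f, data = data)
}

step_stats <- function(fit, n, k, r2_prev, k_prev) {
  sm <- summary(fit)
  r2 <- sm$r.squared
  p_model <- if (k > 0) {
    unname(pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE))
  } else NA_real_
  df_change <- k - k_prev
  r2_change <- r2 - r2_prev
  p_change <- if (df_change != 0) {
    fstat <- (r2_change / abs(df_change)) / ((1 - r2) / (n - k - 1))
    unname(pf(abs(fstat), abs(df_change), n - k - 1, lower.tail = FALSE))
  } else NA_real_
  list(r = sqrt(max(r2, 0)), r_squared = r2, p_model = p_model,
       adj_r_squared = adjusted_r2(r2, n, k), r2_change = r2_change,
       p_change = p_change, see = sm$sigma)
}

#' Stepwise multivariable linear regression
#'
#' Forward-stepwise OLS with backward removal, the classic
#' probability-of-F procedure: at each step the candidate with the smallest
#' partial-F p-value enters if that p-value is at most `p_enter`; after every
#' entry, any included predictor whose p-value has risen to `p_remove` or
#' above is removed (worst first); the procedure stops when no entry or
#' removal changes the model. Each step records R, R^2, adjusted R^2, the
#' R^2-change with its F-test p-value, and the standard error of the
#' estimate (SEE, the residual SD).
#'
#' @param data Data frame holding outcome and candidates.
#' @param outcome Outcome column name.
#' @param candidates Character vector of candidate predictor columns (none
#'   constant; `nrow(data) > length(candidates) + 1`).
#' @param p_enter Entry threshold on the probability of F (default 0.05).
#' @param p_remove Removal threshold (default 0.10); must exceed `p_enter`.
#' @return A `stepwise_fit`: list with `steps` (tibble: `step`, `predictors`
#'   (`+`-joined), `entered`, `removed`, `r`, `r_squared`, `p_model`,
#'   `adj_r_squared`, `r2_change`, `p_change`, `see`), `predictors` (final
#'   set, in entry order), `coefficients` (tibble with estimates, SEs,
#'   t-values, two-tailed p-values), `semipartial` (tibble of squared
#'   semipartial correlations for the final predictors), `model` (the final
#'   `lm`), `n`, `status` (`"ok"` or `"no_predictor_entered"`).
#' @export
stepwise_regression <- function(data, outcome, candidates,
                                p_enter = 0.05, p_remove = 0.10) {
  if (p_enter >= p_remove) {
    abort("`p_enter` must be smaller than `p_remove`.",
          class = "cstload_parameter_error")
  }
  n <- nrow(data)
  if (n <= length(candidates) + 1) {
    abort("Need n > number of candidates + 1.", class = "cstload_shape_error")
  }
  for (v in c(outcome, candidates)) {
    if (!v %in% names(data)) {
      abort(sprintf("Column `%s` not found.", v), class = "cstload_schema_error")
    }
  }
  if (any(vapply(candidates, function(v) sd(data[[v]]) == 0, TRUE))) {
    abort("Constant candidate predictor.", class = "cstload_constant_error")
  }
  included <- character()
  steps <- list()
  r2_prev <- 0; k_prev <- 0L; step_no <- 0L
  coef_p <- function(preds, term) {
    sm <- summary(fit_ols(data, outcome, preds))$coefficients
    sm[term, 4]
  }
  repeat {
    changed <- FALSE
    # entry: candidate with the smallest partial-F probability
    pool <- setdiff(candidates, included)
    if (length(pool)) {
      pvals <- vapply(pool, function(cand) coef_p(c(included, cand), cand), 1)
      best <- which.min(pvals)
      if (pvals[best] <= p_enter) {
        included <- c(included, pool[best])
        step_no <- step_no + 1L
        fit <- fit_ols(data, outcome, included)
        st <- step_stats(fit, n, length(included), r2_prev, k_prev)
        steps[[step_no]] <- tibble::tibble(
          step = step_no, predictors = paste(included, collapse = "+"),
          entered = pool[best], removed = NA_character_, !!!st)
        r2_prev <- st$r_squared; k_prev <- length(included)
        changed <- TRUE
      }
    }
    # removal: any included predictor whose probability of F rose to p_remove
    repeat {
      if (length(included) == 0L) break
      sm <- summary(fit_ols(data, outcome, included))$coefficients
      pv <- sm[included, 4]
      worst <- which.max(pv)
      if (pv[worst] >= p_remove) {
        removed <- included[worst]
        included <- setdiff(included, removed)
        step_no <- step_no + 1L
        fit <- fit_ols(data, outcome, included)
        st <- step_stats(fit, n, length(included), r2_prev, k_prev)
        steps[[step_no]] <- tibble::tibble(
          step = step_no,
          predictors = if (length(included)) paste(included, collapse = "+") else "(none)",
          entered = NA_character_, removed = removed, !!!st)
        r2_prev <- st$r_squared; k_prev <- length(included)
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }
  final_fit <- fit_ols(data, outcome, included)
  coefs <- as.data.frame(summary(final_fit)$coefficients)
  coefficients <- tibble::tibble(term = rownames(coefs),
                                 estimate = coefs[[1]], std_error = coefs[[2]],
                                 statistic = coefs[[3]], p_value = coefs[[4]])
  semipartial <- if (length(included)) {
    tibble::tibble(
      predictor = included,
      sr2 = vapply(included, function(pr)
        squared_semipartial(data, outcome, included, pr), 1))
  } else tibble::tibble(predictor = character(), sr2 = numeric())
  empty_steps <- tibble::tibble(
    step = integer(), predictors = character(), entered = character(),
    removed = character(), r = numeric(), r_squared = numeric(),
    p_model = numeric(), adj_r_squared = numeric(), r2_change = numeric(),
    p_change = numeric(), see = numeric())
  structure(list(steps = if (length(steps)) purrr::list_rbind(steps) else empty_steps,
                 predictors = included, coefficients = coefficients,
                 semipartial = semipartial, model = final_fit, n = n,
                 outcome = outcome, candidates = candidates, data = data,
                 status = if (length(included)) "ok" else "no_predictor_entered"),
            class = "stepwise_fit")
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat(sprintf("<stepwise_fit> outcome %s; %s\n", x$outcome,
              if (x$status == "ok") paste("final model:",
                                          paste(x$predictors, collapse = " + "))
              else "no predictor passed the entry threshold"))
  if (nrow(x$steps)) {
    print(as.data.frame(
      x$steps[, c("step", "predictors", "r", "r_squared", "adj_r_squared",
                  "r2_change", "p_change", "see")]), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Squared semipartial correlation of one predictor
#'
#' The unique contribution of `pred` inside the model `predictors`: the drop
#' in R^2 when `pred` is removed from the full set,
#' `R^2(full) - R^2(full minus pred)`. Identical to the dominance module's
#' additional contribution of `pred` over the remaining predictors.
#'
#' @param data Data frame.
#' @param outcome Outcome column name.
#' @param predictors Full predictor set (must contain `pred`).
#' @param pred The predictor of interest.
#' @return The squared semipartial correlation.
#' @export
squared_semipartial <- function(data, outcome, predictors, pred) {
  if (!pred %in% predictors) {
    abort("`pred` must be one of `predictors`.", class = "cstload_usage_error")
  }
  r2_full <- summary(fit_ols(data, outcome, predictors))$r.squared
  rest <- setdiff(predictors, pred)
  r2_rest <- if (length(rest)) {
    summary(fit_ols(data, outcome, rest))$r.squared
  } else 0
  r2_full - r2_rest
}
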