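#' Goodness-of-fit battery for a fitted outcome model
#'
#' Assembles the standard regression diagnostics used to qualify the
#' multivariable outcome model: multicollinearity screened through pairwise
#' predictor correlations (flag at `|r| >= r_flag`); outliers through
#' casewise standardized residuals (residual / SEE, flag at
#' `|z| > outlier_z`); homoscedasticity delivered as plot-ready pairs of
#' standardized predicted values and studentized residuals (visual check, no
#' numeric test silently substituted); residual normality through a
#' Kolmogorov-Smirnov test of the standardized residuals against a fully
#' specified standard normal (or the Lilliefors-corrected variant); and error
#' independence through the Durbin-Watson statistic
#' \eqn{d = \sum_t (e_t - e_{t-1})^2 / \sum_t e_t^2}, computed over the
#' supplied case order (cross-sectional data make d order-dependent, so the
#' order used is recorded rather than hidden).
#'
#' @param fit A [stepwise_regression()] result or an `lm` with at least one
#'   predictor.
#' @param order Case order for Durbin-Watson (default: row order of the
#'   fitting data).
#' @param r_flag Multicollinearity flag threshold on `|r|`.
#' @param outlier_z Casewise outlier threshold on `|standardized residual|`.
#' @param ks Normality test variant: `"normal"` (fully specified N(0,1)) or
#'   `"lilliefors"` (requires the nortest package).
#' @return A `model_diagnostics` object: list with `predictor_cor` (tibble of
#'   pairwise Pearson r with `flagged`), `max_abs_r`, `casewise` (tibble:
#'   `case`, `std_residual`, `studentized`, `std_predicted`, `outlier`),
#'   `n_outliers`, `ks` (tibble: `variant`, `statistic`, `p_value`), `dw`
#'   (Durbin-Watson d in `[0, 4]`), `dw_order` (`"supplied"` or
#'   `"row order"`), and `shrinkage` (R^2 minus adjusted R^2).
#' @export
model_diagnostics <- function(fit, order = NULL, r_flag = 0.9, outlier_z = 3,
                              ks = c("normal", "lilliefors")) {
  ks <- match.arg(ks)
  model <- if (inherits(fit, "stepwise_fit")) fit$model else fit
  stopifnot(inherits(model, "lm"))
  e <- residuals(model)
  n <- length(e)
  if (n < 3) {
    abort("Need at least 3 residuals.", class = "cstload_shape_error")
  }
  X <- stats::model.matrix(model)
  pred_cols <- setdiff(colnames(X), "(Intercept)")
  k <- length(pred_cols)
  if (k == 0) {
    abort("Model has no predictors; diagnostics are not meaningful.",
          class = "cstload_usage_error")
  }
  pc <- if (k >= 2) {
    cm <- cor(X[, pred_cols, drop = FALSE])
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    tibble::tibble(pred_x = pred_cols[idx[, 1]], pred_y = pred_cols[idx[, 2]],
                   r = cm[idx], flagged = abs(cm[idx]) >= r_flag)
  } else {
    tibble::tibble(pred_x = character(), pred_y = character(),
                   r = numeric(), flagged = logical())
  }
  sm <- summary(model)
  see <- sm$sigma
  std_resid <- e / see
  studentized <- rstandard(model)
  std_pred <- as.vector(scale(fitted(model)))
  casewise <- tibble::tibble(case = seq_len(n), std_residual = std_resid,
                             studentized = studentized,
                             std_predicted = std_pred,
                             outlier = abs(std_resid) > outlier_z)
  ks_res <- if (ks == "lilliefors") {
    if (!requireNamespace("nortest", quietly = TRUE)) {
      abort("The Lilliefors variant needs the `nortest` package.",
            class = "cstload_dependency_error")
    }
    lt <- nortest::lillie.test(std_resid)
    tibble::tibble(variant = "lilliefors", statistic = unname(lt$statistic),
                   p_value = lt$p.value)
  } else {
    kt <- suppressWarnings(ks.test(std_resid, "pnorm"))
    tibble::tibble(variant = "normal", statistic = unname(kt$statistic),
                   p_value = kt$p.value)
  }
  eo <- if (is.null(order)) e else e[order]
  dw <- sum(diff(eo)^2) / sum(eo^2)
  structure(list(predictor_cor = pc,
                 max_abs_r = if (nrow(pc)) max(abs(pc$r)) else NA_real_,
                 casewise = casewise, n_outliers = sum(casewise$outlier),
                 ks = ks_res, dw = dw,
                 dw_order = if (is.null(order)) "row order" else "supplied",
                 shrinkage = sm$r.squared - adjusted_r2(sm$r.squared, n, k)),
            class = "model_diagnostics")
}

#' @export
print.model_diagnostics <- function(x, ...) {
  cat(sprintf(paste0("<model_diagnostics> max |r| between predictors: %s; ",
                     "outliers (|std resid| > 3): %d; KS %s p = %.3f; ",
                     "Durbin-Watson d = %.3f (%s); shrinkage = %.3f\n"),
              ifelse(is.na(x$max_abs_r), "n/a", sprintf("%.3f", x$max_abs_r)),
              x$n_outliers, x$ks$variant, x$ks$p_value, x$dw, x$dw_order,
              x$shrinkage))
  invisible(x)
}

#' Case-resampling bootstrap confidence intervals for model coefficients
#'
#' Refits the model on `B` resamples of the cases (single sampling method)
#' and reports percentile 95% intervals per coefficient. Degenerate resamples
#' (constant predictor or singular design) are redrawn up to `max_redraws`
#' times, then skipped with a warning.
#'
#' @param fit A [stepwise_regression()] result or an `lm`.
#' @param B Number of resamples (>= 100).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @param max_redraws Redraw budget per degenerate resample.
#' @return A tibble: `term`, `estimate` (original fit), `conf_low`,
#'   `conf_high`, `B_effective`.
#' @export
bootstrap_coefficients <- function(fit, B = 1000, seed = 1L, level = 0.95,
                                   max_redraws = 100L) {
  if (B < 100) {
    abort("`B` must be >= 100.", class = "cstload_parameter_error")
  }
  model <- if (inherits(fit, "stepwise_fit")) fit$model else fit
  stopifnot(inherits(model, "lm"))
  X <- stats::model.matrix(model)
  y <- stats::model.response(stats::model.frame(model))
  n <- nrow(X)
  free_cols <- setdiff(colnames(X), "(Intercept)")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  draws <- matrix(NA_real_, B, ncol(X), dimnames = list(NULL, colnames(X)))
  kept <- 0L
  for (b in seq_len(B)) {
    for (try in seq_len(max_redraws + 1L)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]
      degenerate <- length(free_cols) &&
        any(apply(Xb[, free_cols, drop = FALSE], 2, sd) == 0)
      if (!degenerate && qr(Xb)$rank == ncol(Xb)) {
        draws[b, ] <- lm.fit(Xb, y[idx])$coefficients
        kept <- kept + 1L
        break
      }
    }
  }
  if (kept < B) {
    warn(sprintf("%d degenerate resample(s) skipped after %d redraws.",
                 B - kept, max_redraws))
  }
  a <- (1 - level) / 2
  tibble::tibble(
    term = colnames(X),
    estimate = unname(coef(model)),
    conf_low = unname(apply(draws, 2, quantile, probs = a, na.rm = TRUE)),
    conf_high = unname(apply(draws, 2, quantile, probs = 1 - a, na.rm = TRUE)),
    B_effective = kept)
}
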