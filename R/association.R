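#' Spearman correlation with Munro interpretation
#'
#' Rank correlation (mid-rank ties) between two variables, with a two-tailed
#' p-value from the t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on
#' n - 2 degrees of freedom — the convention of mainstream statistics
#' software at cohort-scale n. For n <= 10 an exact permutation p-value is
#' available. Incomplete pairs are dropped (pairwise-complete deletion) and
#' counted.
#'
#' @param x,y Numeric vectors of equal length, each non-constant after
#'   pairwise-complete deletion; at least 3 complete pairs.
#' @param exact Use the exact permutation null (only honoured for n <= 10 and
#'   untied data; otherwise falls back to the t approximation).
#' @param munro_breaks Upper edges of the Munro magnitude bands.
#' @return A one-row tibble: `rho`, `p_value`, `n`, `n_dropped`, `munro`.
#' @export
spearman_assoc <- function(x, y, exact = FALSE,
                           munro_breaks = munro_default_breaks()) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.", class = "cstload_shape_error")
  }
  ok <- complete.cases(x, y)
  n_dropped <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort("Need at least 3 complete pairs.", class = "cstload_shape_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Spearman correlation undefined for a constant vector.",
          class = "cstload_constant_error")
  }
  rho <- cor(x, y, method = "spearman")
  if (exact && n <= 10 && !anyDuplicated(x) && !anyDuplicated(y)) {
    p <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * pt(-abs(tval), df = n - 2)
    }
  }
  tibble::tibble(rho = rho, p_value = p, n = n, n_dropped = n_dropped,
                 munro = munro_class(abs(rho), munro_breaks))
}

#' Munro magnitude bands for correlation coefficients
#'
#' Classifies |rho| into the conventional descriptive bands: 0.00–0.25
#' little/none, 0.26–0.49 low, 0.50–0.69 moderate, 0.70–0.89 high, 0.90–1.00
#' very high (so e.g. |rho| = 0.48 is "low" and 0.53 "moderate").
#'
#' @param abs_rho Correlation magnitude(s) in `[0, 1]`.
#' @param breaks Upper band edges (overridable).
#' @return Character vector of band labels.
#' @export
munro_class <- function(abs_rho, breaks = munro_default_breaks()) {
  if (any(abs_rho < 0 | abs_rho > 1)) {
    abort("`abs_rho` must lie in [0, 1].", class = "cstload_domain_error")
  }
  labels <- names(breaks)
  idx <- vapply(abs_rho, function(r) which(r <= breaks + 1e-12)[1], 1L)
  labels[idx]
}

#' @rdname munro_class
#' @export
munro_default_breaks <- function() {
  c("little/none" = 0.25, "low" = 0.49, "moderate" = 0.69,
    "high" = 0.89, "very high" = 1.00)
}

#' Spearman correlation matrix over cohort variables
#'
#' All pairwise rank correlations among `variables`, pairwise-complete, as a
#' tidy table (one row per unordered pair plus the unit diagonal). The
#' symmetric rho and p matrices are available via [as.matrix()].
#'
#' @param data A data frame (e.g. the cohort table).
#' @param variables Column names to correlate (each numeric, >= 3 complete
#'   cases per pair).
#' @param ... Passed to [spearman_assoc()].
#' @return A tibble of class `cor_table`: `var1`, `var2`, `rho`, `p_value`,
#'   `n`, `munro`.
#' @export
correlation_matrix <- function(data, variables, ...) {
  missing_vars <- setdiff(variables, names(data))
  if (length(missing_vars)) {
    abort(paste0("Variables not in `data`: ", paste(missing_vars, collapse = ", ")),
          class = "cstload_schema_error")
  }
  pairs <- tidyr::expand_grid(i = seq_along(variables), j = seq_along(variables)) |>
    dplyr::filter(.data$i <= .data$j)
  rows <- purrr::pmap(pairs, function(i, j) {
    v1 <- variables[i]; v2 <- variables[j]
    if (i == j) {
      n <- sum(stats::complete.cases(data[[v1]]))
      tibble::tibble(var1 = v1, var2 = v2, rho = 1, p_value = NA_real_,
                     n = n, munro = "very high")
    } else {
      res <- spearman_assoc(data[[v1]], data[[v2]], ...)
      tibble::tibble(var1 = v1, var2 = v2, rho = res$rho,
                     p_value = res$p_value, n = res$n, munro = res$munro)
    }
  })
  out <- purrr::list_rbind(rows)
  attr(out, "variables") <- variables
  class(out) <- c("cor_table", class(out))
  out
}

#' @export
as.matrix.cor_table <- function(x, value = c("rho", "p_value"), ...) {
  value <- match.arg(value)
  vars <- attr(x, "variables")
  m <- matrix(NA_real_, length(vars), length(vars), dimnames = list(vars, vars))
  for (k in seq_len(nrow(x))) {
    m[x$var1[k], x$var2[k]] <- m[x$var2[k], x$var1[k]] <- x[[value]][k]
  }
  m
}

#' Univariate linear regression of an outcome on one predictor
#'
#' Ordinary least squares `y ~ x` with the slope's F-test p-value and the
#' coefficient of determination (which equals the squared Pearson correlation
#' in simple regression).
#'
#' @param x Non-constant numeric predictor.
#' @param y Numeric outcome; at least 3 complete pairs.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
univariate_regression <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("Need at least 3 complete pairs.", class = "cstload_shape_error")
  }
  if (sd(x) == 0) {
    abort("Predictor is constant; regression design is degenerate.",
          class = "cstload_constant_error")
  }
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits trip a spurious warning
  pv <- pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3], lower.tail = FALSE)
  tibble::tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared, p_value = unname(pv), n = length(x))
}

#' Univariate screen of several predictors against one outcome
#'
#' @param data A data frame.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor column names.
#' @return A tibble with one row per predictor (columns of
#'   [univariate_regression()] plus `predictor` and `outcome`).
#' @export
univariate_screen <- function(data, outcome, predictors) {
  purrr::map(predictors, function(p) {
    dplyr::bind_cols(tibble::tibble(predictor = p, outcome = outcome),
                     univariate_regression(data[[p]], data[[outcome]]))
  }) |> purrr::list_rbind()
}
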