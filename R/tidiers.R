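#' Tidy a stepwise fit
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return The final-model coefficient tibble (`term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`).
#' @method tidy stepwise_fit
#' @export
tidy.stepwise_fit <- function(x, ...) x$coefficients

#' One-row summary of a stepwise fit
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return A tibble with `n_steps`, `n_predictors`, `r`, `r_squared`,
#'   `adj_r_squared`, `see`, `n`, `status`.
#' @method glance stepwise_fit
#' @export
glance.stepwise_fit <- function(x, ...) {
  sm <- summary(x$model)
  k <- length(x$predictors)
  tibble::tibble(n_steps = nrow(x$steps), n_predictors = k,
                 r = sqrt(max(sm$r.squared, 0)), r_squared = sm$r.squared,
                 adj_r_squared = if (x$n > k + 1) adjusted_r2(sm$r.squared, x$n, k)
                                 else NA_real_,
                 see = sm$sigma, n = x$n, status = x$status)
}

#' Tidy dominance statistics
#'
#' @param x A `dominance` object.
#' @param ... Unused.
#' @return The conditional-dominance tibble (`predictor`, `size`,
#'   `mean_delta_r2`) — one row per dot of the dominance plot.
#' @method tidy dominance
#' @export
tidy.dominance <- function(x, ...) x$conditional

#' One-row summary of a dominance analysis
#'
#' @param x A `dominance` object.
#' @param ... Unused.
#' @return A tibble with `r2_full`, `sum_general_weights`, `top_predictor`
#'   (largest general weight), and `n_complete_pairs`.
#' @method glance dominance
#' @export
glance.dominance <- function(x, ...) {
  tibble::tibble(r2_full = x$r2_full,
                 sum_general_weights = sum(x$general),
                 top_predictor = names(which.max(x$general)),
                 n_complete_pairs = sum(!is.na(x$pairs$complete)))
}

#' Plot conditional dominance curves
#'
#' One dot per predictor and model size: the mean additional R^2 the
#' predictor contributes to models of that size. Lines connect each
#' predictor across sizes — the figure a dominance analysis is usually read
#' from.
#'
#' @param object A `dominance` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dominance
#' @export
autoplot.dominance <- function(object, ...) {
  ggplot2::ggplot(object$conditional,
                  ggplot2::aes(x = .data$size, y = .data$mean_delta_r2,
                               colour = .data$predictor)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Number of other predictors in the model",
                  y = expression("Additional" ~ R^2),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of a Spearman correlation table
#'
#' @param object A `cor_table` from [correlation_matrix()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cor_table
#' @export
autoplot.cor_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$var1, y = .data$var2,
                                       fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$rho)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(rho)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Residual-versus-prediction plot data
#'
#' @param object A `model_diagnostics` object.
#' @param ... Unused.
#' @return A ggplot of studentized residuals against standardized predicted
#'   values (the visual homoscedasticity check).
#' @method autoplot model_diagnostics
#' @export
autoplot.model_diagnostics <- function(object, ...) {
  ggplot2::ggplot(object$casewise,
                  ggplot2::aes(x = .data$std_predicted, y = .data$studentized)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Standardized predicted value",
                  y = "Studentized residual") +
    ggplot2::theme_minimal()
}

#' Outcome against lesion load, grouped by age
#'
#' Scatter of the six-month motor score against a tract's weighted lesion
#' load, coloured by the dichotomized age group — the usual way to show that
#' older patients with comparable lesion load recover less.
#'
#' @param data Cohort tibble.
#' @param load_col Lesion-load column (default `"w_PMD_LL"`).
#' @param outcome Outcome column (default `"fmue_m6"`).
#' @param age_col Age-group indicator column (default `"age_ge70"`).
#' @return A ggplot.
#' @export
plot_age_grouping <- function(data, load_col = "w_PMD_LL",
                              outcome = "fmue_m6", age_col = "age_ge70") {
  data$age_group <- factor(ifelse(data[[age_col]] == 1, ">= 70 y", "< 70 y"))
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[load_col]],
                                     y = .data[[outcome]],
                                     colour = .data$age_group,
                                     shape = .data$age_group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "Weighted lesion load (weighted voxels)",
                  y = "FM-UE at six months", colour = "Age", shape = "Age") +
    ggplot2::theme_minimal()
}

#' Axial mosaic of a lesion overlay map
#'
#' @param object An `overlay_map`.
#' @param slices Axial slice indices to show (default: six evenly spaced
#'   slices with nonzero overlap).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot overlay_map
#' @export
autoplot.overlay_map <- function(object, slices = NULL, ...) {
  nz <- which(apply(object$data, 3, max) > 0)
  if (is.null(slices)) {
    slices <- if (length(nz)) unique(round(seq(min(nz), max(nz), length.out = 6)))
              else round(dim(object$data)[3] / 2)
  }
  df <- purrr::map(slices, function(z) {
    sl <- object$data[, , z]
    tibble::tibble(x = as.vector(row(sl)), y = as.vector(col(sl)),
                   n = as.vector(sl), slice = z)
  }) |> purrr::list_rbind()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$n)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "Subjects") +
    ggplot2::theme_void()
}
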