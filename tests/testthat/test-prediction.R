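test_that("age dichotomization puts the boundary at the cut", {
  expect_identical(dichotomize_age(69), 0L)
  expect_identical(dichotomize_age(70), 1L)
  expect_identical(dichotomize_age(83), 1L)
  expect_identical(dichotomize_age(c(69.9, 70.0), cut = 70), c(0L, 1L))
  expect_error(dichotomize_age(0), class = "cstload_domain_error")
})

test_that("adjusted R^2 follows its formula and degrees-of-freedom contract", {
  expect_equal(round(adjusted_r2(0.68, 27, 1), 2), 0.67)
  expect_equal(adjusted_r2(0.68, 27, 1), 1 - 0.32 * 26 / 25, tolerance = 1e-12)
  expect_equal(adjusted_r2(1, 12, 3), 1)
  expect_equal(adjusted_r2(0, 27, 3), 1 - 26 / 23, tolerance = 1e-12)
  expect_error(adjusted_r2(0.5, 4, 3), class = "cstload_df_error")
})

test_that("stepwise entry selects the only informative candidate", {
  set.seed(71)
  n <- 200
  df <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  df$y <- 3 * df$x1 + rnorm(n)
  sw <- stepwise_regression(df, "y", c("x1", "x2", "x3"))
  expect_identical(sw$predictors, "x1")
  expect_identical(nrow(sw$steps), 1L)
  expect_identical(sw$steps$entered, "x1")
  expect_identical(sw$status, "ok")
})

test_that("stepwise returns an empty model for pure noise in most replications", {
  empty <- logical(60)
  for (r in seq_len(60)) {
    set.seed(4000 + r)
    n <- 200
    df <- tibble::tibble(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n),
                         y = rnorm(n))
    sw <- stepwise_regression(df, "y", c("x1", "x2", "x3"))
    empty[r] <- sw$status == "no_predictor_entered"
  }
  expect_gte(mean(empty), 0.80)
})

test_that("stepwise enters generative predictors in effect-size order", {
  atlas <- make_tract_template(default_tract_specs())
  params <- cohort_params(n_subjects = 200, beta0 = 15, beta_fm = 0.7,
                          beta_ll = -0.04, beta_age = -2.5, sigma_noise = 3,
                          seed = 77)
  co <- simulate_cohort(params, atlas)$cohort
  sw <- stepwise_regression(co, "fmue_m6", c("fmue_wk1", "w_PMD_LL", "age_ge70"))
  expect_identical(sw$steps$entered, c("fmue_wk1", "w_PMD_LL", "age_ge70"))
  expect_identical(nrow(sw$steps), 3L)
})

test_that("stepwise step statistics satisfy their identities", {
  atlas <- make_tract_template(default_tract_specs())
  co <- simulate_cohort(cohort_params(n_subjects = 60, seed = 21), atlas)$cohort
  sw <- stepwise_regression(co, "fmue_m6", c("fmue_wk1", "w_PMD_LL", "age_ge70",
                                             "nihss"))
  st <- sw$steps
  expect_true(all(diff(st$r_squared) >= -1e-12))
  expect_equal(st$r, sqrt(st$r_squared), tolerance = 1e-12)
  expect_equal(st$r2_change, diff(c(0, st$r_squared)), tolerance = 1e-12)
  k <- lengths(strsplit(st$predictors, "+", fixed = TRUE))
  expect_equal(st$adj_r_squared, adjusted_r2(st$r_squared, sw$n, k),
               tolerance = 1e-12)

  expect_error(stepwise_regression(co, "fmue_m6", c("fmue_wk1"),
                                   p_enter = 0.2, p_remove = 0.1),
               class = "cstload_parameter_error")
  expect_error(stepwise_regression(co, "fmue_m6", c("missing_col")),
               class = "cstload_schema_error")
})

test_that("squared semipartials equal the dominance increment over the rest", {
  set.seed(83)
  n <- 100
  df <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  df$y <- df$a + 0.5 * df$b + rnorm(n)
  sr2 <- squared_semipartial(df, "y", c("a", "b", "c"), "b")
  map <- all_subsets_r2(as.matrix(df[, c("a", "b", "c")]), df$y)
  expect_equal(sr2, additional_contribution(map, "b", c("a", "c")),
               tolerance = 1e-12)

  # orthogonal design: semipartial reduces to the marginal squared correlation
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(3 * n), n, 3))))[, 2:4]
  dfo <- tibble::tibble(a = Q[, 1], b = Q[, 2], c = Q[, 3], y = df$y)
  expect_equal(squared_semipartial(dfo, "y", c("a", "b", "c"), "a"),
               cor(dfo$a, dfo$y)^2, tolerance = 1e-10)

  expect_error(squared_semipartial(df, "y", c("a", "b"), "c"),
               class = "cstload_usage_error")
})

test_that("diagnostics flag collinearity and score residual structure", {
  set.seed(87)
  n <- 80
  x1 <- rnorm(n)
  df <- tibble::tibble(x1 = x1, x2 = x1 * 0.999 + rnorm(n, 0, 0.001),
                       y = x1 + rnorm(n))
  fit <- lm(y ~ x1 + x2, data = df)
  d <- model_diagnostics(fit)
  expect_true(any(d$predictor_cor$flagged))
  expect_gte(d$dw, 0); expect_lte(d$dw, 4)
  expect_identical(nrow(d$casewise), as.integer(n))

  # alternating residuals drive Durbin-Watson toward 4
  xa <- rnorm(100)
  ya <- 2 * xa + rep(c(1, -1), 50)
  da <- model_diagnostics(lm(ya ~ xa))
  expect_gt(da$dw, 3.4)

  expect_error(model_diagnostics(lm(rnorm(5) ~ 1)),
               class = "cstload_usage_error")
})

test_that("KS on standardized residuals behaves under the null", {
  ok <- logical(60)
  for (r in seq_len(60)) {
    set.seed(5000 + r)
    x <- rnorm(400); y <- x + rnorm(400)
    d <- model_diagnostics(lm(y ~ x))
    ok[r] <- d$ks$p_value > 0.05
  }
  expect_gte(mean(ok), 0.90)
})

test_that("Lilliefors variant is available through nortest", {
  skip_if_not_installed("nortest")
  set.seed(91)
  x <- rnorm(60); y <- x + rnorm(60)
  d <- model_diagnostics(lm(y ~ x), ks = "lilliefors")
  expect_identical(d$ks$variant, "lilliefors")
  expect_true(d$ks$p_value >= 0 && d$ks$p_value <= 1)
})

test_that("coefficient bootstrap degenerates to point mass without noise", {
  set.seed(93)
  n <- 50
  x <- rnorm(n)
  y <- 2 + 3 * x            # no noise at all
  cb <- bootstrap_coefficients(lm(y ~ x), B = 200, seed = 4)
  expect_equal(cb$conf_low, cb$conf_high, tolerance = 1e-10)
  expect_equal(cb$conf_low, c(2, 3), tolerance = 1e-8)

  yn <- 2 + 3 * x + rnorm(n)
  fit <- lm(yn ~ x)
  cbn <- bootstrap_coefficients(fit, B = 300, seed = 4)
  expect_true(all(cbn$conf_low <= coef(fit) & coef(fit) <= cbn$conf_high))
  expect_error(bootstrap_coefficients(fit, B = 50),
               class = "cstload_parameter_error")
})

test_that("Durbin-Watson agrees with the reference implementation", {
  skip_if_not_installed("lmtest")
  set.seed(97)
  x <- rnorm(60); y <- x + rnorm(60)
  fit <- lm(y ~ x)
  d <- model_diagnostics(fit)
  expect_equal(d$dw, unname(lmtest::dwtest(fit)$statistic), tolerance = 1e-10)
})
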