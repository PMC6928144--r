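test_that("subset R^2 maps agree with per-subset OLS refits", {
  set.seed(11)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- drop(X %*% c(1, 0.5, 0) + rnorm(n))
  map <- all_subsets_r2(X, y)
  expect_length(map$r2, 8)
  expect_identical(unname(map$r2[1]), 0)
  oracle <- subset_r2_lm_oracle(X, y)
  expect_equal(unname(map$r2), oracle, tolerance = 1e-10)

  # single predictor: R^2 equals squared Pearson correlation
  m1 <- all_subsets_r2(X[, 1, drop = FALSE], y)
  expect_length(m1$r2, 2)
  expect_equal(unname(m1$r2[2]), cor(X[, 1], y)^2, tolerance = 1e-12)

  # exact linear outcome
  mex <- all_subsets_r2(X, drop(X %*% c(2, -1, 3)))
  expect_equal(unname(mex$r2[8]), 1, tolerance = 1e-12)

  expect_error(all_subsets_r2(cbind(a = rep(1, 10)), rnorm(10)),
               class = "cstload_constant_error")
  expect_error(all_subsets_r2(matrix(rnorm(6), 3, 2), rnorm(3)),
               class = "cstload_shape_error")
})

test_that("subset R^2 is monotone under inclusion", {
  set.seed(19)
  X <- matrix(rnorm(200), 50, 4)
  y <- rnorm(50)
  map <- all_subsets_r2(X, y)
  r2 <- unname(map$r2)
  for (m in 0:14) {
    for (i in 0:3) {
      if (bitwAnd(m, 2^i) == 0) {
        expect_gte(r2[m + 2^i + 1] - r2[m + 1], -1e-10)
      }
    }
  }
})

test_that("additional contributions follow their definition", {
  set.seed(13)
  X <- matrix(rnorm(150), 50, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- X[, 1] + rnorm(50)
  map <- all_subsets_r2(X, y)
  expect_equal(additional_contribution(map, "a"),
               unname(map$r2["a"]), tolerance = 1e-12)
  expect_equal(additional_contribution(map, "b", c("a", "c")),
               unname(map$r2["a+b+c"] - map$r2["a+c"]), tolerance = 1e-12)
  expect_error(additional_contribution(map, "a", c("a", "b")),
               class = "cstload_usage_error")

  # collinear twin adds nothing
  X2 <- cbind(X[, 1:2], twin = X[, 1])
  colnames(X2) <- c("a", "b", "twin")
  map2 <- suppressWarnings(all_subsets_r2(X2, y))
  expect_lt(abs(additional_contribution(map2, "twin", c("a", "b"))), 1e-8)
})

test_that("orthogonal predictors contribute the same increment in every context", {
  set.seed(29)
  raw <- matrix(rnorm(300), 100, 3)
  Q <- qr.Q(qr(cbind(1, raw)))[, 2:4]  # orthogonal to intercept and each other
  colnames(Q) <- c("q1", "q2", "q3")
  y <- rnorm(100)
  map <- all_subsets_r2(Q, y)
  for (pred in colnames(Q)) {
    others <- setdiff(colnames(Q), pred)
    deltas <- c(
      additional_contribution(map, pred),
      additional_contribution(map, pred, others[1]),
      additional_contribution(map, pred, others[2]),
      additional_contribution(map, pred, others))
    expect_lt(max(deltas) - min(deltas), 1e-10)
  }
})

test_that("a strong predictor completely dominates pure noise", {
  set.seed(41)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 2 * x1 + rnorm(n)
  map <- all_subsets_r2(cbind(x1 = x1, x2 = x2), y)
  ds <- dominance_stats(map)
  pair <- ds$pairs[ds$pairs$pred_x == "x1" & ds$pairs$pred_y == "x2", ]
  expect_identical(pair$complete, "x1")
  expect_identical(pair$conditional, "x1")
  expect_identical(pair$general, "x1")
  expect_identical(pair$relation, "complete")
  expect_equal(sum(ds$general), ds$r2_full, tolerance = 1e-9)
})

test_that("byte-identical predictors establish no dominance at any level", {
  set.seed(43)
  x <- rnorm(80)
  X <- cbind(a = x, b = x)
  y <- x + rnorm(80)
  map <- suppressWarnings(all_subsets_r2(X, y))
  ds <- dominance_stats(map)
  expect_true(is.na(ds$pairs$complete))
  expect_true(is.na(ds$pairs$conditional))
  expect_true(is.na(ds$pairs$general))
  expect_identical(ds$pairs$relation, "none")
})

test_that("designations match an exhaustive oracle and respect the hierarchy", {
  set.seed(59)
  for (trial in 1:12) {
    p <- sample(3:5, 1)
    n <- 40
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p) * rbinom(p, 1, 0.7)
    y <- X %*% beta + rnorm(n)
    colnames(X) <- paste0("v", seq_len(p))
    map <- all_subsets_r2(X, y)
    ds <- dominance_stats(map)
    oracle <- dominance_oracle(unname(map$r2), p)
    expect_equal(unname(ds$general), oracle$general, tolerance = 1e-9)
    k <- 0
    for (i in seq_len(p)) for (j in seq_len(p)) if (i < j) {
      k <- k + 1
      codes <- oracle$pairs[[paste(i, j)]]
      row <- ds$pairs[k, ]
      decode <- function(code) {
        if (code == 1L) colnames(X)[i]
        else if (code == -1L) colnames(X)[j]
        else NA_character_
      }
      expect_identical(row$complete, decode(codes["complete"]))
      expect_identical(row$conditional, decode(codes["conditional"]))
      expect_identical(row$general, decode(codes["general"]))
      # complete implies conditional implies general
      if (!is.na(row$complete)) expect_identical(row$conditional, row$complete)
      if (!is.na(row$conditional)) expect_identical(row$general, row$conditional)
    }
  }
})

test_that("dominance bootstrap is seeded, reproducible, and validates B", {
  set.seed(61)
  n <- 60
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- X[, 1] + 0.3 * X[, 2] + rnorm(n)
  b1 <- bootstrap_reproducibility(X, y, B = 50, seed = 99)
  b2 <- bootstrap_reproducibility(X, y, B = 50, seed = 99)
  expect_identical(b1, b2)
  expect_setequal(unique(b1$level), c("complete", "conditional", "general"))
  expect_true(all(b1$reproducibility >= 0 & b1$reproducibility <= 1))
  expect_identical(nrow(b1), 9L)

  expect_error(bootstrap_reproducibility(X, y, B = 0),
               class = "cstload_parameter_error")
})

test_that("reproducibility ranges summarize pairwise general dominance", {
  set.seed(67)
  X <- cbind(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  y <- X[, 1] + rnorm(40)
  b <- bootstrap_reproducibility(X, y, B = 40, seed = 8)
  rng <- reproducibility_range(b)
  expect_identical(nrow(rng), 3L)
  expect_true(all(rng$min_reproducibility <= rng$max_reproducibility))
  gen_a <- b$reproducibility[b$level == "general" &
                               (b$pred_x == "a" | b$pred_y == "a")]
  expect_equal(rng$min_reproducibility[rng$predictor == "a"], min(gen_a))
})
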