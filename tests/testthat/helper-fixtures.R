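# Small mask builders and independent oracles shared across test files.

rand_mask <- function(dim, p = 0.2, affine = diag(4)) {
  mask_vol(array(runif(prod(dim)) < p, dim), affine)
}

# Tube tract: per-slice voxel counts set exactly, packed from the slice origin.
tube_tract <- function(areas, dim = c(6, 6, length(areas)), affine = diag(4)) {
  stopifnot(all(areas <= dim[1] * dim[2]))
  arr <- array(0L, dim)
  plane <- dim[1] * dim[2]
  for (z in seq_along(areas)) {
    if (areas[z] > 0) arr[(z - 1) * plane + seq_len(areas[z])] <- 1L
  }
  mask_vol(arr, affine)
}

# Brute-force weighted lesion load: per-voxel sum of m*/m(z) over the
# intersection — independent of the slicewise implementation.
wll_bruteforce <- function(lesion, tract) {
  m <- apply(tract$data, 3, sum)
  ms <- max(m)
  idx <- which(lesion$data > 0 & tract$data > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  sum(ms / m[idx[, 3]])
}

# Independent all-subsets R^2: one stats::lm refit per subset.
subset_r2_lm_oracle <- function(X, y) {
  X <- as.matrix(X)
  p <- ncol(X)
  out <- numeric(2^p)
  for (mask in 1:(2^p - 1)) {
    S <- which(bitwAnd(mask, 2^(0:(p - 1))) > 0)
    out[mask + 1] <- summary(lm(y ~ X[, S, drop = FALSE]))$r.squared
  }
  out
}

# Independent pairwise dominance designations recomputed from an R^2 vector
# (indexed by bitmask + 1), used for the implication checks.
dominance_oracle <- function(r2, p) {
  bits <- 2^(0:(p - 1))
  masks <- 0:(2^p - 1)
  size <- vapply(masks, function(m) sum(bitwAnd(m, bits) > 0), 1)
  delta <- function(i, m) r2[m + bits[i] + 1] - r2[m + 1]
  excl <- function(i) masks[bitwAnd(masks, bits[i]) == 0]
  cond_mean <- function(i, k) {
    ms <- excl(i); ms <- ms[size[ms + 1] == k]
    mean(vapply(ms, function(m) delta(i, m), 1))
  }
  gen <- vapply(seq_len(p), function(i)
    mean(vapply(0:(p - 1), function(k) cond_mean(i, k), 1)), 1)
  pairs <- list()
  for (i in seq_len(p)) for (j in seq_len(p)) if (i < j) {
    both <- masks[bitwAnd(masks, bits[i]) == 0 & bitwAnd(masks, bits[j]) == 0]
    di <- vapply(both, function(m) delta(i, m), 1)
    dj <- vapply(both, function(m) delta(j, m), 1)
    ci <- vapply(0:(p - 1), function(k) cond_mean(i, k), 1)
    cj <- vapply(0:(p - 1), function(k) cond_mean(j, k), 1)
    pairs[[paste(i, j)]] <- c(
      complete = if (all(di > dj)) 1L else if (all(dj > di)) -1L else 0L,
      conditional = if (all(ci > cj)) 1L else if (all(cj > ci)) -1L else 0L,
      general = if (gen[i] > gen[j]) 1L else if (gen[j] > gen[i]) -1L else 0L)
  }
  list(general = gen, pairs = pairs)
}

# --- cached parameter-recovery simulation ------------------------------------
# 100 cohorts of 200 subjects from the generative model with well-separated
# standardized effects; reused by the synthetic-data and acceptance suites.

.recovery_cache <- new.env(parent = emptyenv())

recovery_betas <- function() {
  c(beta0 = 15, beta_fm = 0.7, beta_ll = -0.02, beta_age = -5)
}

recovery_sim <- function(n_reps = 100) {
  key <- as.character(n_reps)
  if (!is.null(.recovery_cache[[key]])) return(.recovery_cache[[key]])
  atlas <- make_tract_template(default_tract_specs())
  tr <- recovery_betas()
  gen <- c("fmue_wk1", "w_PMD_LL", "age_ge70")
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    params <- cohort_params(n_subjects = 200, beta0 = tr["beta0"],
                            beta_fm = tr["beta_fm"], beta_ll = tr["beta_ll"],
                            beta_age = tr["beta_age"], sigma_noise = 3,
                            seed = 1000 + r)
    co <- simulate_cohort(params, atlas)$cohort
    sw <- stepwise_regression(co, "fmue_m6", gen)
    fit <- lm(fmue_m6 ~ fmue_wk1 + w_PMD_LL + age_ge70, data = co)
    ols_ci <- stats::confint(fit)
    boot <- bootstrap_coefficients(fit, B = 1000, seed = 2000 + r)
    truth <- c(tr["beta_fm"], tr["beta_ll"], tr["beta_age"])
    rows[[r]] <- tibble::tibble(
      rep = r,
      exact_selection = setequal(sw$predictors, gen),
      ols_cov_fm = ols_ci[2, 1] <= truth[1] && truth[1] <= ols_ci[2, 2],
      ols_cov_ll = ols_ci[3, 1] <= truth[2] && truth[2] <= ols_ci[3, 2],
      ols_cov_age = ols_ci[4, 1] <= truth[3] && truth[3] <= ols_ci[4, 2],
      boot_cov_fm = boot$conf_low[2] <= truth[1] && truth[1] <= boot$conf_high[2],
      boot_cov_ll = boot$conf_low[3] <= truth[2] && truth[2] <= boot$conf_high[3],
      boot_cov_age = boot$conf_low[4] <= truth[3] && truth[3] <= boot$conf_high[4])
  }
  res <- purrr::list_rbind(rows)
  .recovery_cache[[key]] <- res
  res
}
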