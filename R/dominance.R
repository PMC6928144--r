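# --- subset bookkeeping -----------------------------------------------------
# For p predictors, subsets are bitmasks 0..2^p-1; structures are cached per p
# since the dominance bootstrap re-walks the same lattice thousands of times.

.subset_cache <- new.env(parent = emptyenv())

subset_structure <- function(p) {
  key <- as.character(p)
  if (!is.null(.subset_cache[[key]])) return(.subset_cache[[key]])
  masks <- 0:(2^p - 1)
  bits <- 2^(0:(p - 1))
  inmask <- vapply(bits, function(b) bitwAnd(masks, b) > 0, logical(length(masks)))
  size <- as.integer(rowSums(inmask))
  members <- apply(inmask, 1, which, simplify = FALSE)
  pred <- lapply(seq_len(p), function(i) {
    excl <- which(!inmask[, i])            # masks not containing i (1-based idx)
    list(iS = excl, iSi = excl + bits[i], sizes = size[excl])
  })
  pair <- list()
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i < j) {
        pair[[paste(i, j)]] <- which(!inmask[, i] & !inmask[, j])
      }
    }
  }
  str <- list(p = p, masks = masks, bits = bits, size = size,
              members = members, pred = pred, pair = pair)
  .subset_cache[[key]] <- str
  str
}

# R^2 of every predictor subset from the centred cross-product matrices.
# One small linear solve per subset; a rank-deficient subset falls back to the
# SVD pseudo-solution and is flagged.
r2_all_subsets <- function(X, y, str) {
  Z <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  cyy <- sum(yc^2)
  if (cyy == 0) {
    abort("Outcome is constant; R^2 undefined.", class = "cstload_constant_error")
  }
  C <- crossprod(Z)
  cxy <- drop(crossprod(Z, yc))
  n_sub <- 2^str$p
  r2 <- numeric(n_sub)
  flagged <- integer()
  for (m in 2:n_sub) {
    S <- str$members[[m]]
    CS <- C[S, S, drop = FALSE]
    sol <- tryCatch(solve(CS, cxy[S]), error = function(e) NULL)
    if (is.null(sol)) {
      sv <- svd(CS)
      pos <- sv$d > max(sv$d) * 1e-12
      sol <- sv$v[, pos, drop = FALSE] %*%
        ((crossprod(sv$u[, pos, drop = FALSE], cxy[S])) / sv$d[pos])
      flagged <- c(flagged, m - 1L)
    }
    r2[m] <- sum(cxy[S] * sol) / cyy
  }
  list(r2 = r2, flagged = flagged)
}

#' R-squared of every predictor subset
#'
#' Fits (via the centred cross-product matrices) the OLS regression of `y` on
#' each of the 2^p subsets of the predictors, including the empty model
#' (R^2 = 0). This map is the substrate of dominance analysis: every
#' additional-contribution and dominance statistic is a function of it. The
#' map is monotone under subset inclusion.
#'
#' @param X Numeric matrix or data frame of predictors (no constant column);
#'   `nrow(X) > ncol(X) + 1`.
#' @param y Numeric outcome.
#' @return A `subset_r2` object: list with `r2` (named numeric of length 2^p;
#'   names are `+`-joined predictor labels, `"(none)"` for the empty set),
#'   `predictors`, `n`, and `flagged` (labels of rank-deficient subsets whose
#'   R^2 used the pseudo-solution).
#' @export
all_subsets_r2 <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  if (p < 1 || p > 20) {
    abort("Between 1 and 20 predictors are supported.",
          class = "cstload_parameter_error")
  }
  if (nrow(X) <= p + 1) {
    abort("Need n > p + 1 observations.", class = "cstload_shape_error")
  }
  csd <- apply(X, 2, sd)
  if (any(csd == 0)) {
    abort(paste0("Constant predictor(s): ",
                 paste(colnames(X)[csd == 0], collapse = ", ")),
          class = "cstload_constant_error")
  }
  str <- subset_structure(p)
  res <- r2_all_subsets(X, y, str)
  labels <- vapply(str$members, function(S) {
    if (!length(S)) "(none)" else paste(colnames(X)[S], collapse = "+")
  }, "")
  out <- list(r2 = setNames(res$r2, labels), predictors = colnames(X),
              n = nrow(X), flagged = labels[res$flagged + 1L])
  if (length(out$flagged)) {
    warn(paste0("Rank-deficient subset(s), pseudo-solution used: ",
                paste(out$flagged, collapse = "; ")))
  }
  class(out) <- "subset_r2"
  out
}

#' @export
print.subset_r2 <- function(x, ...) {
  cat(sprintf("<subset_r2> %d predictors, %d subsets, full-model R^2 = %.4f\n",
              length(x$predictors), length(x$r2), x$r2[length(x$r2)]))
  invisible(x)
}

subset_mask <- function(map, preds) {
  idx <- match(preds, map$predictors)
  if (anyNA(idx)) {
    abort(paste0("Unknown predictor(s): ",
                 paste(preds[is.na(idx)], collapse = ", ")),
          class = "cstload_usage_error")
  }
  if (length(idx)) sum(2^(idx - 1)) else 0
}

#' Additional R-squared contribution of a predictor over a subset
#'
#' `r2(S + pred) - r2(S)`: the increase in explained variance when `pred`
#' joins the model already containing `S`. Non-negative up to floating-point
#' noise by monotonicity of the subset map.
#'
#' @param map A [all_subsets_r2()] result.
#' @param pred Predictor label.
#' @param subset Character vector of predictor labels excluding `pred`
#'   (default: the empty model).
#' @return The scalar increase in R^2.
#' @export
additional_contribution <- function(map, pred, subset = character()) {
  stopifnot(inherits(map, "subset_r2"))
  if (pred %in% subset) {
    abort("`pred` must not be a member of `subset`.",
          class = "cstload_usage_error")
  }
  m0 <- subset_mask(map, subset)
  m1 <- m0 + 2^(match(pred, map$predictors) - 1)
  unname(map$r2[m1 + 1] - map$r2[m0 + 1])
}

# --- dominance designations --------------------------------------------------
# Levels: complete (pairwise Delta-R^2 comparison over every subset excluding
# both), conditional (size-averaged contributions at every model size), and
# general (grand average). Strict inequalities; any tie yields "undetermined"
# (0). Encoded +1 = first predictor dominates, -1 = second, 0 = undetermined.

dominance_core <- function(r2, str, clip = 1e-10) {
  p <- str$p
  n_sub <- length(r2)
  delta <- matrix(NA_real_, n_sub, p)
  for (i in seq_len(p)) {
    pi <- str$pred[[i]]
    d <- r2[pi$iSi] - r2[pi$iS]
    d[d < 0 & d > -clip] <- 0
    delta[pi$iS, i] <- d
  }
  cond <- matrix(NA_real_, p, p)   # row: predictor, col: size k = 0..p-1
  for (i in seq_len(p)) {
    pi <- str$pred[[i]]
    cond[i, ] <- vapply(0:(p - 1), function(k)
      mean(delta[pi$iS[pi$sizes == k], i]), numeric(1))
  }
  general <- rowMeans(cond)
  npair <- p * (p - 1) / 2
  comp <- integer(npair); condd <- integer(npair); gen <- integer(npair)
  k <- 0L
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i < j) {
        k <- k + 1L
        idx <- str$pair[[paste(i, j)]]
        di <- delta[idx, i]; dj <- delta[idx, j]
        comp[k] <- if (all(di > dj)) 1L else if (all(dj > di)) -1L else 0L
        ci <- cond[i, ]; cj <- cond[j, ]
        condd[k] <- if (all(ci > cj)) 1L else if (all(cj > ci)) -1L else 0L
        gen[k] <- if (general[i] > general[j]) 1L
                  else if (general[j] > general[i]) -1L else 0L
      }
    }
  }
  list(delta = delta, cond = cond, general = general,
       designations = rbind(complete = comp, conditional = condd, general = gen))
}

pair_index <- function(p) {
  out <- NULL
  for (i in seq_len(p)) for (j in seq_len(p)) if (i < j) out <- rbind(out, c(i, j))
  out
}

#' Dominance statistics from a subset R-squared map
#'
#' Computes, per predictor, the mean additional R^2 contribution at each
#' model size (conditional averages) and their grand mean (the general
#' dominance weight), and, per predictor pair, the strongest dominance
#' relation established: complete (one predictor adds more R^2 than the other
#' over every subset excluding both), conditional (greater size-k average at
#' every size), or general (greater general weight). Complete implies
#' conditional implies general; ties at a level leave that level
#' undetermined. General weights sum to the full-model R^2.
#'
#' @param map A [all_subsets_r2()] result.
#' @return A `dominance` object: `conditional` (tibble: `predictor`, `size`,
#'   `mean_delta_r2` — one row per dot of the conditional-dominance plot),
#'   `general` (named numeric of general weights), `pairs` (tibble:
#'   `pred_x`, `pred_y`, `complete`, `conditional`, `general`, each the
#'   dominating predictor's label or `NA` if undetermined, and `relation`,
#'   the strongest level established), and `r2_full`.
#' @export
dominance_stats <- function(map) {
  stopifnot(inherits(map, "subset_r2"))
  p <- length(map$predictors)
  str <- subset_structure(p)
  core <- dominance_core(unname(map$r2), str)
  conditional <- purrr::map(seq_len(p), function(i) {
    tibble::tibble(predictor = map$predictors[i], size = 0:(p - 1),
                   mean_delta_r2 = core$cond[i, ])
  }) |> purrr::list_rbind()
  pi <- pair_index(p)
  des <- core$designations
  decode <- function(code, i, j) {
    dplyr::case_when(code == 1L ~ map$predictors[i],
                     code == -1L ~ map$predictors[j],
                     TRUE ~ NA_character_)
  }
  pairs <- tibble::tibble(
    pred_x = map$predictors[pi[, 1]],
    pred_y = map$predictors[pi[, 2]],
    complete = decode(des["complete", ], pi[, 1], pi[, 2]),
    conditional = decode(des["conditional", ], pi[, 1], pi[, 2]),
    general = decode(des["general", ], pi[, 1], pi[, 2])) |>
    dplyr::mutate(relation = dplyr::case_when(
      !is.na(.data$complete) ~ "complete",
      !is.na(.data$conditional) ~ "conditional",
      !is.na(.data$general) ~ "general",
      TRUE ~ "none"))
  structure(list(conditional = conditional,
                 general = setNames(core$general, map$predictors),
                 pairs = pairs, r2_full = unname(map$r2[length(map$r2)]),
                 predictors = map$predictors),
            class = "dominance")
}

#' @export
print.dominance <- function(x, ...) {
  cat("<dominance> general weights (sum = full-model R^2):\n")
  print(round(sort(x$general, decreasing = TRUE), 4))
  invisible(x)
}

#' Bootstrap reproducibility of dominance designations
#'
#' Draws `B` case resamples with replacement, recomputes the dominance
#' designations on each, and reports, for every predictor pair and level, the
#' fraction of resamples that reproduce the designation observed in the
#' original sample. A resample in which some predictor (or the outcome) is
#' constant is redrawn up to `max_redraws` times; if still degenerate it is
#' kept in the denominator as non-reproducing and a warning is raised.
#'
#' @param X Predictor matrix or data frame; `nrow(X) >= ncol(X) + 2`.
#' @param y Numeric outcome.
#' @param B Number of resamples (>= 1).
#' @param seed Integer seed (fixing it makes the result bit-reproducible).
#' @param max_redraws Redraw budget per degenerate resample.
#' @return A `dominance_boot` object: tibble with `pred_x`, `pred_y`,
#'   `level`, `original` (the designated dominator in the original sample, or
#'   `NA`), and `reproducibility` in `[0, 1]`; attributes carry `B` and the
#'   original [dominance_stats()].
#' @export
bootstrap_reproducibility <- function(X, y, B = 1000, seed = 1L,
                                      max_redraws = 100L) {
  if (B < 1) {
    abort("`B` must be >= 1.", class = "cstload_parameter_error")
  }
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X); n <- nrow(X)
  if (n < p + 2) {
    abort("Need n >= p + 2 observations.", class = "cstload_shape_error")
  }
  str <- subset_structure(p)
  orig_map <- all_subsets_r2(X, y)
  orig <- dominance_core(unname(orig_map$r2), str)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  npair <- p * (p - 1) / 2
  match_counts <- matrix(0L, 3, npair, dimnames = list(c("complete", "conditional", "general"), NULL))
  n_failed <- 0L
  for (b in seq_len(B)) {
    ok <- FALSE
    for (try in seq_len(max_redraws + 1L)) {
      idx <- sample.int(n, n, replace = TRUE)
      Xb <- X[idx, , drop = FALSE]; yb <- y[idx]
      if (all(apply(Xb, 2, sd) > 0) && sd(yb) > 0) { ok <- TRUE; break }
    }
    if (!ok) { n_failed <- n_failed + 1L; next }
    res <- r2_all_subsets(Xb, yb, str)
    db <- dominance_core(res$r2, str)
    match_counts <- match_counts + (db$designations == orig$designations)
  }
  if (n_failed > 0) {
    warn(sprintf("%d resample(s) stayed degenerate after %d redraws; counted as non-reproducing.",
                 n_failed, max_redraws))
  }
  pi <- pair_index(p)
  preds <- colnames(X)
  rows <- purrr::map(c("complete", "conditional", "general"), function(lv) {
    code <- orig$designations[lv, ]
    tibble::tibble(
      pred_x = preds[pi[, 1]], pred_y = preds[pi[, 2]], level = lv,
      original = dplyr::case_when(code == 1L ~ preds[pi[, 1]],
                                  code == -1L ~ preds[pi[, 2]],
                                  TRUE ~ NA_character_),
      reproducibility = match_counts[lv, ] / B)
  })
  out <- purrr::list_rbind(rows)
  attr(out, "B") <- B
  attr(out, "dominance") <- dominance_stats(orig_map)
  class(out) <- c("dominance_boot", class(out))
  out
}

#' Per-predictor reproducibility range of general dominance
#'
#' Summarizes a [bootstrap_reproducibility()] table as, for each predictor,
#' the minimum and maximum of its pairwise general-dominance reproducibility
#' values — the "reproducibility range" convention for reporting how stably a
#' predictor's general dominance survives resampling.
#'
#' @param boot A `dominance_boot` table.
#' @return A tibble: `predictor`, `min_reproducibility`,
#'   `max_reproducibility`.
#' @export
reproducibility_range <- function(boot) {
  stopifnot(inherits(boot, "dominance_boot"))
  gen <- dplyr::filter(boot, .data$level == "general")
  preds <- unique(c(gen$pred_x, gen$pred_y))
  purrr::map(preds, function(pr) {
    vals <- gen$reproducibility[gen$pred_x == pr | gen$pred_y == pr]
    tibble::tibble(predictor = pr,
                   min_reproducibility = min(vals),
                   max_reproducibility = max(vals))
  }) |> purrr::list_rbind()
}
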