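#' Ellipsoidal synthetic lesion
#'
#' Builds the binary mask of the ellipsoid
#' \eqn{\{v : \sum_i ((v_i - c_i)/r_i)^2 \le 1\}} intersected with the grid —
#' a simple, deterministic stand-in for an ischaemic lesion.
#'
#' @param center Voxel triple (1-based, may be fractional).
#' @param radii Semi-axes `(rx, ry, rz)` in voxels, all strictly positive.
#'   Radii below 0.5 yield the single voxel nearest the centre.
#' @param dim Grid shape.
#' @param affine Voxel-to-world transform.
#' @return A [mask_vol()].
#' @export
make_lesion <- function(center, radii, dim = c(64L, 64L, 40L),
                        affine = default_affine(2, dim)) {
  if (any(radii <= 0)) {
    abort("Lesion radii must be strictly positive.",
          class = "cstload_parameter_error")
  }
  if (any(center < 1) || any(center > dim)) {
    abort("Lesion center must lie inside the grid.",
          class = "cstload_parameter_error")
  }
  arr <- array(0L, dim)
  lo <- pmax(1L, floor(center - radii))
  hi <- pmin(dim, ceiling(center + radii))
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- ((xs - center[1]) / radii[1])^2
  dy2 <- ((ys - center[2]) / radii[2])^2
  dz2 <- ((zs - center[3]) / radii[3])^2
  box <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  if (!any(box)) {  # sub-voxel ellipsoid: nearest voxel to the centre
    arr[round(center[1]), round(center[2]), round(center[3])] <- 1L
  } else {
    arr[xs, ys, zs] <- box * 1L
  }
  mask_vol(arr, affine)
}

#' Parameters of the synthetic clinical cohort
#'
#' Encodes the generative model used throughout the test-bed: six-month
#' Fugl-Meyer Upper Extremity (FM-UE) score is a linear function of the
#' one-week score, the weighted premotor-dorsal (PMD) lesion load, and an
#' age >= 70 indicator, plus Gaussian noise, then rounded to the integer
#' 0–66 instrument scale:
#' \deqn{FM_{6m} = \beta_0 + \beta_{fm} FM_{1w} + \beta_{ll} wPMDLL +
#'       \beta_{age} 1[age \ge 70] + \epsilon,\quad \epsilon \sim N(0, \sigma^2).}
#'
#' Defaults: 27 subjects; age from Normal(68, 10) truncated to 30–95 years
#' (cohorts of this kind centre in the late 60s); 70% right-hemisphere
#' strokes; one-week FM-UE drawn as `66 * Beta(0.6, 0.8)` rounded (wide,
#' left-heavy severity mix); NIHSS ~ Poisson(9) capped at 42; lesion centres
#' jittered around the capsular portion of the corticospinal bundle with
#' uniform 2–6 voxel semi-axes.
#'
#' @param n_subjects Number of subjects (>= 4).
#' @param beta0,beta_fm,beta_ll,beta_age Linear coefficients (FM-UE points;
#'   `beta_fm` per FM-UE point, `beta_ll` per weighted voxel, `beta_age` per
#'   age-group step).
#' @param sigma_noise Residual SD in FM-UE points (>= 0).
#' @param age_mean,age_sd,age_range Truncated-normal age distribution (years).
#' @param p_right Probability that the affected hemisphere is the right one.
#' @param fm1_shape Two Beta shape parameters for the one-week FM-UE draw.
#' @param lesion_center_sd Per-axis SD (voxels) of the lesion centre around
#'   the capsular reference point of the affected hemisphere.
#' @param lesion_radius_range Uniform range (voxels) of each semi-axis.
#' @param age_cut Age threshold (years) for the dichotomized age indicator.
#' @param seed Integer seed; every random draw descends from it.
#' @return A `cohort_params` list.
#' @export
cohort_params <- function(n_subjects = 27, beta0 = 10, beta_fm = 0.75,
                          beta_ll = -0.08, beta_age = -6, sigma_noise = 6,
                          age_mean = 68, age_sd = 10, age_range = c(30, 95),
                          p_right = 0.7, fm1_shape = c(0.6, 0.8),
                          lesion_center_sd = c(3, 4, 5),
                          lesion_radius_range = c(2, 6),
                          age_cut = 70, seed = 1L) {
  if (n_subjects < 4) {
    abort("`n_subjects` must be >= 4.", class = "cstload_parameter_error")
  }
  if (sigma_noise < 0) {
    abort("`sigma_noise` must be >= 0.", class = "cstload_parameter_error")
  }
  structure(list(n_subjects = as.integer(n_subjects), beta0 = beta0,
                 beta_fm = beta_fm, beta_ll = beta_ll, beta_age = beta_age,
                 sigma_noise = sigma_noise, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range, p_right = p_right,
                 fm1_shape = fm1_shape, lesion_center_sd = lesion_center_sd,
                 lesion_radius_range = lesion_radius_range,
                 age_cut = age_cut, seed = as.integer(seed)),
            class = "cohort_params")
}

# Subject-stable substream: subject i draws from a seed derived from (seed, i)
# by a fixed counter formula, so subject i's data do not depend on n_subjects.
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 99991 * i) %% 2147483629)
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

#' Simulate a stroke cohort against a tract atlas
#'
#' For each subject: draw age, affected hemisphere, an ellipsoidal lesion
#' near the corticospinal bundle of that hemisphere, and clinical scores; the
#' "true" weighted PMD lesion load entering the outcome model is computed with
#' [weighted_lesion_load()] against the supplied atlas — the same scorer the
#' analysis pipeline uses — so stored and recomputed loads agree exactly.
#' Six-month FM-UE follows the linear model in [cohort_params()], rounded and
#' clamped to the 0–66 integer scale (which induces the mild floor/ceiling
#' effects real FM-UE data show).
#'
#' @param params A [cohort_params()].
#' @param atlas A `tract_atlas` covering both hemispheres (or at least every
#'   hemisphere the draw can produce).
#' @return A list with `cohort` (tibble: `subject_id`, `age`, `age_ge70`,
#'   `hemisphere`, `nihss`, `fmue_wk1`, `fmue_m6`, and one `w_<tract>_LL`
#'   column per tract incl. the SMATT union), `lesions` (named list of
#'   [mask_vol()]), and `params` (the generating coefficients, also attached
#'   to the cohort as attribute `generating_coefs`).
#' @export
simulate_cohort <- function(params, atlas) {
  stopifnot(inherits(params, "cohort_params"), inherits(atlas, "tract_atlas"))
  n <- params$n_subjects
  dimg <- atlas$dim
  capsule_r <- c(42, 31, 14)  # reference point near the internal capsule (R)
  lesions <- vector("list", n)
  rows <- vector("list", n)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  for (i in seq_len(n)) {
    set.seed(subject_seed(params$seed, i))
    age <- rtruncnorm1(params$age_mean, params$age_sd,
                       params$age_range[1], params$age_range[2])
    hemi <- if (runif(1) < params$p_right) "R" else "L"
    ctr <- capsule_r
    if (hemi == "L") ctr[1] <- dimg[1] + 1 - ctr[1]
    center <- pmin(pmax(round(rnorm(3, ctr, params$lesion_center_sd)),
                        c(8, 8, 4)), dimg - c(7, 7, 3))
    radii <- runif(3, params$lesion_radius_range[1], params$lesion_radius_range[2])
    lesion <- make_lesion(center, radii, dim = dimg, affine = atlas$affine)
    fm1 <- round(66 * rbeta(1, params$fm1_shape[1], params$fm1_shape[2]))
    nihss <- min(42L, rpois(1, 9))
    eps <- rnorm(1, 0, params$sigma_noise)
    loads <- vapply(c("SMATT", smatt_labels()), function(lab) {
      key <- paste(lab, hemi, sep = "_")
      weighted_lesion_load(lesion, atlas$tracts[[key]],
                           profile = atlas$profiles[[key]])$weighted_ll
    }, numeric(1))
    age70 <- as.integer(age >= params$age_cut)
    fm6 <- params$beta0 + params$beta_fm * fm1 + params$beta_ll * loads[["PMD"]] +
      params$beta_age * age70 + eps
    fm6 <- min(66, max(0, round(fm6)))
    id <- sprintf("sub-%03d", i)
    lesions[[i]] <- lesion
    rows[[i]] <- tibble::tibble(
      subject_id = id, age = age, age_ge70 = age70, hemisphere = hemi,
      nihss = nihss, fmue_wk1 = fm1, fmue_m6 = fm6,
      !!!setNames(as.list(loads), paste0("w_", names(loads), "_LL")))
  }
  cohort <- purrr::list_rbind(rows)
  names(lesions) <- cohort$subject_id
  if (sd(cohort$age_ge70) == 0 || sd(cohort$w_PMD_LL) == 0 ||
      sd(cohort$fmue_wk1) == 0) {
    warn("Degenerate cohort: at least one generative predictor is constant.")
  }
  coefs <- params[c("beta0", "beta_fm", "beta_ll", "beta_age", "sigma_noise")]
  attr(cohort, "generating_coefs") <- coefs
  list(cohort = cohort, lesions = lesions, params = params)
}
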