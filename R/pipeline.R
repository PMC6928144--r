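#' Configuration of a full pipeline run
#'
#' Collects every tunable of the end-to-end analysis in one validated list.
#' In synthetic mode the template, lesions, and cohort are generated in
#' memory from `seed`; otherwise `template_path`, `lesion_dir`, and
#' `cohort_csv` must point at existing inputs on a shared grid.
#'
#' @param output_dir Writable output directory (created if needed).
#' @param synthetic Generate inputs with the synthetic-data module?
#' @param template_path NIfTI template (file + JSON sidecar, or directory of
#'   per-tract volumes); required when `synthetic = FALSE`.
#' @param lesion_dir Directory of per-subject lesion NIfTI files named
#'   `<subject_id>*.nii[.gz]`; required when `synthetic = FALSE`.
#' @param cohort_csv Cohort table CSV; required when `synthetic = FALSE`.
#' @param n_subjects Cohort size in synthetic mode.
#' @param hemisphere_policy `"ipsilesional"` or `"flip"` (see
#'   [lesion_load_table()]).
#' @param age_cut Age dichotomization threshold (years).
#' @param p_enter,p_remove Stepwise thresholds.
#' @param B_dominance Dominance-bootstrap resamples.
#' @param B_coef Coefficient-bootstrap resamples.
#' @param seed Integer seed; required whenever any bootstrap count is
#'   positive.
#' @param munro_breaks Munro band edges (named numeric).
#' @return A validated `run_config` list.
#' @export
run_config <- function(output_dir, synthetic = TRUE, template_path = NULL,
                       lesion_dir = NULL, cohort_csv = NULL, n_subjects = 27,
                       hemisphere_policy = "ipsilesional", age_cut = 70,
                       p_enter = 0.05, p_remove = 0.10, B_dominance = 1000,
                       B_coef = 1000, seed = NULL,
                       munro_breaks = munro_default_breaks()) {
  if ((B_dominance > 0 || B_coef > 0) && is.null(seed)) {
    abort("`seed` must be set whenever a bootstrap count is positive.",
          class = "cstload_config_error")
  }
  if (!synthetic) {
    for (field in c("template_path", "lesion_dir", "cohort_csv")) {
      val <- get(field)
      if (is.null(val)) {
        abort(sprintf("Non-synthetic mode requires `%s`.", field),
              class = "cstload_config_error")
      }
      if (!file.exists(val) && !dir.exists(val)) {
        abort(sprintf("`%s` does not exist: %s", field, val),
              class = "cstload_config_error")
      }
    }
  }
  structure(list(output_dir = output_dir, synthetic = synthetic,
                 template_path = template_path, lesion_dir = lesion_dir,
                 cohort_csv = cohort_csv, n_subjects = n_subjects,
                 hemisphere_policy = hemisphere_policy, age_cut = age_cut,
                 p_enter = p_enter, p_remove = p_remove,
                 B_dominance = B_dominance, B_coef = B_coef,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 munro_breaks = munro_breaks),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path A `.yaml`/`.yml` or `.json` file whose fields match the
#'   arguments of [run_config()].
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  fields <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(fields$munro_breaks)) {
    fields$munro_breaks <- unlist(fields$munro_breaks)
  }
  do.call(run_config, fields)
}

#' Generate and write a complete demonstration dataset
#'
#' Emits, under `dir`: a two-hemisphere synthetic tract template
#' (`template/`, per-tract NIfTI plus a JSON label map), one lesion NIfTI per
#' subject (`lesions/`), the cohort table (`cohort.csv`), and a sidecar JSON
#' recording the true generative coefficients. The default cohort size is 27
#' subjects.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param n_subjects Cohort size.
#' @param params Optional [cohort_params()] overriding the defaults (its
#'   `seed`/`n_subjects` are overridden by the arguments here).
#' @return Invisibly, a list with `template_dir`, `lesion_dir`, `cohort_csv`,
#'   `sidecar`, `atlas`, `cohort`, `lesions`.
#' @export
make_demo_dataset <- function(seed, dir, n_subjects = 27, params = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(params)) params <- cohort_params()
  params$seed <- as.integer(seed)
  params$n_subjects <- as.integer(n_subjects)
  atlas <- make_tract_template(default_tract_specs())
  sim <- simulate_cohort(params, atlas)
  template_dir <- file.path(dir, "template")
  write_tract_atlas(atlas, template_dir)
  lesion_dir <- file.path(dir, "lesions")
  dir.create(lesion_dir, showWarnings = FALSE)
  for (id in names(sim$lesions)) {
    write_mask(sim$lesions[[id]], file.path(lesion_dir, paste0(id, "_lesion.nii.gz")))
  }
  cohort_csv <- file.path(dir, "cohort.csv")
  write.csv(sim$cohort, cohort_csv, row.names = FALSE)
  sidecar <- file.path(dir, "generative_params.json")
  jsonlite::write_json(
    c(attr(sim$cohort, "generating_coefs"),
      list(seed = params$seed, n_subjects = params$n_subjects)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(list(template_dir = template_dir, lesion_dir = lesion_dir,
                 cohort_csv = cohort_csv, sidecar = sidecar, atlas = atlas,
                 cohort = sim$cohort, lesions = sim$lesions))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Stage %s failed: %s", name, conditionMessage(e)),
          class = "cstload_stage_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Executes lesion-load quantification, association statistics, dominance
#' analysis with bootstrap reproducibility, and the stepwise outcome model
#' with diagnostics and coefficient bootstrap, writing every table the
#' downstream report needs plus a run manifest. With the same configuration
#' and seed, all numeric outputs are reproduced byte-identically.
#'
#' Outputs under `config$output_dir`: `lesion_load_long.csv`,
#' `lesion_load_wide.csv`, `lesion_overlay.nii.gz`, `correlations_tidy.csv`,
#' `correlations_matrix.csv` (Spearman rho with p in parentheses),
#' `univariate.csv`, `dominance_conditional.csv` (one row per dot of the
#' dominance plot), `dominance_pairs.csv`, `dominance_reproducibility.csv`,
#' `stepwise_steps.csv`, `stepwise_coefficients.csv` (with bootstrap CIs),
#' `diagnostics.json`, `age_grouping.csv`, and `manifest.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted objects: `cohort`, `ll_table`,
#'   `overlay`, `correlations`, `univariate`, `subset_r2`, `dominance`,
#'   `reproducibility`, `stepwise`, `diagnostics`, `coef_boot`, `paths`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  ll_cols <- paste0("w_", c("SMATT", smatt_labels()), "_LL")

  inputs <- stage("input", {
    if (config$synthetic) {
      atlas <- make_tract_template(default_tract_specs())
      params <- cohort_params(n_subjects = config$n_subjects,
                              age_cut = config$age_cut,
                              seed = config$seed %||% 1L)
      sim <- simulate_cohort(params, atlas)
      list(atlas = atlas, cohort = sim$cohort, lesions = sim$lesions)
    } else {
      atlas <- read_tract_atlas(config$template_path)
      cohort <- tibble::as_tibble(
        utils::read.csv(config$cohort_csv, stringsAsFactors = FALSE))
      files <- list.files(config$lesion_dir, pattern = "\\.nii(\\.gz)?$",
                          full.names = TRUE)
      ids <- sub("(_lesion)?\\.nii(\\.gz)?$", "", basename(files))
      lesions <- setNames(lapply(files, read_mask), ids)
      missing_ids <- setdiff(cohort$subject_id, ids)
      if (length(missing_ids)) {
        abort(paste0("No lesion file for subject(s): ",
                     paste(missing_ids, collapse = ", ")))
      }
      list(atlas = atlas, cohort = cohort,
           lesions = lesions[cohort$subject_id])
    }
  })
  cohort <- inputs$cohort
  if (!"age_ge70" %in% names(cohort)) {
    cohort$age_ge70 <- dichotomize_age(cohort$age, config$age_cut)
  }

  ll <- stage("lesion_load", {
    tbl <- lesion_load_table(inputs$lesions, inputs$atlas,
                             hemisphere = cohort$hemisphere,
                             policy = config$hemisphere_policy)
    wide <- lesion_load_wide(tbl)
    # recomputed loads are authoritative for the analysis table
    cohort <- dplyr::left_join(
      dplyr::select(cohort, -dplyr::any_of(ll_cols)), wide, by = "subject_id")
    overlay <- lesion_overlay_map(inputs$lesions)
    write.csv(tbl, file.path(out, "lesion_load_long.csv"), row.names = FALSE)
    write.csv(wide, file.path(out, "lesion_load_wide.csv"), row.names = FALSE)
    write_overlay_map(overlay, file.path(out, "lesion_overlay.nii.gz"))
    list(tbl = tbl, overlay = overlay, cohort = cohort)
  })
  cohort <- ll$cohort

  assoc <- stage("association_stats", {
    vars <- c("fmue_wk1", ll_cols)
    ct <- correlation_matrix(cohort, vars, munro_breaks = config$munro_breaks)
    uni <- univariate_screen(cohort, "fmue_m6", ll_cols)
    write.csv(ct, file.path(out, "correlations_tidy.csv"), row.names = FALSE)
    rho <- as.matrix(ct, "rho"); pv <- as.matrix(ct, "p_value")
    cells <- matrix(sprintf("%.2f (%s)", rho,
                            ifelse(is.na(pv), "-", sprintf("%.3f", pv))),
                    nrow(rho), dimnames = dimnames(rho))
    write.csv(cells, file.path(out, "correlations_matrix.csv"))
    write.csv(uni, file.path(out, "univariate.csv"), row.names = FALSE)
    list(ct = ct, uni = uni)
  })

  dom <- stage("dominance", {
    X <- as.matrix(cohort[, ll_cols])
    y <- cohort$fmue_m6
    map <- all_subsets_r2(X, y)
    ds <- dominance_stats(map)
    rep_tbl <- if (config$B_dominance > 0) {
      bootstrap_reproducibility(X, y, B = config$B_dominance,
                                seed = config$seed)
    } else NULL
    write.csv(ds$conditional, file.path(out, "dominance_conditional.csv"),
              row.names = FALSE)
    write.csv(ds$pairs, file.path(out, "dominance_pairs.csv"), row.names = FALSE)
    if (!is.null(rep_tbl)) {
      write.csv(rep_tbl, file.path(out, "dominance_reproducibility.csv"),
                row.names = FALSE)
      write.csv(reproducibility_range(rep_tbl),
                file.path(out, "dominance_reproducibility_range.csv"),
                row.names = FALSE)
    }
    list(map = map, ds = ds, rep_tbl = rep_tbl)
  })

  pred <- stage("prediction_model", {
    top_tract <- names(which.max(dom$ds$general))
    candidates <- c("fmue_wk1", top_tract, "age_ge70")
    sw <- stepwise_regression(cohort, "fmue_m6", candidates,
                              p_enter = config$p_enter,
                              p_remove = config$p_remove)
    diag <- if (length(sw$predictors)) model_diagnostics(sw) else NULL
    cb <- if (config$B_coef > 0 && length(sw$predictors)) {
      bootstrap_coefficients(sw, B = config$B_coef, seed = config$seed)
    } else NULL
    write.csv(sw$steps, file.path(out, "stepwise_steps.csv"), row.names = FALSE)
    coefs <- sw$coefficients
    if (!is.null(cb)) {
      coefs <- dplyr::left_join(coefs,
                                dplyr::select(cb, "term", "conf_low", "conf_high"),
                                by = "term")
    }
    coefs <- dplyr::left_join(coefs, dom_semipartial(sw), by = "term")
    write.csv(coefs, file.path(out, "stepwise_coefficients.csv"),
              row.names = FALSE)
    if (!is.null(diag)) {
      jsonlite::write_json(
        list(max_abs_predictor_r = diag$max_abs_r, n_outliers = diag$n_outliers,
             ks = as.list(diag$ks), durbin_watson = diag$dw,
             dw_order = diag$dw_order, shrinkage = diag$shrinkage),
        file.path(out, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
    }
    fig4 <- dplyr::select(cohort, "subject_id",
                          dplyr::all_of(c(top_tract, "fmue_m6", "age_ge70")))
    write.csv(fig4, file.path(out, "age_grouping.csv"), row.names = FALSE)
    list(sw = sw, diag = diag, cb = cb, top_tract = top_tract)
  })

  manifest <- list(package = "cstload",
                   version = as.character(utils::packageVersion("cstload")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
                   n_subjects = nrow(cohort),
                   top_tract = pred$top_tract)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, ll_table = ll$tbl, overlay = ll$overlay,
                 correlations = assoc$ct, univariate = assoc$uni,
                 subset_r2 = dom$map, dominance = dom$ds,
                 reproducibility = dom$rep_tbl, stepwise = pred$sw,
                 diagnostics = pred$diag, coef_boot = pred$cb,
                 paths = list(output_dir = out)))
}

# squared semipartials keyed by coefficient term, for the coefficient table
dom_semipartial <- function(sw) {
  dplyr::rename(sw$semipartial, term = "predictor",
                squared_semipartial = "sr2")
}
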