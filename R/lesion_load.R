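#' Per-slice area profile of a tract
#'
#' The weighting scheme needs, for each axial slice x, the tract's area
#' m(x) (set voxels in that slice) and the maximum slice area m* over the
#' whole tract. Because the corticospinal tract funnels toward the internal
#' capsule, m(x) shrinks on descending slices and the ratio m*/m(x) up-weights
#' lesioned voxels where the tract is narrow.
#'
#' @param tract A non-empty [mask_vol()].
#' @return A list with `m` (integer vector of per-slice areas, indexed by
#'   slice), `m_star` (max slice area), and `z_support` (slices with
#'   `m > 0`).
#' @export
slice_profile <- function(tract) {
  stopifnot(inherits(tract, "mask_vol"))
  m <- as.integer(colSums(tract$data, dims = 2L))
  if (all(m == 0L)) {
    abort("Tract mask is empty; slice profile undefined.",
          class = "cstload_empty_tract_error")
  }
  list(m = m, m_star = max(m), z_support = which(m > 0L))
}

slice_counts <- function(arr) {
  colSums(arr, dims = 2L)
}

#' Slice-weighted lesion load of one lesion in one tract
#'
#' For each axial slice x the lesion-in-tract voxel count n(x) is weighted by
#' m*/m(x), the ratio of the tract's largest slice area to its area at x, and
#' the weighted slice counts are summed:
#' \deqn{wLL = \sum_x n(x) \, m(x^*) / m(x).}
#' Slices where the tract is absent contribute nothing (n(x) is by definition
#' 0 there), so no division by zero can arise. The result is reported in
#' dimensionless "weighted voxels"; multiply by the voxel volume for ml.
#'
#' @param lesion,tract [mask_vol()] objects on the same grid; `tract`
#'   non-empty.
#' @param profile Optional precomputed [slice_profile()] of `tract` (used by
#'   the pipeline to avoid recomputation); validated against `tract`'s grid
#'   only through the caller.
#' @return A list of class `lesion_load_record`: `raw_overlap` (voxels),
#'   `weighted_ll` (weighted voxels), `n_by_slice` (integer vector).
#' @examples
#' # tract with slice areas 10, 5, 2; lesion hits 2 voxels on the 5-area
#' # slice and 1 on the 2-area slice: wLL = 2*(10/5) + 1*(10/2) = 9
#' tr <- array(0L, c(4, 4, 3)); le <- array(0L, c(4, 4, 3))
#' tr[1:10] <- 1L; tr[16 + 1:5] <- 1L; tr[32 + 1:2] <- 1L
#' le[16 + 1:2] <- 1L; le[32 + 1] <- 1L
#' weighted_lesion_load(mask_vol(le), mask_vol(tr))$weighted_ll
#' @export
weighted_lesion_load <- function(lesion, tract, profile = NULL) {
  chk <- check_same_grid(lesion, tract)
  if (!chk$same) {
    abort(paste0("Lesion and tract are not on the same grid: ",
                 paste(chk$report, collapse = "; ")),
          class = "cstload_grid_error")
  }
  if (is.null(profile)) profile <- slice_profile(tract)
  d <- dim(lesion$data)
  # crop to the lesion's occupied slice range: n(x) is zero outside it
  lprof <- slice_counts(lesion$data)
  if (all(lprof == 0)) {
    n <- integer(d[3])
  } else {
    occ <- which(lprof > 0)
    z0 <- occ[1]; z1 <- occ[length(occ)]
    inter <- lesion$data[, , z0:z1, drop = FALSE] * tract$data[, , z0:z1, drop = FALSE]
    n <- integer(d[3])
    n[z0:z1] <- as.integer(slice_counts(inter))
  }
  sup <- profile$m > 0L
  structure(list(raw_overlap = sum(n),
                 weighted_ll = sum(n[sup] * (profile$m_star / profile$m[sup])),
                 n_by_slice = n),
            class = "lesion_load_record")
}

#' Weighted lesion load of every subject in every tract
#'
#' Scores each lesion against the whole-CST union ("SMATT") and the six
#' sub-pathway tracts of the relevant hemisphere, yielding one row per
#' subject x tract.
#'
#' Hemisphere policy: under `"ipsilesional"` (default) each subject is scored
#' against the tracts of their affected hemisphere, which must be supplied;
#' under `"flip"` every lesion is mirrored onto `canonical_hemisphere` with
#' [flip_lr()] when it sits on the other side, and scored there.
#'
#' @param lesions Named list of [mask_vol()] (names are subject ids).
#' @param atlas A `tract_atlas` on the same grid.
#' @param hemisphere Character vector of affected hemispheres (`"L"`/`"R"`),
#'   one per lesion (recycled if length 1). Required for the ipsilesional
#'   policy.
#' @param policy `"ipsilesional"` or `"flip"`.
#' @param canonical_hemisphere Target hemisphere for the `"flip"` policy.
#' @return A tibble with columns `subject_id`, `tract`, `hemisphere_used`,
#'   `raw_overlap`, `weighted_ll`.
#' @export
lesion_load_table <- function(lesions, atlas, hemisphere = NULL,
                              policy = c("ipsilesional", "flip"),
                              canonical_hemisphere = "R") {
  policy <- match.arg(policy)
  stopifnot(inherits(atlas, "tract_atlas"))
  ids <- names(lesions) %||% as.character(seq_along(lesions))
  if (policy == "ipsilesional") {
    if (is.null(hemisphere)) {
      abort("Ipsilesional policy requires an affected `hemisphere` per subject.",
            class = "cstload_policy_error")
    }
    hemisphere <- rep_len(as.character(hemisphere), length(lesions))
    if (anyNA(hemisphere) || !all(hemisphere %in% atlas$hemispheres)) {
      abort("Unknown or missing affected hemisphere under ipsilesional policy.",
            class = "cstload_policy_error")
    }
  } else {
    hemisphere <- rep_len(canonical_hemisphere, length(lesions))
  }
  tract_names <- c("SMATT", smatt_labels())
  rows <- purrr::map2(lesions, seq_along(lesions), function(les, i) {
    h <- hemisphere[i]
    if (policy == "flip") {
      side <- lesion_side(les)
      if (!is.na(side) && side != canonical_hemisphere) les <- flip_lr(les)
    }
    purrr::map(tract_names, function(lab) {
      key <- paste(lab, h, sep = "_")
      rec <- weighted_lesion_load(les, atlas$tracts[[key]],
                                  profile = atlas$profiles[[key]])
      tibble::tibble(subject_id = ids[i], tract = lab, hemisphere_used = h,
                     raw_overlap = rec$raw_overlap,
                     weighted_ll = rec$weighted_ll)
    }) |> purrr::list_rbind()
  })
  purrr::list_rbind(rows)
}

# Side of a lesion in world coordinates: "R" for positive world-x centroid,
# "L" for negative, NA for an empty mask.
lesion_side <- function(les) {
  idx <- which(les$data > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(NA_character_)
  wx <- cbind(idx, 1) %*% t(les$affine[1, , drop = FALSE])
  if (mean(wx) >= 0) "R" else "L"
}

#' Pivot a lesion-load table to one `w_<tract>_LL` column per tract
#'
#' @param ll_table Output of [lesion_load_table()].
#' @return A tibble with `subject_id` and columns `w_SMATT_LL`, `w_M1_LL`, ...
#' @export
lesion_load_wide <- function(ll_table) {
  ll_table |>
    dplyr::mutate(col = paste0("w_", .data$tract, "_LL")) |>
    dplyr::select("subject_id", "col", "weighted_ll") |>
    tidyr::pivot_wider(names_from = "col", values_from = "weighted_ll")
}

#' Voxelwise lesion frequency (overlay) map
#'
#' Sums the binary lesion masks voxelwise, giving at each voxel the number of
#' subjects whose lesion covers it — the standard group lesion-overlay figure.
#'
#' @param lesions List of [mask_vol()] on a shared grid.
#' @return An `overlay_map`: list with `data` (integer 3D array of counts,
#'   max <= number of subjects) and `affine`.
#' @export
lesion_overlay_map <- function(lesions) {
  stopifnot(length(lesions) >= 1L)
  ref <- lesions[[1]]
  for (les in lesions[-1]) {
    chk <- check_same_grid(ref, les)
    if (!chk$same) {
      abort(paste0("Overlay requires a shared grid: ",
                   paste(chk$report, collapse = "; ")),
            class = "cstload_grid_error")
    }
  }
  acc <- Reduce(`+`, lapply(lesions, `[[`, "data"))
  structure(list(data = acc, affine = ref$affine), class = "overlay_map")
}

#' @export
print.overlay_map <- function(x, ...) {
  cat(sprintf("<overlay_map> %s, max overlap %d\n",
              paste(dim(x$data), collapse = "x"), max(x$data)))
  invisible(x)
}

#' Write an overlay map as NIfTI
#'
#' @param map An `overlay_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlay_map <- function(map, path) {
  img <- RNifti::asNifti(map$data)
  RNifti::pixdim(img) <- sqrt(colSums(map$affine[1:3, 1:3]^2))
  RNifti::`sform<-`(img, structure(map$affine, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(map$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}
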