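#' Tract specification for the synthetic template
#'
#' Describes one tube-like corticospinal sub-pathway: a per-slice centerline
#' and an in-plane radius profile that narrows from the cortical slices down
#' toward the internal capsule, mimicking the funnel shape of the pyramidal
#' tract. The z-support is the contiguous slice range `z_range[1]:z_range[2]`.
#'
#' @param label Tract label, one of `"M1"`, `"PMD"`, `"PMV"`, `"SMA"`,
#'   `"preSMA"`, `"S1"`.
#' @param hemisphere `"L"` or `"R"`.
#' @param z_range Integer vector of length 2, bottom and top slice (1-based).
#' @param centerline Numeric matrix with one `(x, y)` row per slice of the
#'   z-support, voxel coordinates.
#' @param radius_profile Strictly positive per-slice radius (voxels), one
#'   value per slice of the z-support.
#' @return A `tract_spec` list.
#' @export
tract_spec <- function(label, hemisphere, z_range, centerline, radius_profile) {
  label <- match.arg(label, smatt_labels())
  hemisphere <- match.arg(hemisphere, c("L", "R"))
  z <- seq.int(z_range[1], z_range[2])
  centerline <- as.matrix(centerline)
  if (nrow(centerline) != length(z) || ncol(centerline) != 2L) {
    abort("`centerline` must have one (x, y) row per slice of the z-support.",
          class = "cstload_geometry_error")
  }
  if (length(radius_profile) != length(z) || any(radius_profile <= 0)) {
    abort("`radius_profile` must be strictly positive over the z-support.",
          class = "cstload_geometry_error")
  }
  structure(list(label = label, hemisphere = hemisphere, z = z,
                 centerline = centerline, radius_profile = radius_profile),
            class = "tract_spec")
}

smatt_labels <- function() c("M1", "PMD", "PMV", "SMA", "preSMA", "S1")

#' Default synthetic corticospinal tract geometry
#'
#' Six sub-pathways per hemisphere on the default 64 x 64 x 40 grid (2 mm
#' isotropic). Each tract starts from a distinct cortical origin on the upper
#' slices and descends, narrowing linearly, toward a common point near the
#' posterior limb of the internal capsule, so adjacent tracts overlap slightly
#' on the lower slices (as the real template does).
#'
#' @param hemisphere `"L"`, `"R"`, or `c("L", "R")` (default both).
#' @return A list of [tract_spec()] objects.
#' @export
default_tract_specs <- function(hemisphere = c("L", "R")) {
  origins <- list( # (x, y) cortical origins, right hemisphere, 64^2 in-plane
    M1     = c(45, 30),
    PMD    = c(44, 38),
    PMV    = c(50, 42),
    SMA    = c(38, 36),
    preSMA = c(38, 44),
    S1     = c(47, 24)
  )
  capsule <- c(42, 31)   # shared lower terminus (right)
  z_range <- c(8L, 36L)
  nz <- z_range[2] - z_range[1] + 1L
  t_frac <- seq(0, 1, length.out = nz)  # 0 at capsule, 1 at cortex
  radii <- list(M1 = c(1.8, 4.2), PMD = c(1.6, 3.8), PMV = c(1.5, 3.2),
                SMA = c(1.6, 3.5), preSMA = c(1.4, 3.0), S1 = c(1.7, 3.8))
  specs <- list()
  for (h in hemisphere) {
    for (lab in smatt_labels()) {
      o <- origins[[lab]]; cp <- capsule
      if (h == "L") { o[1] <- 65 - o[1]; cp[1] <- 65 - cp[1] }
      cl <- cbind(cp[1] + (o[1] - cp[1]) * t_frac,
                  cp[2] + (o[2] - cp[2]) * t_frac)
      r <- radii[[lab]][1] + (radii[[lab]][2] - radii[[lab]][1]) * t_frac
      specs[[paste(lab, h, sep = "_")]] <-
        tract_spec(lab, h, z_range, cl, r)
    }
  }
  specs
}

default_affine <- function(voxel_mm = 2, dim = c(64L, 64L, 40L)) {
  rbind(c(voxel_mm, 0, 0, -voxel_mm * (dim[1] - 1) / 2),
        c(0, voxel_mm, 0, -voxel_mm * (dim[2] - 1) / 2),
        c(0, 0, voxel_mm, -voxel_mm * (dim[3] - 1) / 2),
        c(0, 0, 0, 1))
}

#' Rasterize tract specifications into a tract atlas
#'
#' Each tract is the union of filled discs, one per slice of its z-support:
#' slice `z` holds the disc of `radius_profile[z]` voxels around
#' `centerline[z, ]`. Discs must fit inside the grid. Overlap between
#' neighbouring tracts is permitted (the real template also assigns some
#' voxels to more than one tract).
#'
#' @param specs List of [tract_spec()] objects covering the six labels for at
#'   least one hemisphere.
#' @param dim Grid shape (default `c(64, 64, 40)`).
#' @param affine Voxel-to-world transform (default 2 mm isotropic, centred).
#' @return A `tract_atlas`: list with `tracts` (named list of [mask_vol()],
#'   names `<label>_<hemisphere>`), `dim`, `affine`, `hemispheres`, and
#'   cached slice profiles.
#' @export
make_tract_template <- function(specs, dim = c(64L, 64L, 40L),
                                affine = default_affine(2, dim)) {
  if (inherits(specs, "tract_spec")) specs <- list(specs)
  hemis <- unique(vapply(specs, `[[`, "", "hemisphere"))
  for (h in hemis) {
    labs <- vapply(specs[vapply(specs, `[[`, "", "hemisphere") == h], `[[`, "", "label")
    if (!all(smatt_labels() %in% labs)) {
      abort(sprintf("Hemisphere %s must cover all six tract labels.", h),
            class = "cstload_geometry_error")
    }
  }
  xg <- matrix(seq_len(dim[1]), dim[1], dim[2])
  yg <- matrix(seq_len(dim[2]), dim[1], dim[2], byrow = TRUE)
  tracts <- list()
  for (sp in specs) {
    arr <- array(0L, dim)
    for (k in seq_along(sp$z)) {
      z <- sp$z[k]; cx <- sp$centerline[k, 1]; cy <- sp$centerline[k, 2]
      r <- sp$radius_profile[k]
      if (z < 1 || z > dim[3] || cx - r < 1 || cx + r > dim[1] ||
          cy - r < 1 || cy + r > dim[2]) {
        abort(sprintf("Tract %s_%s: disc at slice %d exceeds grid bounds.",
                      sp$label, sp$hemisphere, z),
              class = "cstload_geometry_error")
      }
      arr[, , z] <- arr[, , z] | ((xg - cx)^2 + (yg - cy)^2 <= r^2)
    }
    tracts[[paste(sp$label, sp$hemisphere, sep = "_")]] <-
      mask_vol(arr, affine)
  }
  new_tract_atlas(tracts, dim, affine)
}

new_tract_atlas <- function(tracts, dim, affine) {
  hemis <- sort(unique(sub("^.*_", "", names(tracts))))
  atlas <- structure(list(tracts = tracts, dim = dim, affine = affine,
                          hemispheres = hemis, profiles = NULL),
                     class = "tract_atlas")
  # precompute union tracts and slice profiles once; reused by every scorer call
  for (h in hemis) {
    members <- tracts[endsWith(names(tracts), paste0("_", h))]
    u <- Reduce(`|`, lapply(members, `[[`, "data"))
    atlas$tracts[[paste0("SMATT_", h)]] <- mask_vol(u * 1L, affine)
  }
  atlas$profiles <- lapply(atlas$tracts, function(tr) slice_profile(tr))
  atlas
}

#' @export
print.tract_atlas <- function(x, ...) {
  cat(sprintf("<tract_atlas> grid %s, hemispheres: %s\n  tracts: %s\n",
              paste(x$dim, collapse = "x"),
              paste(x$hemispheres, collapse = ", "),
              paste(names(x$tracts), collapse = ", ")))
  invisible(x)
}

#' Retrieve one tract (or the whole-CST union) from an atlas
#'
#' @param atlas A `tract_atlas`.
#' @param label Tract label, `"SMATT"` for the voxelwise union.
#' @param hemisphere `"L"` or `"R"`.
#' @return A [mask_vol()].
#' @export
atlas_tract <- function(atlas, label, hemisphere) {
  key <- paste(label, hemisphere, sep = "_")
  tr <- atlas$tracts[[key]]
  if (is.null(tr)) {
    abort(sprintf("Atlas has no tract %s.", key), class = "cstload_schema_error")
  }
  tr
}

#' Read a tract atlas from NIfTI files
#'
#' Accepts either dialect: (i) a directory of per-tract binary volumes named
#' `<label>_<hemisphere>.nii[.gz]`, or (ii) one integer-labelled volume plus a
#' JSON sidecar mapping label integers to `"<label>_<hemisphere>"` names.
#'
#' @param path Directory (dialect i) or NIfTI file (dialect ii).
#' @param labels_json For dialect (ii), path to the JSON label map; defaults
#'   to `<path minus extension>_labels.json`.
#' @return A `tract_atlas`.
#' @export
read_tract_atlas <- function(path, labels_json = NULL) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    keys <- sub("\\.nii(\\.gz)?$", "", basename(files))
    keep <- grepl(paste0("^(", paste(c(smatt_labels(), "SMATT"), collapse = "|"),
                         ")_(L|R)$"), keys)
    files <- files[keep]; keys <- keys[keep]
    keys_use <- !startsWith(keys, "SMATT_")  # union is rederived, not trusted
    if (!length(files[keys_use])) {
      abort(sprintf("No tract NIfTI files found under %s.", path),
            class = "cstload_io_error")
    }
    tracts <- setNames(lapply(files[keys_use], read_mask), keys[keys_use])
  } else {
    vol <- RNifti::readNifti(path)
    if (RNifti::orientation(vol) != "RAS") RNifti::orientation(vol) <- "RAS"
    arr <- as.array(vol)
    aff <- unclass(RNifti::xform(vol)); attributes(aff) <- list(dim = c(4L, 4L))
    if (is.null(labels_json)) {
      labels_json <- paste0(sub("\\.nii(\\.gz)?$", "", path), "_labels.json")
    }
    lab_map <- jsonlite::read_json(labels_json, simplifyVector = TRUE)
    tracts <- lapply(lab_map, function(v) mask_vol((arr == v) * 1L, aff))
    names(tracts) <- names(lab_map)
  }
  g <- tracts[[1]]
  for (nm in names(tracts)[-1]) {
    chk <- check_same_grid(g, tracts[[nm]])
    if (!chk$same) {
      abort(sprintf("Tract %s is not on the shared grid: %s", nm,
                    paste(chk$report, collapse = "; ")),
            class = "cstload_grid_error")
    }
  }
  new_tract_atlas(tracts, dim(g$data), g$affine)
}

#' Write a tract atlas as per-tract NIfTI files plus a JSON label map
#'
#' @param atlas A `tract_atlas`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tract_atlas <- function(atlas, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  keys <- names(atlas$tracts)
  for (key in keys) {
    write_mask(atlas$tracts[[key]], file.path(dir, paste0(key, ".nii.gz")))
  }
  jsonlite::write_json(setNames(as.list(seq_along(keys)), keys),
                       file.path(dir, "labels.json"), auto_unbox = TRUE)
  invisible(dir)
}
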