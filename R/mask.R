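#' Binary mask volumes
#'
#' A `mask_vol` is the package's container for a binary 3D volume on a known
#' voxel grid: a 3D array of 0/1 integers plus a 4x4 voxel-to-world affine in
#' millimetres. The third array axis is the axial (z) slice direction; volumes
#' read from disk are reoriented to the closest-to-RAS convention so that this
#' holds. Voxel indices follow R's 1-based convention.
#'
#' @param data A 3D array whose values are all 0 or 1 (logical arrays are
#'   accepted and coerced).
#' @param affine A 4x4 invertible voxel-to-world transform (mm). Defaults to
#'   the identity.
#' @return A `mask_vol` object: a list with elements `data` (integer 3D array)
#'   and `affine` (4x4 matrix).
#' @examples
#' m <- mask_vol(array(c(1, 0), dim = c(4, 4, 3)))
#' sum(m$data)
#' @export
mask_vol <- function(data, affine = diag(4)) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || any(dim(data) < 1L)) {
    abort("`data` must be a 3D array with every dimension >= 1.",
          class = "cstload_dim_error")
  }
  if (is.logical(data)) data <- data * 1L
  rng <- range(data)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1 ||
      (rng[1] != rng[2] && any(data != 0L & data != 1L))) {
    abort("`data` must be binary (all values 0 or 1); see `read_mask()` for binarization.",
          class = "cstload_value_error")
  }
  storage.mode(data) <- "integer"
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || !is.finite(det_ <- det(affine)) ||
      abs(det_) < .Machine$double.eps) {
    abort("`affine` must be an invertible 4x4 matrix.",
          class = "cstload_affine_error")
  }
  structure(list(data = data, affine = affine), class = "mask_vol")
}

#' @export
print.mask_vol <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask_vol> %d x %d x %d, %d set voxels\n",
              d[1], d[2], d[3], sum(x$data)))
  invisible(x)
}

#' @export
dim.mask_vol <- function(x) dim(x$data)

#' Read a binary mask from a NIfTI file
#'
#' Reads a NIfTI-1 volume, reorients it to the closest-to-RAS axis order (so
#' the third axis is axial), and binarizes it: strictly positive voxels map to
#' 1, zero or negative voxels to 0. If any value other than 0/1 is present a
#' warning reports how many voxels were collapsed, since the analysis assumes
#' genuinely binary lesions and templates.
#'
#' @param path Path to a `.nii` or `.nii.gz` file holding a 3D volume.
#' @return A [mask_vol()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "cstload_io_error")
  }
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) abort(sprintf("Cannot read NIfTI file %s: %s",
                                                    path, conditionMessage(e)),
                                            class = "cstload_io_error"))
  d <- dim(img)
  if (length(d) > 3L) {
    if (all(d[-(1:3)] == 1L)) {
      dim(img) <- d[1:3]
    } else {
      abort(sprintf("Expected a 3D volume, got %dD in %s.", length(d), path),
            class = "cstload_dim_error")
    }
  }
  if (RNifti::orientation(img) != "RAS") {
    RNifti::orientation(img) <- "RAS"
    inform(sprintf("Reoriented %s to RAS.", basename(path)))
  }
  arr <- as.array(img)
  nonbin <- sum(arr != 0 & arr != 1)
  if (nonbin > 0) {
    warn(sprintf("Binarized %d non-binary voxel(s) in %s (value > 0 -> 1).",
                 nonbin, basename(path)))
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  mask_vol((arr > 0) * 1L, aff)
}

#' Write a binary mask to a NIfTI file
#'
#' The inverse of [read_mask()]: `read_mask(write_mask(v, p))` reproduces `v`
#' bit-exactly in its data and to float32 serialization precision in its
#' affine. Data are stored as `uint8`.
#'
#' @param vol A [mask_vol()].
#' @param path Output path; the parent directory must exist.
#' @return `path`, invisibly.
#' @export
write_mask <- function(vol, path) {
  stopifnot(inherits(vol, "mask_vol"))
  if (!dir.exists(dirname(path))) {
    abort(sprintf("Directory does not exist: %s", dirname(path)),
          class = "cstload_io_error")
  }
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  RNifti::`sform<-`(img, structure(vol$affine, code = 2L)) -> img
  RNifti::`qform<-`(img, structure(vol$affine, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Check that two volumes share a voxel grid
#'
#' Overlap arithmetic is only meaningful on a shared grid; registration is out
#' of scope, so grids must already match. Shapes must be equal and affines
#' must agree elementwise within `tol` (absolute), which absorbs float
#' serialization noise.
#'
#' @param a,b [mask_vol()] objects.
#' @param tol Absolute per-element affine tolerance.
#' @return A list with `same` (logical) and `report` (character vector naming
#'   each mismatch; empty when `same` is `TRUE`).
#' @export
check_same_grid <- function(a, b, tol = 1e-4) {
  stopifnot(inherits(a, "mask_vol"), inherits(b, "mask_vol"))
  report <- character()
  if (!identical(dim(a$data), dim(b$data))) {
    report <- c(report, sprintf("shape mismatch: (%s) vs (%s)",
                                paste(dim(a$data), collapse = ","),
                                paste(dim(b$data), collapse = ",")))
  }
  dd <- abs(a$affine - b$affine)
  if (any(dd > tol)) {
    bad <- which(dd > tol, arr.ind = TRUE)
    report <- c(report, sprintf("affine[%d,%d] differs by %.6g",
                                bad[, 1], bad[, 2], dd[bad]))
  }
  list(same = length(report) == 0L, report = report)
}

same_grid <- function(a, b, tol = 1e-4) check_same_grid(a, b, tol)$same

#' Mirror a mask about the midsagittal plane of its grid
#'
#' Flips the volume along the voxel axis that carries the world left-right
#' direction, identified from the affine's first row. The operation is an
#' involution and conserves the set-voxel count; a voxel at index `i` along an
#' axis of length `X` moves to `X + 1 - i`. Used to map lesions onto a
#' canonical hemisphere before scoring against a single-hemisphere template.
#'
#' @param vol A [mask_vol()].
#' @return The mirrored [mask_vol()] on the same grid.
#' @export
flip_lr <- function(vol) {
  stopifnot(inherits(vol, "mask_vol"))
  row_x <- abs(vol$affine[1, 1:3])
  j <- which.max(row_x)
  if (row_x[j] <= max(row_x[-j]) + 1e-8) {
    abort("Affine has no dominant left-right voxel axis; cannot mirror.",
          class = "cstload_orientation_error")
  }
  idx <- rep(list(quote(expr = )), 3)
  idx[[j]] <- rev(seq_len(dim(vol$data)[j]))
  flipped <- do.call(`[`, c(list(vol$data), idx, list(drop = FALSE)))
  mask_vol(flipped, vol$affine)
}
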