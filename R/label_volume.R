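#' Binary label volume with a voxel-to-world affine
#'
#' A `label_volume` holds a 3D binary occupancy grid together with the 4x4
#' affine that maps 0-based voxel-centre indices to world coordinates in mm
#' (the NIfTI convention). All downstream geometry (meshes, contours,
#' metrics) lives in world mm, so results are independent of the voxel grid
#' the segmentation happened to be stored on.
#'
#' @param data 3D array; any numeric/integer/logical values, coerced to
#'   binary with values > 0 mapped to 1.
#' @param affine 4x4 voxel-index-to-world transform; last row `(0,0,0,1)`.
#'   Defaults to a diagonal scaling by `spacing`.
#' @param spacing per-axis voxel size in mm, used only when `affine` is not
#'   given.
#' @return An object of class `label_volume` with elements `data` (integer
#'   0/1 array), `affine` and `spacing` (derived from the affine columns).
#' @export
label_volume <- function(data, affine = NULL, spacing = c(1, 1, 1)) {
  if (length(dim(data)) != 3L)
    fs_abort("`data` must be a 3D array", "fastsurf_invalid_input")
  if (is.null(affine)) {
    fs_stopifnot(length(spacing) == 3 && all(spacing > 0),
                 "`spacing` must be 3 positive values",
                 "fastsurf_invalid_input")
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4, 4)) ||
      max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-12)
    fs_abort("`affine` must be 4x4 with last row (0,0,0,1)",
             "fastsurf_invalid_input")
  if (abs(det(affine[1:3, 1:3])) < 1e-12)
    fs_abort("`affine` is singular", "fastsurf_invalid_input")
  arr <- array(as.integer(data > 0), dim = dim(data))
  structure(
    list(data = arr, affine = affine,
         spacing = sqrt(colSums(affine[1:3, 1:3]^2))),
    class = "label_volume")
}

#' @exportS3Method print label_volume
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s voxels, spacing %s mm, %d foreground\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              sum(x$data)))
  invisible(x)
}

#' Validate a label volume for the reconstruction path
#'
#' Checks the invariants the fairing pipeline relies on: binary data, an
#' invertible affine, and a foreground forming a single 26-connected
#' component.
#'
#' @param vol a [label_volume].
#' @param require_foreground error on an all-zero volume (default `TRUE`).
#' @return `vol`, invisibly.
#' @export
validate_label_volume <- function(vol, require_foreground = TRUE) {
  fs_stopifnot(inherits(vol, "label_volume"), "not a label_volume",
               "fastsurf_invalid_input")
  n_fg <- sum(vol$data)
  if (n_fg == 0L) {
    if (require_foreground)
      fs_abort("label volume has empty foreground",
               "fastsurf_empty_segmentation")
    return(invisible(vol))
  }
  if (count_components(vol) > 1L)
    fs_abort("foreground is not a single 26-connected component",
             "fastsurf_multi_component")
  invisible(vol)
}

count_components <- function(vol) {
  labels <- cpp_label_components(array(vol$data > 0, dim(vol$data)),
                                 as.integer(dim(vol$data)))
  max(labels)
}

#' Map 0-based voxel indices to world mm
#'
#' @param vol a [label_volume].
#' @param idx n x 3 matrix of 0-based voxel indices (may be fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  h <- cbind(idx, 1) %*% t(vol$affine)
  h[, 1:3, drop = FALSE]
}

#' Read a binary label volume from NIfTI
#'
#' Values > 0 are coerced to foreground. The voxel-to-world affine is taken
#' from the image xform (sform/qform).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [label_volume].
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  arr <- array(as.numeric(img), dim = dim(img))
  label_volume(arr, affine = matrix(as.numeric(aff), 4, 4))
}

#' Write a label volume to NIfTI
#'
#' @param vol a [label_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  img <- RNifti::asNifti(array(as.integer(vol$data), dim(vol$data)),
                         pixdim = vol$spacing)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
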