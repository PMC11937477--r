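#' Image volume container
#'
#' A light 3D scalar volume: a numeric array with isotropic-or-not voxel
#' spacing in mm, a world-space origin, and a modality tag. World coordinates
#' of voxel (i, j, k) (1-based array indices) are
#' `origin + (c(i, j, k) - 1) * spacing`, matching the NIfTI affine written by
#' [write_volume()].
#'
#' @param data numeric 3D array of intensities.
#' @param spacing voxel size in mm, length 3 (or scalar, recycled).
#' @param modality one of `"CT-like"`, `"UTE-like"`, `"T2w-like"`, or any tag.
#' @param origin world position (mm) of voxel (1, 1, 1).
#' @return An object of class `brw_volume`.
#' @export
brw_volume <- function(data, spacing = c(1, 1, 1), modality = "generic",
                       origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  spacing <- rep_len(as.numeric(spacing), 3)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("voxel spacing must be positive and finite", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, modality = modality,
         origin = rep_len(as.numeric(origin), 3)),
    class = "brw_volume"
  )
}

#' @export
print.brw_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brw_volume %s> %d x %d x %d voxels, spacing %s mm\n",
              x$modality, d[1], d[2], d[3],
              paste(format(x$spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  intensity range [%.3g, %.3g]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.brw_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "brw_volume")

#' Convert voxel indices to world coordinates (mm)
#'
#' @param vol a [brw_volume()].
#' @param ijk matrix (n x 3) or vector of 1-based voxel indices (may be
#'   fractional).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk - 1, 2, vol$spacing, `*`), 2, vol$origin, `+`)
}

#' Convert world coordinates (mm) to (fractional) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz matrix (n x 3) or vector of world coordinates in mm.
#' @return n x 3 matrix of 1-based fractional voxel indices.
#' @export
world_to_voxel <- function(vol, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  sweep(sweep(xyz, 2, vol$origin, `-`), 2, vol$spacing, `/`) + 1
}

#' Write a volume to a NIfTI file
#'
#' The affine is diagonal with the voxel spacing, translated by the origin.
#'
#' @param vol a [brw_volume()].
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI file as a volume
#'
#' @param path NIfTI file path.
#' @param modality modality tag to attach.
#' @return A [brw_volume()].
#' @export
read_volume <- function(path, modality = "generic") {
  img <- tryCatch(RNifti::readNifti(path), error = function(e) {
    stop(sprintf("cannot read NIfTI volume '%s': %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  arr <- as.array(img)
  if (length(dim(arr)) != 3) stop("expected a 3D volume", call. = FALSE)
  arr <- array(as.numeric(arr), dim(arr))   # drop RNifti header attributes
  sp <- RNifti::pixdim(img)
  brw_volume(arr, spacing = rep_len(sp, 3), modality = modality)
}

#' Write a deformation field as 4D NIfTI (3 displacement components, mm)
#'
#' @param field array (nx, ny, nz, 3) of displacements in mm.
#' @param spacing voxel spacing in mm.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, spacing, path) {
  stopifnot(length(dim(field)) == 4, dim(field)[4] == 3)
  img <- RNifti::asNifti(field)
  RNifti::pixdim(img) <- c(rep_len(spacing, 3), 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}
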