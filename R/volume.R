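# Volumetric containers and NIfTI I/O.

persi_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "persi_error")))
}

#' Construct a 3D volume
#'
#' A `volume3d` is the package's carrier for PET images, tissue probability
#' maps, and atlas label images: a 3D numeric array plus voxel spacing in mm
#' and a 4x4 voxel-to-world affine.
#'
#' @param data numeric 3D array; must contain no `NaN`.
#' @param voxel_size numeric length-3, voxel edge lengths in mm (all > 0).
#' @param affine 4x4 voxel-index-to-mm matrix; defaults to a diagonal
#'   scaling by `voxel_size`.
#' @return An object of class `volume3d` with elements `data`, `voxel_size`
#'   and `affine`.
#' @export
volume3d <- function(data, voxel_size = c(1, 1, 1), affine = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    persi_error("`data` must be a 3D array", "persi_dim_error")
  if (any(dim(data) < 1L))
    persi_error("all three volume dimensions must be >= 1", "persi_dim_error")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0))
    persi_error("`voxel_size` must be 3 strictly positive values", "persi_geometry_error")
  n_nan <- sum(is.nan(data))
  if (n_nan > 0L)
    persi_error(sprintf("volume contains %d NaN voxel(s)", n_nan),
                "persi_nan_error", n_nan = n_nan)
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  affine <- unclass(as.matrix(affine))[1:4, 1:4]
  attributes(affine) <- list(dim = c(4L, 4L))
  structure(list(data = data, voxel_size = voxel_size, affine = affine),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, %s mm spacing, range [%g, %g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$voxel_size, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' Read a 3D NIfTI volume
#'
#' Reads a NIfTI-1 image, applies any scaling slope/intercept, and validates
#' that the result is a 3D volume free of `NaN`s.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume3d] with voxel size and affine taken from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    persi_error(sprintf("file not found: %s", path), "persi_io_error")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    persi_error(sprintf("expected a 3D image, got %dD: %s", length(d), path),
                "persi_dim_error")
  affine <- unclass(RNifti::xform(img))
  a <- array(as.numeric(img), dim = d)  # plain array, scaling already applied
  volume3d(a, voxel_size = abs(RNifti::pixdim(img))[1:3], affine = affine)
}

#' Write a volume as NIfTI
#'
#' Data are stored as 32-bit float with identity scaling; geometry is carried
#' in the qform/sform.
#'
#' @param vol a [volume3d].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Construct a binary mask paired with a volume geometry
#'
#' @param data logical 3D array.
#' @param voxel_size voxel spacing in mm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(data, voxel_size = c(1, 1, 1)) {
  if (!is.array(data) || length(dim(data)) != 3L || !is.logical(data))
    persi_error("mask `data` must be a logical 3D array", "persi_dim_error")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 n_voxels = sum(data)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s voxels, %d in mask\n",
              paste(dim(x$data), collapse = "x"), x$n_voxels))
  invisible(x)
}

#' Binarize a tissue probability map
#'
#' Thresholds a probabilistic segmentation (values in \[0, 1\]) to a binary
#' mask. Voxels strictly above the threshold are retained; the default 0.9 is
#' the conventional cut for deriving a conservative white-matter mask from a
#' T1 segmentation.
#'
#' @param prob a [volume3d] of tissue probabilities in \[0, 1\]
#'   (tolerance 1e-6).
#' @param threshold scalar in (0, 1); default 0.9.
#' @return A [binary_mask] true where `prob > threshold`.
#' @export
binarize_segmentation <- function(prob, threshold = 0.9) {
  stopifnot(inherits(prob, "volume3d"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    persi_error("`threshold` must be a single value in (0, 1)", "persi_parameter_error")
  rng <- range(prob$data)
  if (rng[1] < -1e-6 || rng[2] > 1 + 1e-6)
    persi_error(sprintf("probability values outside [0, 1]: range [%g, %g]",
                        rng[1], rng[2]), "persi_probability_error")
  mask <- prob$data > threshold
  if (!any(mask))
    persi_error(sprintf("no voxels exceed threshold %g; mask is empty", threshold),
                "persi_degenerate_mask_error")
  binary_mask(mask, voxel_size = prob$voxel_size)
}
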