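# Reference regions and count normalization.

new_reference_region <- function(mask, mean_intensity, method,
                                 window = NULL) {
  if (!is.finite(mean_intensity) || mean_intensity <= 0)
    persi_error("reference mean intensity must be strictly positive",
                "persi_normalization_error")
  structure(list(mask = mask, mean_intensity = mean_intensity,
                 n_voxels = mask$n_voxels, method = method, window = window),
            class = "reference_region")
}

#' @export
print.reference_region <- function(x, ...) {
  cat(sprintf("<reference_region> method %s, %d voxels, mean %.5g\n",
              x$method, x$n_voxels, x$mean_intensity))
  if (!is.null(x$window))
    cat(sprintf("  intensity window [%.5g, %.5g]\n", x$window[1], x$window[2]))
  invisible(x)
}

#' Select the PERSI white-matter reference region
#'
#' Retains the white-matter voxels whose intensity falls inside the window of
#' full width FWHM centred on the fitted lower peak,
#' `[mu_low - FWHM/2, mu_low + FWHM/2]` with
#' `FWHM = fwhm_from_sigma(sigma_low)`, discarding the higher-intensity
#' (spill-in contaminated) voxels. The window is closed at both ends.
#'
#' @param pet a [volume3d].
#' @param wm_mask a [binary_mask] of white matter on the same grid.
#' @param fit a `bimodal_fit` of the WM histogram.
#' @param min_voxels minimum retained voxel count (default 100).
#' @return A `reference_region` with `method = "persi_wm"`, its voxel mask,
#'   retained-voxel mean and the intensity window used.
#' @export
select_reference_voxels <- function(pet, wm_mask, fit, min_voxels = 100L) {
  stopifnot(inherits(pet, "volume3d"), inherits(wm_mask, "binary_mask"),
            inherits(fit, "bimodal_fit"))
  if (!isTRUE(fit$converged))
    persi_error("bimodal fit did not converge; no reference derivable",
                "persi_fit_error")
  half <- fwhm_from_sigma(fit$sigma_low) / 2
  lo <- fit$mu_low - half
  hi <- fit$mu_low + half
  sel <- wm_mask$data & pet$data >= lo & pet$data <= hi
  n <- sum(sel)
  if (n < min_voxels)
    persi_error(sprintf("only %d voxels in the reference window (minimum %d)",
                        n, min_voxels),
                "persi_sparse_reference_error", n_retained = n)
  new_reference_region(binary_mask(sel, voxel_size = pet$voxel_size),
                       mean(pet$data[sel]), method = "persi_wm",
                       window = c(lo, hi))
}

#' Whole-cerebellum reference region
#'
#' The conventional comparison reference: the mean intensity over every voxel
#' of the atlas' `whole_cerebellum` region.
#'
#' @param vol a [volume3d].
#' @param atlas an `roi_atlas` containing `whole_cerebellum`.
#' @return A `reference_region` with `method = "whole_cerebellum"`.
#' @export
cerebellum_reference <- function(vol, atlas) {
  m <- region_mask(atlas, "whole_cerebellum")
  if (m$n_voxels == 0L)
    persi_error("whole_cerebellum region is empty", "persi_atlas_error")
  new_reference_region(m, mean(vol$data[m$data]), method = "whole_cerebellum")
}

#' Normalize a volume by a reference region
#'
#' Divides every voxel by the reference mean intensity, producing an SUVR
#' image: the mean of the output over the reference mask is 1.
#'
#' @param pet a [volume3d].
#' @param ref a `reference_region` with positive mean.
#' @return A [volume3d] of normalized intensities.
#' @export
normalize_volume <- function(pet, ref) {
  stopifnot(inherits(pet, "volume3d"), inherits(ref, "reference_region"))
  if (!is.finite(ref$mean_intensity) || ref$mean_intensity <= 0)
    persi_error("reference mean must be strictly positive",
                "persi_normalization_error")
  volume3d(pet$data / ref$mean_intensity, voxel_size = pet$voxel_size,
           affine = pet$affine)
}
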