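# Intensity histograms over masked voxels.

#' Histogram of masked voxel intensities
#'
#' Bins the PET intensities of all voxels in `mask` into `n_bins` equal-width
#' bins spanning the observed \[min, max\]. The maximum value is included in
#' the last bin, so counts always sum to the mask cardinality.
#'
#' @param pet a [volume3d].
#' @param mask a [binary_mask] on the same grid.
#' @param n_bins number of bins (default 128).
#' @return An object of class `intensity_histogram` with `bin_edges`
#'   (length `n_bins + 1`), `mids`, `counts`, `bin_width` and `n_voxels`.
#' @export
build_histogram <- function(pet, mask, n_bins = 128L) {
  stopifnot(inherits(pet, "volume3d"), inherits(mask, "binary_mask"))
  if (!identical(dim(pet$data), dim(mask$data)))
    persi_error("PET volume and mask grids differ in shape", "persi_geometry_error")
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L)
    persi_error("`n_bins` must be a positive integer", "persi_parameter_error")
  x <- pet$data[mask$data]
  if (length(x) == 0L)
    persi_error("mask is empty", "persi_degenerate_mask_error")
  if (any(!is.finite(x)))
    persi_error("masked intensities contain non-finite values", "persi_nan_error")
  rng <- range(x)
  if (rng[2] - rng[1] <= 0)
    persi_error("masked region has constant intensity; histogram is degenerate",
                "persi_degenerate_histogram_error")
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  width <- (rng[2] - rng[1]) / n_bins
  bin <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  structure(list(bin_edges = edges,
                 mids = (edges[-1L] + edges[-(n_bins + 1L)]) / 2,
                 counts = counts, bin_width = width, n_voxels = length(x)),
            class = "intensity_histogram")
}

#' @export
print.intensity_histogram <- function(x, ...) {
  cat(sprintf("<intensity_histogram> %d bins over [%g, %g], %d voxels\n",
              length(x$counts), x$bin_edges[1],
              x$bin_edges[length(x$bin_edges)], x$n_voxels))
  invisible(x)
}

# weighted quantile of binned data, used for fit initialization
histogram_quantile <- function(hist, p) {
  cw <- cumsum(hist$counts) / hist$n_voxels
  idx <- which(cw >= p)[1]
  hist$mids[idx]
}
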