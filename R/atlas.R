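# ROI atlas handling: label volumes, region lookup, regional means.

#' Names of the eight analysis regions
#'
#' The cortical regions over which SUVRs are computed: the four lobes, the
#' anterior and posterior cingulate, the precuneus, and Braak stage I/II
#' (entorhinal cortex plus hippocampus, pooled).
#'
#' @return Character vector of the 8 region names.
#' @export
persi_regions <- function() {
  c("frontal_lobe", "parietal_lobe", "temporal_lobe", "occipital_lobe",
    "anterior_cingulate", "posterior_cingulate", "precuneus", "braak_1_2")
}

required_regions <- function() c(persi_regions(), "whole_cerebellum")

#' Build an ROI atlas from a label volume
#'
#' Couples an integer-labelled parcellation volume with a mapping from region
#' names to label sets. A region may pool several labels (Braak I/II pools the
#' entorhinal and hippocampal labels into a single region). The mapping must
#' cover the 8 analysis regions plus `whole_cerebellum`.
#'
#' @param label_volume a [volume3d] of non-negative integer labels
#'   (0 = background).
#' @param region_spec named list: region name -> integer vector of labels.
#' @return An object of class `roi_atlas` with elements `labels` (integer
#'   array), `region_map`, `voxel_size`, and per-region voxel counts.
#' @export
load_atlas <- function(label_volume, region_spec) {
  stopifnot(inherits(label_volume, "volume3d"))
  lab <- label_volume$data
  if (any(lab < 0) || max(abs(lab - round(lab))) > 1e-6)
    persi_error("label volume must contain non-negative integers",
                "persi_atlas_error")
  lab <- array(as.integer(round(lab)), dim = dim(lab))
  if (!is.list(region_spec) || is.null(names(region_spec)))
    persi_error("`region_spec` must be a named list of label vectors",
                "persi_atlas_error")
  region_spec <- lapply(region_spec, function(v) as.integer(v))
  missing <- setdiff(required_regions(), names(region_spec))
  if (length(missing) > 0L)
    persi_error(sprintf("region_spec is missing required regions: %s",
                        paste(missing, collapse = ", ")),
                "persi_atlas_error", missing_regions = missing)

  counts <- vapply(region_spec, function(lbls) sum(lab %in% lbls), integer(1))
  empty <- names(counts)[counts == 0L]
  if (length(empty) > 0L)
    persi_error(sprintf("regions with zero voxels in label volume: %s",
                        paste(empty, collapse = ", ")),
                "persi_atlas_error", empty_regions = empty)

  # labels shared between two named regions are legal but worth flagging
  all_lbls <- unlist(region_spec, use.names = FALSE)
  dup <- unique(all_lbls[duplicated(all_lbls)])
  if (length(dup) > 0L)
    warning(sprintf("labels assigned to more than one region: %s",
                    paste(dup, collapse = ", ")))

  structure(list(labels = lab, region_map = region_spec,
                 voxel_size = label_volume$voxel_size,
                 region_counts = counts),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("<roi_atlas> %s voxels, %d regions\n",
              paste(dim(x$labels), collapse = "x"), length(x$region_map)))
  for (r in names(x$region_map))
    cat(sprintf("  %-20s labels {%s}  %d voxels\n", r,
                paste(x$region_map[[r]], collapse = ","),
                x$region_counts[[r]]))
  invisible(x)
}

#' Logical mask of one atlas region
#'
#' @param atlas an `roi_atlas`.
#' @param region region name present in the atlas.
#' @return A [binary_mask] over the union of the region's labels.
#' @export
region_mask <- function(atlas, region) {
  stopifnot(inherits(atlas, "roi_atlas"))
  if (!region %in% names(atlas$region_map))
    persi_error(sprintf("unknown region: %s", region), "persi_lookup_error")
  binary_mask(array(atlas$labels %in% atlas$region_map[[region]],
                    dim = dim(atlas$labels)),
              voxel_size = atlas$voxel_size)
}

#' Mean intensity over an atlas region
#'
#' Arithmetic mean of the volume's intensities over all voxels carrying any of
#' the region's labels (a pooled mean, not a per-label average).
#'
#' @param vol a [volume3d] sharing the atlas grid.
#' @param atlas an `roi_atlas`.
#' @param region region name.
#' @return Scalar mean intensity.
#' @export
roi_mean <- function(vol, atlas, region) {
  stopifnot(inherits(vol, "volume3d"))
  if (!identical(dim(vol$data), dim(atlas$labels)))
    persi_error("volume and atlas grids differ in shape", "persi_geometry_error")
  m <- region_mask(atlas, region)
  mean(vol$data[m$data])
}
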