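# Regional SUVR computation per subject against both reference methods.

#' Control parameters for SUVR computation
#'
#' @param wm_threshold WM probability threshold for the binary WM mask
#'   (default 0.9).
#' @param n_bins bins for the WM intensity histogram (default 128).
#' @param fwhm_mm Gaussian smoothing FWHM in mm (default 8).
#' @param smooth apply smoothing before ROI averaging (default `TRUE`;
#'   disable for ground-truth checks against unblurred phantoms).
#' @param min_ref_voxels minimum PERSI reference voxel count (default 100).
#' @param methods reference methods to run.
#' @param max_failure_rate per-subject failure rate above which the whole
#'   cohort run is aborted (default 0.2).
#' @param fit_options a [fit_control] for the bimodal fit.
#' @param verbose print one status line per subject.
#' @return A list of class `suvr_control`.
#' @export
suvr_control <- function(wm_threshold = 0.9, n_bins = 128L, fwhm_mm = 8,
                         smooth = TRUE, min_ref_voxels = 100L,
                         methods = c("persi_wm", "whole_cerebellum"),
                         max_failure_rate = 0.2,
                         fit_options = fit_control(),
                         verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  structure(list(wm_threshold = wm_threshold, n_bins = as.integer(n_bins),
                 fwhm_mm = fwhm_mm, smooth = isTRUE(smooth),
                 min_ref_voxels = as.integer(min_ref_voxels),
                 methods = methods, max_failure_rate = max_failure_rate,
                 fit_control = fit_options, verbose = isTRUE(verbose)),
            class = "suvr_control")
}

# references + fit diagnostics for one already-loaded subject
subject_references <- function(pet, wm_prob, atlas, control) {
  out <- list(refs = list(), fit = NULL)
  if ("persi_wm" %in% control$methods) {
    wm_mask <- binarize_segmentation(wm_prob, control$wm_threshold)
    h <- build_histogram(pet, wm_mask, control$n_bins)
    fit <- fit_bimodal(h, control$fit_control)
    out$refs$persi_wm <- select_reference_voxels(pet, wm_mask, fit,
                                                 control$min_ref_voxels)
    out$fit <- fit
  }
  if ("whole_cerebellum" %in% control$methods)
    out$refs$whole_cerebellum <- cerebellum_reference(pet, atlas)
  out
}

#' Compute the cohort SUVR table
#'
#' For every subject in the manifest, derives the requested reference
#' regions from the unsmoothed PET volume, then computes the mean SUVR of
#' each of the eight analysis regions on the count-normalized, smoothed
#' image. Because Gaussian convolution is linear and normalization divides by
#' a scalar, the PET volume is smoothed once and divided by each reference
#' mean, which is identical to smoothing each normalized image.
#'
#' Subjects whose PERSI fit fails are excluded and logged rather than
#' aborting the run; if more than `max_failure_rate` of subjects fail, a
#' cohort error is raised.
#'
#' @param manifest a `cohort_manifest` (see [read_manifest]).
#' @param atlas an `roi_atlas` on the common grid.
#' @param control a [suvr_control].
#' @return A `data.frame` of class `suvr_table` in long format
#'   (`subject_id`, `group`, `region`, `method`, `suvr`), with attributes
#'   `fits` (per-subject fit diagnostics) and `failures` (named list of
#'   error messages).
#' @export
compute_suvr_table <- function(manifest, atlas, control = suvr_control()) {
  stopifnot(inherits(atlas, "roi_atlas"))
  regions <- persi_regions()
  rows <- vector("list", nrow(manifest))
  fits <- list()
  failures <- list()

  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$subject_id[i]
    grp <- manifest$group[i]
    res <- tryCatch({
      pet <- read_volume(manifest$pet_path[i])
      wm <- read_volume(manifest$wm_path[i])
      if (!identical(dim(pet$data), dim(atlas$labels)) ||
          !identical(dim(wm$data), dim(atlas$labels)))
        persi_error(sprintf("subject %s: grid shape differs from atlas", sid),
                    "persi_geometry_error")
      sr <- subject_references(pet, wm, atlas, control)
      smoothed <- if (control$smooth) gaussian_smooth(pet, control$fwhm_mm) else pet
      roi_means <- vapply(regions, function(r) roi_mean(smoothed, atlas, r),
                          numeric(1))
      recs <- do.call(rbind, lapply(names(sr$refs), function(m) {
        data.frame(subject_id = sid, group = grp, region = regions,
                   method = m, suvr = unname(roi_means) / sr$refs[[m]]$mean_intensity,
                   stringsAsFactors = FALSE)
      }))
      list(recs = recs, fit = sr$fit, refs = sr$refs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[sid]] <- conditionMessage(res)
      if (control$verbose) message(sprintf("  %s [%s]: FAILED (%s)", sid, grp,
                                           conditionMessage(res)))
      next
    }
    rows[[i]] <- res$recs
    if (!is.null(res$fit)) {
      fits[[sid]] <- c(res$fit[c("amp_low", "mu_low", "sigma_low",
                                 "amp_high", "mu_high", "sigma_high", "rss",
                                 "converged", "unimodal_fallback")],
                       list(n_reference_voxels = res$refs$persi_wm$n_voxels,
                            reference_mean = res$refs$persi_wm$mean_intensity))
    }
    if (control$verbose) message(sprintf("  %s [%s]: ok", sid, grp))
  }

  n_fail <- length(failures)
  if (n_fail / max(nrow(manifest), 1L) > control$max_failure_rate)
    persi_error(sprintf("%d of %d subjects failed (rate above %.0f%%)",
                        n_fail, nrow(manifest), 100 * control$max_failure_rate),
                "persi_cohort_error")
  tab <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(tab) <- NULL
  structure(tab, class = c("suvr_table", "data.frame"),
            fits = fits, failures = failures)
}

#' Per-group SUVR summary
#'
#' Mean and SD of SUVR per (group, region, method), the per-panel numbers of
#' a group-comparison bar chart.
#'
#' @param table a `suvr_table`.
#' @return A data.frame with columns `group`, `region`, `method`,
#'   `mean_suvr`, `sd_suvr`, `n`.
#' @export
suvr_summary <- function(table) {
  agg <- stats::aggregate(suvr ~ group + region + method,
                          data = as.data.frame(table),
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                              n = length(v)))
  out <- data.frame(agg[c("group", "region", "method")],
                    mean_suvr = agg$suvr[, "mean"], sd_suvr = agg$suvr[, "sd"],
                    n = as.integer(agg$suvr[, "n"]))
  out[order(out$method, out$region, out$group), , drop = FALSE]
}
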