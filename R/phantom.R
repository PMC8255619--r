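# Seeded synthetic phantom cohorts with full ground truth.
#
# The phantom emulates the statistical structure the PERSI analysis relies
# on, not anatomy: a cerebral ellipsoid with a white-matter core, a
# partial-volume buffer shell, a cortical shell split into the eight analysis
# regions, a CSF rim, and a separate cerebellar ellipsoid. Patient groups
# receive spill-in contamination in the WM voxels nearest the cortex, which
# makes the WM intensity histogram bimodal; controls stay unimodal.

#' Default per-group regional uptake ratios
#'
#' Target SUVRs (uptake relative to clean white matter) per region and
#' diagnostic group. Controls sit slightly below 1, AD regions are elevated
#' by 20-40% with the largest effects in the temporal lobe and Braak I/II,
#' and MCI is intermediate (midway between HC and AD).
#'
#' @return An 8 x 3 numeric matrix, rows [persi_regions()], columns
#'   HC/MCI/AD.
#' @export
default_uptake_ratios <- function() {
  hc <- rep(0.95, 8)
  ad <- c(frontal_lobe = 1.20, parietal_lobe = 1.25, temporal_lobe = 1.35,
          occipital_lobe = 1.28, anterior_cingulate = 1.15,
          posterior_cingulate = 1.28, precuneus = 1.32, braak_1_2 = 1.35)
  m <- cbind(HC = hc, MCI = (hc + ad) / 2, AD = unname(ad))
  rownames(m) <- persi_regions()
  m
}

#' Specification of a phantom cohort
#'
#' Collects the geometry, intensity model and noise structure of the
#' synthetic cohort. All intensities are expressed relative to the clean
#' white-matter mean.
#'
#' @param shape grid dimensions (default 64^3).
#' @param voxel_size voxel edge lengths in mm (default 2 mm isotropic).
#' @param wm_mean,wm_sd clean WM component: mean intensity and voxel SD
#'   (the SD includes acquisition noise; defaults 1.0 and 0.10).
#' @param contamination_fraction named vector per group: fraction of WM
#'   voxels receiving spill-in (defaults HC 0, MCI 0.15, AD 0.30).
#' @param contamination_ratio mean intensity of contaminated voxels relative
#'   to `wm_mean` (default 1.4, i.e. +40%).
#' @param contamination_sd voxel SD of the contamination component
#'   (default 0.15).
#' @param uptake_ratios 8 x 3 matrix of regional target SUVRs
#'   (see [default_uptake_ratios]).
#' @param uptake_between_sd between-subject SD of each regional uptake ratio
#'   (default 0.10); the knob that sets group effect sizes, since
#'   `d = (ratio_patient - ratio_control) / uptake_between_sd` when other
#'   noise sources are negligible.
#' @param cerebellum_ratio cerebellar mean relative to WM (default 1.0).
#' @param cerebellum_nuisance_sd between-subject SD of a multiplicative
#'   cerebellar nuisance factor (default 0.08), emulating the small size,
#'   truncation and noise susceptibility of the cerebellar reference.
#' @param csf_ratio CSF mean relative to WM (default 0.25).
#' @param global_jitter_sd SD of the per-subject log global scale factor
#'   (default 0.10); SUVRs are invariant to it by construction.
#' @param noise_sd additional additive Gaussian voxel noise applied to all
#'   head voxels (default 0; compartment SDs already model voxel noise).
#' @return A validated list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L), voxel_size = c(2, 2, 2),
                         wm_mean = 1.0, wm_sd = 0.10,
                         contamination_fraction = c(HC = 0, MCI = 0.15, AD = 0.30),
                         contamination_ratio = 1.4, contamination_sd = 0.15,
                         uptake_ratios = default_uptake_ratios(),
                         uptake_between_sd = 0.10,
                         cerebellum_ratio = 1.0, cerebellum_nuisance_sd = 0.08,
                         csf_ratio = 0.25,
                         global_jitter_sd = 0.10, noise_sd = 0) {
  sds <- c(wm_sd, contamination_sd, uptake_between_sd, cerebellum_nuisance_sd,
           global_jitter_sd, noise_sd)
  if (any(sds < 0))
    persi_error("all SDs must be non-negative", "persi_spec_error")
  if (any(contamination_fraction < 0) || any(contamination_fraction >= 1))
    persi_error("contamination fractions must lie in [0, 1)", "persi_spec_error")
  if (any(uptake_ratios <= 0) || wm_mean <= 0 || contamination_ratio <= 0 ||
      cerebellum_ratio <= 0 || csf_ratio <= 0)
    persi_error("mean intensities and uptake ratios must be positive",
                "persi_spec_error")
  if (!identical(sort(rownames(uptake_ratios)), sort(persi_regions())) ||
      !identical(sort(colnames(uptake_ratios)), sort(persi_groups())))
    persi_error("uptake_ratios must be an 8-region x HC/MCI/AD matrix",
                "persi_spec_error")
  structure(list(shape = as.integer(shape), voxel_size = as.numeric(voxel_size),
                 wm_mean = wm_mean, wm_sd = wm_sd,
                 contamination_fraction = contamination_fraction,
                 contamination_ratio = contamination_ratio,
                 contamination_sd = contamination_sd,
                 uptake_ratios = uptake_ratios[persi_regions(), persi_groups()],
                 uptake_between_sd = uptake_between_sd,
                 cerebellum_ratio = cerebellum_ratio,
                 cerebellum_nuisance_sd = cerebellum_nuisance_sd,
                 csf_ratio = csf_ratio,
                 global_jitter_sd = global_jitter_sd, noise_sd = noise_sd),
            class = "phantom_spec")
}

#' Set a designed group effect size for one region
#'
#' Rewrites the patient group's uptake ratio so that the true standardized
#' mean difference against `control` equals `d`:
#' `ratio_patient = ratio_control + d * uptake_between_sd`.
#'
#' @param spec a [phantom_spec].
#' @param region one of [persi_regions()].
#' @param d target Cohen's d.
#' @param patient,control group labels (defaults AD vs HC).
#' @return The modified spec.
#' @export
spec_with_effect <- function(spec, region, d, patient = "AD", control = "HC") {
  stopifnot(inherits(spec, "phantom_spec"), region %in% persi_regions())
  spec$uptake_ratios[region, patient] <-
    spec$uptake_ratios[region, control] + d * spec$uptake_between_sd
  spec
}

# normalized ellipsoidal radius field: sqrt(sum(((idx - c) / R)^2))
ellipsoid_rho <- function(shape, center, radii) {
  d1 <- ((seq_len(shape[1]) - center[1]) / radii[1])^2
  d2 <- ((seq_len(shape[2]) - center[2]) / radii[2])^2
  d3 <- ((seq_len(shape[3]) - center[3]) / radii[3])^2
  sqrt(outer(outer(d1, d2, `+`), d3, `+`))
}

#' Deterministic phantom geometry
#'
#' Builds the tissue zones, ROI label volume and tissue probability maps for
#' a spec. Pure function of the spec (no randomness); [generate_cohort]
#' computes it once and shares it across subjects.
#'
#' Zones by normalized cerebral radius rho: WM core (rho <= 0.52), a
#' partial-volume buffer (0.52-0.62) painted with cortical uptake but
#' belonging strongly to no tissue class, cortex (0.62-0.88) carrying the
#' ROI labels, an outer uptake halo (0.88-0.97), and CSF (0.97-1.0). The
#' buffer and halo give the labelled cortex a same-intensity margin on both
#' sides, so smoothing erodes regional means only mildly; the buffer also
#' keeps cortical uptake out of the thresholded WM mask. Cortex is split
#' into 8 angular sectors, one per region; the Braak I/II sector carries two
#' labels (entorhinal-like and hippocampus-like halves) to exercise label
#' pooling. The cerebellum is a disjoint ellipsoid (label 10).
#'
#' @param spec a [phantom_spec].
#' @return A list with zone masks, `labels`, `region_map`, probability
#'   arrays `wm_prob`/`gm_prob`/`csf_prob`, the contamination ordering, and
#'   an `roi_atlas`.
#' @export
phantom_geometry <- function(spec) {
  sh <- spec$shape
  c_cer <- c(0.508, 0.508, 0.5625) * sh
  r_cer <- c(0.40625, 0.4375, 0.3125) * sh
  rho <- ellipsoid_rho(sh, c_cer, r_cer)
  rho_cb <- ellipsoid_rho(sh, c(0.508, 0.203, 0.172) * sh,
                          c(0.1406, 0.1094, 0.09375) * sh)

  wm_core <- rho <= 0.52
  buffer <- rho > 0.52 & rho <= 0.62
  cortex <- rho > 0.62 & rho <= 0.88
  halo <- rho > 0.88 & rho <= 0.97
  csf <- rho > 0.97 & rho <= 1.0
  cerebellum <- rho_cb <= 1.0
  if (any(cerebellum & rho <= 1.0))
    persi_error("cerebellum overlaps the cerebral ellipsoid", "persi_spec_error")

  # 8 angular sectors around the cerebral axis
  xs <- (seq_len(sh[1]) - c_cer[1]) / r_cer[1]
  ys <- (seq_len(sh[2]) - c_cer[2]) / r_cer[2]
  theta <- atan2(rep(ys, each = sh[1]), rep(xs, times = sh[2]))
  sector2d <- pmin(floor((theta + pi) / (pi / 4)) + 1L, 8L)
  sector <- array(rep(sector2d, times = sh[3]), dim = sh)

  regions <- persi_regions()
  labels <- array(0L, dim = sh)
  upper_z <- slice.index(labels, 3) >= c_cer[3]
  for (k in 1:7) labels[cortex & sector == k] <- k
  braak <- cortex & sector == 8L
  labels[braak & upper_z] <- 8L   # entorhinal-like half
  labels[braak & !upper_z] <- 9L  # hippocampus-like half
  labels[cerebellum] <- 10L

  region_map <- c(stats::setNames(as.list(1:7), regions[1:7]),
                  list(braak_1_2 = c(8L, 9L), whole_cerebellum = 10L))
  for (r in names(region_map))
    if (!any(labels %in% region_map[[r]]))
      persi_error(sprintf("phantom region %s is empty", r), "persi_spec_error")

  smooth_prob <- function(binary) {
    v <- gaussian_smooth(volume3d(0.98 * binary, spec$voxel_size),
                         fwhm_mm = min(spec$voxel_size))
    pmin(pmax(v$data, 0), 1)
  }
  wm_prob <- smooth_prob(wm_core) + 0.49 * buffer
  gm_prob <- smooth_prob((cortex | halo | cerebellum)) + 0.49 * buffer
  csf_prob <- smooth_prob(csf)

  atlas <- load_atlas(volume3d(labels * 1.0, spec$voxel_size), region_map)

  # WM voxels ranked by proximity to cortex (descending rho): the spill-in
  # contamination is placed at the top of this ordering
  wm_idx <- which(wm_core)
  wm_order <- wm_idx[order(rho[wm_idx], decreasing = TRUE)]

  list(wm_core = wm_core, buffer = buffer, cortex = cortex, halo = halo,
       csf = csf, cerebellum = cerebellum, sector = sector, labels = labels,
       region_map = region_map, atlas = atlas,
       wm_prob = pmin(wm_prob, 1), gm_prob = pmin(gm_prob, 1),
       csf_prob = csf_prob, wm_by_proximity = wm_order,
       head = rho <= 1.0 | cerebellum)
}

#' Generate one phantom subject
#'
#' Draws a PET volume plus GM/WM/CSF probability maps for one subject,
#' deterministically given `(spec, group, seed)`. WM voxels come from the
#' clean Gaussian component; in patient groups, the spec'd fraction of WM
#' voxels nearest the cortex is replaced by draws from the higher-intensity
#' contamination component. Cortical sectors (including their buffer and
#' halo margins) are drawn at the subject's regional uptake ratio times the
#' WM mean; the whole volume is multiplied by a per-subject global scale
#' factor.
#'
#' @param spec a [phantom_spec].
#' @param group `"HC"`, `"MCI"` or `"AD"`.
#' @param seed integer seed for this subject.
#' @param geom optional precomputed [phantom_geometry].
#' @param dir if non-`NULL`, write the four volumes there as NIfTI.
#' @param subject_id id used in file names (default derived from the seed).
#' @return A list with `pet`, `gm`, `wm`, `csf` ([volume3d]s), `truth`
#'   (ground-truth record, see details) and, when written, `paths`. The
#'   truth records the subject's realized uptake ratios, global scale,
#'   cerebellar nuisance, the empirical clean-WM / cerebellar / regional
#'   means of the emitted volume, the contamination voxel indices, and the
#'   volume's global mean.
#' @export
generate_subject <- function(spec, group, seed, geom = NULL, dir = NULL,
                             subject_id = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  group <- match.arg(group, persi_groups())
  if (is.null(geom)) geom <- phantom_geometry(spec)
  if (is.null(subject_id)) subject_id <- sprintf("sub_%s_%d", group, seed)
  set.seed(as.integer(seed))

  scale <- exp(stats::rnorm(1, 0, spec$global_jitter_sd))
  nu <- stats::rnorm(1, 0, spec$cerebellum_nuisance_sd)
  regions <- persi_regions()
  r_subj <- pmax(spec$uptake_ratios[, group] +
                   stats::rnorm(8, 0, spec$uptake_between_sd), 0.05)
  names(r_subj) <- regions

  pet <- array(0, dim = spec$shape)

  # white matter: clean component, then spill-in nearest the cortex
  wm_idx <- which(geom$wm_core)
  n_wm <- length(wm_idx)
  f <- spec$contamination_fraction[[group]]
  n_cont <- as.integer(round(f * n_wm))
  cont_idx <- if (n_cont > 0L) geom$wm_by_proximity[seq_len(n_cont)] else integer(0)
  clean_idx <- setdiff(wm_idx, cont_idx)
  pet[clean_idx] <- stats::rnorm(length(clean_idx), spec$wm_mean, spec$wm_sd)
  if (n_cont > 0L)
    pet[cont_idx] <- stats::rnorm(n_cont,
                                  spec$contamination_ratio * spec$wm_mean,
                                  spec$contamination_sd)

  # cortical uptake, painted over buffer + cortex + halo of each sector
  uptake_zone <- geom$buffer | geom$cortex | geom$halo
  for (k in seq_along(regions)) {
    idx <- which(uptake_zone & geom$sector == k)
    pet[idx] <- stats::rnorm(length(idx), r_subj[k] * spec$wm_mean, spec$wm_sd)
  }

  cb_idx <- which(geom$cerebellum)
  pet[cb_idx] <- stats::rnorm(length(cb_idx),
                              spec$cerebellum_ratio * spec$wm_mean * (1 + nu),
                              spec$wm_sd)
  csf_idx <- which(geom$csf)
  pet[csf_idx] <- stats::rnorm(length(csf_idx),
                               spec$csf_ratio * spec$wm_mean, spec$wm_sd)
  if (spec$noise_sd > 0) {
    head_idx <- which(geom$head)
    pet[head_idx] <- pet[head_idx] + stats::rnorm(length(head_idx), 0, spec$noise_sd)
  }
  pet <- pmax(pet, 0) * scale

  regional_means <- vapply(names(geom$region_map)[
    names(geom$region_map) != "whole_cerebellum"],
    function(r) mean(pet[geom$labels %in% geom$region_map[[r]]]), numeric(1))

  truth <- list(subject_id = subject_id, group = group, seed = as.integer(seed),
                global_scale = scale, cerebellum_nuisance = nu,
                uptake_ratios = r_subj,
                clean_wm_mean = mean(pet[clean_idx]),
                wm_mean_design = spec$wm_mean * scale,
                cerebellum_mean = mean(pet[cb_idx]),
                regional_means = regional_means,
                contamination_indices = cont_idx,
                n_wm_core = n_wm, n_contaminated = n_cont,
                global_mean = mean(pet))

  vols <- list(pet = volume3d(pet, spec$voxel_size),
               gm = volume3d(geom$gm_prob, spec$voxel_size),
               wm = volume3d(geom$wm_prob, spec$voxel_size),
               csf = volume3d(geom$csf_prob, spec$voxel_size))
  out <- c(vols, list(truth = truth))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- stats::setNames(
      file.path(dir, sprintf("%s_%s.nii.gz", subject_id, names(vols))),
      names(vols))
    for (nm in names(vols)) write_volume(vols[[nm]], paths[[nm]])
    out$paths <- paths
  }
  out
}

#' Generate a phantom cohort on disk
#'
#' Materializes a full cohort: per-subject NIfTI volumes, an atlas label
#' volume, a region-spec YAML, a cohort manifest CSV and a ground-truth JSON
#' (scalar fields only; full contamination indices are kept in the returned
#' object). Subject seeds are derived deterministically from `master_seed`.
#' Default group sizes are 65 HC / 60 MCI / 12 AD, a typical single-site
#' tau-PET study layout.
#'
#' @param spec a [phantom_spec].
#' @param n_per_group named integer vector of group sizes; groups with 0
#'   subjects are skipped; each requested group needs n >= 2.
#' @param master_seed integer master seed.
#' @param dir output directory (created if needed).
#' @return A list with `manifest` (validated `cohort_manifest`),
#'   `manifest_path`, `atlas` (`roi_atlas`), `atlas_path`,
#'   `region_spec_path`, `truths` (per-subject ground truth), `geom`,
#'   and `dir`.
#' @export
generate_cohort <- function(spec, n_per_group = c(HC = 65L, MCI = 60L, AD = 12L),
                            master_seed = 1L, dir = tempfile("persi_cohort_")) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_per_group <- n_per_group[n_per_group > 0]
  if (length(n_per_group) == 0L || is.null(names(n_per_group)))
    persi_error("`n_per_group` must be a named vector of positive counts",
                "persi_spec_error")
  if (any(n_per_group < 2L))
    persi_error("each requested group needs at least 2 subjects",
                "persi_spec_error")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir))
    persi_error(sprintf("cannot create directory %s", dir), "persi_io_error")

  geom <- phantom_geometry(spec)
  atlas_path <- file.path(dir, "atlas.nii.gz")
  write_volume(volume3d(geom$labels * 1.0, spec$voxel_size), atlas_path)
  region_spec_path <- file.path(dir, "regions.yaml")
  yaml::write_yaml(lapply(geom$region_map, as.integer), region_spec_path)

  n_total <- sum(n_per_group)
  set.seed(as.integer(master_seed))
  seeds <- sample.int(2147483646L, n_total)

  rows <- list()
  truths <- list()
  i <- 0L
  for (grp in names(n_per_group)) {
    for (j in seq_len(n_per_group[[grp]])) {
      i <- i + 1L
      sid <- sprintf("%s_%03d", grp, j)
      subj <- generate_subject(spec, grp, seeds[i], geom = geom, dir = dir,
                               subject_id = sid)
      rows[[i]] <- data.frame(subject_id = sid, group = grp,
                              pet_path = basename(subj$paths[["pet"]]),
                              gm_path = basename(subj$paths[["gm"]]),
                              wm_path = basename(subj$paths[["wm"]]),
                              csf_path = basename(subj$paths[["csf"]]),
                              stringsAsFactors = FALSE)
      truths[[sid]] <- subj$truth
    }
  }
  manifest_path <- file.path(dir, "manifest.csv")
  write_manifest(do.call(rbind, rows), manifest_path)
  manifest <- read_manifest(manifest_path)

  truth_scalars <- lapply(truths, function(t)
    t[setdiff(names(t), "contamination_indices")])
  jsonlite::write_json(truth_scalars, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)

  list(manifest = manifest, manifest_path = manifest_path,
       atlas = geom$atlas, atlas_path = atlas_path,
       region_spec_path = region_spec_path, truths = truths, geom = geom,
       dir = dir, subject_seeds = seeds)
}

#' Expected contamination fraction inside an intensity window
#'
#' Analytic mixture calculation used to audit reference purity: given the
#' spec's clean and contamination components and a realized contamination
#' fraction `f`, returns the probability that a WM voxel retained in
#' `window` came from the contamination component,
#' `f P_c(W) / (f P_c(W) + (1 - f) P_k(W))`.
#'
#' @param spec a [phantom_spec].
#' @param window numeric length-2 intensity window (on the unscaled
#'   intensity axis; divide by the subject's global scale first).
#' @param f realized contamination fraction among the histogrammed voxels.
#' @return Expected contamination fraction among retained voxels.
#' @export
expected_window_contamination <- function(spec, window, f) {
  s_k <- sqrt(spec$wm_sd^2 + spec$noise_sd^2)
  s_c <- sqrt(spec$contamination_sd^2 + spec$noise_sd^2)
  p_k <- stats::pnorm(window[2], spec$wm_mean, s_k) -
    stats::pnorm(window[1], spec$wm_mean, s_k)
  p_c <- stats::pnorm(window[2], spec$contamination_ratio * spec$wm_mean, s_c) -
    stats::pnorm(window[1], spec$contamination_ratio * spec$wm_mean, s_c)
  f * p_c / (f * p_c + (1 - f) * p_k)
}
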