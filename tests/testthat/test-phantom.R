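# The synthetic phantom generator and its ground truth.

test_that("generation is bit-identical under a fixed (spec, seed)", {
  spec <- small_spec()
  a <- generate_subject(spec, "AD", seed = 7)
  b <- generate_subject(spec, "AD", seed = 7)
  expect_identical(a$pet$data, b$pet$data)
  expect_identical(a$truth, b$truth)
  c <- generate_subject(spec, "AD", seed = 8)
  expect_false(identical(a$pet$data, c$pet$data))
})

test_that("control subjects produce unimodal WM histograms", {
  spec <- small_spec()
  s <- generate_subject(spec, "HC", seed = 101)
  expect_identical(s$truth$n_contaminated, 0L)
  fit <- fit_bimodal(build_histogram(s$pet, binarize_segmentation(s$wm, 0.9), 128L))
  expect_true(fit$unimodal_fallback)
})

test_that("patient spill-in yields a recoverable bimodal WM histogram", {
  spec <- phantom_spec()  # AD: 30% contamination at +40%, full-size grid
  s <- generate_subject(spec, "AD", seed = 102)
  fit <- fit_bimodal(build_histogram(s$pet, binarize_segmentation(s$wm, 0.9), 128L))
  expect_false(fit$unimodal_fallback)
  sc <- s$truth$global_scale
  expect_lt(abs(fit$mu_low / (1.0 * sc) - 1), 0.02)
  expect_lt(abs(fit$mu_high / (1.4 * sc) - 1), 0.02)
})

test_that("probability maps are near 1 in tissue cores and decay at boundaries", {
  spec <- small_spec()
  geom <- phantom_geometry(spec)
  # interior of the WM core (away from the buffer) is confidently WM
  interior <- geom$wm_core & !geom$buffer
  expect_gt(stats::quantile(geom$wm_prob[interior], 0.5), 0.95)
  expect_true(all(geom$wm_prob[geom$cortex] < 0.9))
  expect_true(all(geom$wm_prob >= 0 & geom$wm_prob <= 1))
})

test_that("the analytic WM mixture integrates to the voxel count", {
  spec <- small_spec()
  s <- generate_subject(spec, "AD", seed = 103)
  wm <- binarize_segmentation(s$wm, 0.9)
  h <- build_histogram(s$pet, wm, 128L)
  sc <- s$truth$global_scale
  f <- mean(which(wm$data) %in% s$truth$contamination_indices)
  dens <- (1 - f) * dnorm(h$mids, spec$wm_mean * sc, spec$wm_sd * sc) +
    f * dnorm(h$mids, spec$contamination_ratio * spec$wm_mean * sc,
              spec$contamination_sd * sc)
  expect_lt(abs(sum(dens * h$bin_width) * h$n_voxels / sum(h$counts) - 1), 0.01)
})

test_that("contamination raises the naive WM mean but barely moves the PERSI mean", {
  fracs <- c(0, 0.1, 0.2, 0.3, 0.4)
  naive <- persi_ref <- numeric(length(fracs))
  for (i in seq_along(fracs)) {
    spec <- phantom_spec(contamination_fraction = c(HC = 0, MCI = 0.15, AD = fracs[i]),
                         global_jitter_sd = 0)
    s <- generate_subject(spec, "AD", seed = 104)
    wm <- binarize_segmentation(s$wm, 0.9)
    naive[i] <- mean(s$pet$data[wm$data])
    fit <- fit_bimodal(build_histogram(s$pet, wm, 128L))
    persi_ref[i] <- select_reference_voxels(s$pet, wm, fit)$mean_intensity
  }
  expect_true(all(diff(naive) > 0))
  expect_lt(max(abs(persi_ref / persi_ref[1] - 1)), 0.02)
})

test_that("cohort generation writes a loadable, deterministic file set", {
  spec <- small_spec()
  d <- withr::local_tempdir()
  cohort <- generate_cohort(spec, n_per_group = c(HC = 3L, AD = 3L),
                            master_seed = 9, dir = file.path(d, "c1"))
  expect_identical(nrow(cohort$manifest), 6L)
  expect_true(all(file.exists(cohort$manifest$pet_path)))
  expect_true(file.exists(cohort$atlas_path))
  expect_true(file.exists(cohort$region_spec_path))
  pet <- read_volume(cohort$manifest$pet_path[1])
  expect_identical(dim(pet$data), spec$shape)
  # reloadable through the standard entry points
  m <- read_manifest(cohort$manifest_path)
  atlas <- load_atlas(read_volume(cohort$atlas_path),
                      yaml::read_yaml(cohort$region_spec_path))
  expect_identical(atlas$region_counts, cohort$atlas$region_counts)
  # same master seed reproduces the same subject seeds and volumes
  cohort2 <- generate_cohort(spec, n_per_group = c(HC = 3L, AD = 3L),
                             master_seed = 9, dir = file.path(d, "c2"))
  expect_identical(cohort$subject_seeds, cohort2$subject_seeds)
  expect_identical(read_volume(cohort$manifest$pet_path[1])$data,
                   read_volume(cohort2$manifest$pet_path[1])$data)
  expect_error(generate_cohort(spec, n_per_group = c(HC = 1L), master_seed = 9),
               class = "persi_spec_error")
})

test_that("without spill-in and cerebellar nuisance the two references agree", {
  spec <- small_spec(contamination_fraction = c(HC = 0, MCI = 0, AD = 0),
                     cerebellum_nuisance_sd = 0)
  cohort <- generate_cohort(spec, n_per_group = c(HC = 2L, AD = 2L),
                            master_seed = 10, dir = withr::local_tempdir())
  tab <- compute_suvr_table(cohort$manifest, cohort$atlas,
                            suvr_control(smooth = FALSE))
  wide <- merge(tab[tab$method == "persi_wm", c("subject_id", "region", "suvr")],
                tab[tab$method == "whole_cerebellum", c("subject_id", "region", "suvr")],
                by = c("subject_id", "region"))
  expect_true(all(abs(wide$suvr.x / wide$suvr.y - 1) < 0.05))
})

test_that("spec validation rejects inconsistent parameters", {
  expect_error(phantom_spec(wm_sd = -1), class = "persi_spec_error")
  expect_error(phantom_spec(contamination_fraction = c(HC = 0, MCI = 0.5, AD = 1)),
               class = "persi_spec_error")
  bad_ratios <- default_uptake_ratios()[1:7, ]
  expect_error(phantom_spec(uptake_ratios = bad_ratios), class = "persi_spec_error")
})

test_that("spec_with_effect sets the designed standardized difference", {
  spec <- small_spec()
  spec2 <- spec_with_effect(spec, "temporal_lobe", d = 1.5)
  delta <- spec2$uptake_ratios["temporal_lobe", "AD"] -
    spec2$uptake_ratios["temporal_lobe", "HC"]
  expect_equal(delta / spec2$uptake_between_sd, 1.5)
})
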