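# Regional means, cerebellum reference, and the cohort SUVR table.

test_that("roi_mean is the arithmetic mean over the region's labels", {
  atlas <- tiny_atlas(n = 6L, k = 4L)
  vol <- volume3d(array(0, dim = c(6, 6, 6)))
  vol$data[1:4] <- c(1, 2, 3, 4)
  expect_equal(roi_mean(vol, atlas, "temporal_lobe"), 2.5)
  uni <- volume3d(array(7.3, dim = c(6, 6, 6)))
  for (r in persi_regions()) expect_equal(roi_mean(uni, atlas, r), 7.3)
  expect_error(roi_mean(vol, atlas, "thalamus"), class = "persi_lookup_error")
})

test_that("roi_mean equals a brute-force mean over labelled phantom voxels", {
  spec <- small_spec()
  geom <- phantom_geometry(spec)
  s <- generate_subject(spec, "AD", seed = 81, geom = geom)
  for (r in c("temporal_lobe", "braak_1_2")) {
    lbls <- geom$region_map[[r]]
    brute <- mean(s$pet$data[geom$labels %in% lbls])
    expect_equal(roi_mean(s$pet, geom$atlas, r), brute)
  }
})

test_that("cerebellum reference is definitionally the whole-cerebellum mean", {
  atlas <- tiny_atlas()
  vol <- volume3d(array(2.0, dim = c(6, 6, 6)))
  ref <- cerebellum_reference(vol, atlas)
  expect_equal(ref$mean_intensity, 2.0)
  expect_identical(ref$method, "whole_cerebellum")

  spec <- small_spec()
  geom <- phantom_geometry(spec)
  s <- generate_subject(spec, "HC", seed = 82, geom = geom)
  ref2 <- cerebellum_reference(s$pet, geom$atlas)
  expect_equal(ref2$mean_intensity, roi_mean(s$pet, geom$atlas, "whole_cerebellum"))
  expect_lt(abs(ref2$mean_intensity / s$truth$cerebellum_mean - 1), 1e-12)
})

test_that("uniform toy cohort yields SUVR 1 everywhere (cerebellum arm)", {
  d <- withr::local_tempdir()
  spec <- small_spec()
  geom <- phantom_geometry(spec)
  lab_path <- file.path(d, "atlas.nii.gz")
  write_volume(volume3d(geom$labels * 1.0, spec$voxel_size), lab_path)
  rows <- list()
  for (sid in c("u1", "u2")) {
    uni <- volume3d(array(4.2, dim = spec$shape), spec$voxel_size)
    p <- file.path(d, paste0(sid, "_pet.nii.gz"))
    write_volume(uni, p)
    w <- file.path(d, paste0(sid, "_wm.nii.gz"))
    write_volume(volume3d(geom$wm_prob, spec$voxel_size), w)
    rows[[sid]] <- data.frame(subject_id = sid, group = c(u1 = "HC", u2 = "AD")[sid],
                              pet_path = p, gm_path = w, wm_path = w, csf_path = w)
  }
  manifest <- validate_manifest(do.call(rbind, rows), base_dir = d)
  atlas <- load_atlas(read_volume(lab_path), geom$region_map)
  tab <- compute_suvr_table(manifest, atlas,
                            suvr_control(methods = "whole_cerebellum"))
  expect_identical(nrow(tab), 2L * 8L)
  expect_true(all(abs(tab$suvr - 1) < 1e-9))
})

test_that("table has complete factorial coverage and ground-truth accuracy", {
  spec <- small_spec()
  cohort <- generate_cohort(spec, n_per_group = c(HC = 3L, AD = 3L),
                            master_seed = 83, dir = withr::local_tempdir())
  tab <- compute_suvr_table(cohort$manifest, cohort$atlas,
                            suvr_control(smooth = FALSE))
  expect_identical(nrow(tab), 6L * 8L * 2L)
  expect_identical(anyDuplicated(tab[c("subject_id", "region", "method")]), 0L)
  # each subject's PERSI temporal SUVR tracks its own realized uptake ratio
  for (sid in unique(tab$subject_id)) {
    got <- tab$suvr[tab$subject_id == sid & tab$region == "temporal_lobe" &
                      tab$method == "persi_wm"]
    truth <- cohort$truths[[sid]]
    want <- truth$regional_means[["temporal_lobe"]] / truth$clean_wm_mean
    expect_lt(abs(got / want - 1), 0.02)
  }
})

test_that("failing subjects are excluded and logged; high failure rates abort", {
  spec <- small_spec()
  cohort <- generate_cohort(spec, n_per_group = c(HC = 2L, AD = 2L),
                            master_seed = 84, dir = withr::local_tempdir())
  # corrupt one subject's PET so it cannot be read
  bad <- cohort$manifest$pet_path[1]
  writeLines("not a nifti", bad)
  tab <- suppressWarnings(
    compute_suvr_table(cohort$manifest, cohort$atlas,
                       suvr_control(smooth = FALSE, max_failure_rate = 0.5)))
  expect_identical(sort(names(attr(tab, "failures"))),
                   cohort$manifest$subject_id[1])
  expect_identical(nrow(tab), 3L * 8L * 2L)
  expect_error(
    suppressWarnings(
      compute_suvr_table(cohort$manifest, cohort$atlas,
                         suvr_control(smooth = FALSE, max_failure_rate = 0.1))),
    class = "persi_cohort_error")
})

test_that("group summary reports mean, SD and n per cell", {
  tab <- structure(
    data.frame(subject_id = rep(c("a", "b", "c"), each = 2),
               group = rep(c("HC", "HC", "AD"), each = 2),
               region = "temporal_lobe",
               method = rep(c("persi_wm", "whole_cerebellum"), 3),
               suvr = c(1.0, 1.1, 1.2, 1.3, 1.6, 1.7)),
    class = c("suvr_table", "data.frame"))
  s <- suvr_summary(tab)
  hc <- s[s$group == "HC" & s$method == "persi_wm", ]
  expect_equal(hc$mean_suvr, 1.1)
  expect_equal(hc$sd_suvr, sd(c(1.0, 1.2)))
  expect_identical(hc$n, 2L)
})
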