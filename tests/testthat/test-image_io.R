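# NIfTI round trips, mask construction, atlas validation.

test_that("write-then-read preserves values and geometry", {
  vol <- volume3d(array(1.0, dim = c(10, 10, 10)), voxel_size = c(2, 2, 2))
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  expect_identical(dim(back$data), c(10L, 10L, 10L))
  expect_equal(back$data, vol$data, tolerance = 0)
  expect_equal(back$voxel_size, c(2, 2, 2))

  # arbitrary values survive to float32 precision
  set.seed(11)
  vol2 <- volume3d(array(rnorm(8^3, 5, 2), dim = c(8, 8, 8)),
                   voxel_size = c(1.5, 2, 2.5))
  f2 <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol2, f2)
  back2 <- read_volume(f2)
  expect_lt(max(abs(back2$data - vol2$data)), 1e-5)
  expect_equal(back2$voxel_size, vol2$voxel_size)
})

test_that("volumes with NaN voxels are rejected with the affected count", {
  a <- array(1.0, dim = c(4, 4, 4))
  a[c(3, 9)] <- NaN
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(a), f, datatype = "float")
  err <- expect_error(read_volume(f), class = "persi_nan_error")
  expect_match(conditionMessage(err), "2 NaN")
})

test_that("missing files and non-3D images raise typed errors", {
  expect_error(read_volume(file.path(tempdir(), "nope_missing.nii.gz")),
               class = "persi_io_error")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(4, 4, 4, 2))), f)
  expect_error(read_volume(f), class = "persi_dim_error")
})

test_that("phantom volumes round-trip with the generator's recorded mean", {
  spec <- small_spec()
  s <- generate_subject(spec, "AD", seed = 5,
                        dir = withr::local_tempdir(), subject_id = "s1")
  pet <- read_volume(s$paths[["pet"]])
  expect_lt(abs(mean(pet$data) - s$truth$global_mean), 1e-6)
})

test_that("binarize_segmentation thresholds strictly and rejects degenerate masks", {
  vol <- volume3d(array(0.95, dim = c(4, 4, 4)))
  expect_true(all(binarize_segmentation(vol, 0.9)$data))
  low <- volume3d(array(0.5, dim = c(4, 4, 4)))
  expect_error(binarize_segmentation(low, 0.9),
               class = "persi_degenerate_mask_error")
  # boundary voxels exactly at the threshold are excluded
  edge <- volume3d(array(c(0.9, rep(0.95, 7)), dim = c(2, 2, 2)))
  expect_equal(binarize_segmentation(edge, 0.9)$n_voxels, 7L)
  out_of_range <- volume3d(array(1.5, dim = c(2, 2, 2)))
  expect_error(binarize_segmentation(out_of_range, 0.9),
               class = "persi_probability_error")
})

test_that("binarization is monotone in the threshold and counts match brute force", {
  set.seed(21)
  prob <- volume3d(array(runif(10^3), dim = c(10, 10, 10)))
  thresholds <- c(0.2, 0.5, 0.8, 0.95)
  counts <- vapply(thresholds, function(th) {
    m <- binarize_segmentation(prob, th)
    expect_identical(m$n_voxels, sum(prob$data > th))  # brute-force count
    m$n_voxels
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("phantom WM mask cardinality equals an exhaustive voxel count", {
  spec <- small_spec()
  s <- generate_subject(spec, "HC", seed = 3)
  m <- binarize_segmentation(s$wm, 0.9)
  expect_identical(m$n_voxels, sum(s$wm$data > 0.9))
})

test_that("load_atlas validates completeness and region content", {
  lab <- array(0, dim = c(4, 4, 4))
  lab[1:4] <- 1
  lab[5:8] <- 2
  spec_ok <- c(stats::setNames(rep(list(1L), 8L), persi_regions()),
               list(whole_cerebellum = 2L))
  # labels shared across regions are legal but flagged
  expect_warning(atlas <- load_atlas(volume3d(lab), spec_ok),
                 "more than one region")
  expect_s3_class(atlas, "roi_atlas")
  expect_identical(unname(atlas$region_counts[["whole_cerebellum"]]), 4L)

  incomplete <- spec_ok[setdiff(names(spec_ok), "precuneus")]
  err <- expect_error(suppressWarnings(load_atlas(volume3d(lab), incomplete)),
                      class = "persi_atlas_error")
  expect_match(conditionMessage(err), "precuneus")

  empty <- spec_ok
  empty$precuneus <- 99L  # label absent from the volume
  expect_error(suppressWarnings(load_atlas(volume3d(lab), empty)),
               class = "persi_atlas_error")
})

test_that("phantom atlas region voxel counts match the generator's records", {
  spec <- small_spec()
  geom <- phantom_geometry(spec)
  for (r in names(geom$region_map)) {
    expect_identical(unname(geom$atlas$region_counts[[r]]),
                     sum(geom$labels %in% geom$region_map[[r]]))
  }
})

test_that("manifest validation catches duplicates, bad groups, missing files", {
  d <- withr::local_tempdir()
  file.create(file.path(d, c("p.nii", "g.nii", "w.nii", "c.nii")))
  df <- data.frame(subject_id = c("a", "b"), group = c("HC", "AD"),
                   pet_path = "p.nii", gm_path = "g.nii", wm_path = "w.nii",
                   csf_path = "c.nii")
  m <- validate_manifest(df, base_dir = d)
  expect_s3_class(m, "cohort_manifest")
  dup <- df; dup$subject_id <- c("a", "a")
  expect_error(validate_manifest(dup, base_dir = d),
               class = "persi_manifest_error")
  bad <- df; bad$group <- c("HC", "XX")
  expect_error(validate_manifest(bad, base_dir = d),
               class = "persi_manifest_error")
  gone <- df; gone$pet_path <- "absent.nii"
  expect_error(validate_manifest(gone, base_dir = d),
               class = "persi_io_error")
})
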