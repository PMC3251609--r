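test_that("generated subjects mirror their specification and are internally valid", {
  spec <- phantom_spec()
  s <- generate_subject(spec)

  expect_setequal(names(s$target_masks), c("premotor", "motor"))
  expect_setequal(names(s$truth_peaks_mm), c("premotor", "motor"))
  for (b in spec$bundles)
    expect_equal(s$truth_peaks_mm[[b$target_name]], b$thalamic_origin_mm)

  # mask containment and disjointness
  expect_true(all(s$thalamus_mask$data <= s$brain_mask$data))
  for (tm in s$target_masks) {
    expect_true(all(tm$data <= s$brain_mask$data))
    expect_false(any(tm$data & s$thalamus_mask$data))
  }

  # stored fibre directions are unit vectors wherever defined
  f <- s$orientation_field
  dm <- matrix(f$dirs, prod(dim(f$ndirs)), 6L)
  n1 <- sqrt(rowSums(dm[, 1:3]^2))
  expect_true(all(abs(n1[f$ndirs >= 1] - 1) < 1e-9))

  # determinism: regenerating from the same spec is bit-identical
  expect_identical(s[setdiff(names(s), "spec")],
                   generate_subject(spec)[setdiff(names(s), "spec")])
})

test_that("zero-dispersion straight-bundle voxels carry the exact axis tangent", {
  s <- generate_subject(straight_spec(dispersion_deg = 0))
  f <- s$orientation_field
  on <- which(f$ndirs == 1L)
  dm <- matrix(f$dirs, prod(dim(f$ndirs)), 6L)
  # bundle runs along +y; every tangent must equal (0, 1, 0)
  expect_true(all(abs(dm[on, 1]) < 1e-9))
  expect_true(all(abs(dm[on, 2] - 1) < 1e-9))
  expect_true(all(abs(dm[on, 3]) < 1e-9))
  expect_true(all(f$dispersion_deg[on] == 0))
})

test_that("invalid phantom specifications are rejected", {
  expect_error(phantom_spec(grid_shape = c(8, 32, 32)), "grid_shape")
  expect_error(phantom_spec(voxel_size_mm = 0), "voxel_size_mm")
  # origin outside the thalamus sphere
  expect_error(phantom_spec(bundles = list(
    bundle_spec("motor", c(16, 28, 16), c(20, 28, 12)))), "outside the thalamus")
  # cortical patch touching the thalamus
  expect_error(phantom_spec(bundles = list(
    bundle_spec("motor", c(16, 13, 16), c(16, 20, 16),
                cortical_patch_radius_mm = 3))), "intersects the thalamus")
  expect_error(bundle_spec("motor", c(0, 0, 0), c(1, 1, 1),
                           dispersion_deg = 95), "dispersion_deg")
  # IH on the AC-PC line cannot define a midsagittal plane
  expect_error(landmark_set(AC = c(0, 0, 0), PC = c(0, -25, 0),
                            IH = c(0, -10, 0)), "collinear")
})

test_that("cohort generation reproduces the requested displacement statistics", {
  # central bundle far from the thalamus wall so resampling never truncates
  base <- phantom_spec(bundles = list(
    bundle_spec("premotor", c(16, 13, 16), c(12, 28, 20),
                bend_mm = c(0, 0, 2.5))))

  expect_error(generate_cohort(base, 1, 1), "at least 2")

  coh0 <- generate_cohort(base, 3, peak_sd_mm = 0, seed = 2,
                          pose_jitter = FALSE)
  expect_length(coh0, 3L)
  pk0 <- t(sapply(coh0, function(s) s$truth_peaks_mm$premotor))
  expect_equal(max(dist(pk0)), 0)

  coh <- generate_cohort(base, 250, peak_sd_mm = 2, seed = 5,
                         pose_jitter = FALSE)
  expect_length(coh, 250L)
  pk <- t(sapply(coh, function(s) s$truth_peaks_mm$premotor))
  offs <- sweep(pk, 2, c(16, 13, 16))
  # pooled per-axis SD of the displacement matches the requested SD
  expect_equal(sd(as.vector(offs)), 2, tolerance = 0.1)
  # closed form for the mean pairwise distance of iid 3D Gaussians:
  # E||X - Y|| = 4 sigma / sqrt(pi)
  expect_equal(mean_pairwise_distance(pk)$mean, 4 * 2 / sqrt(pi),
               tolerance = 0.05)
})

test_that("cohort subjects carry recoverable head poses", {
  base <- straight_spec()
  coh <- generate_cohort(base, 3, peak_sd_mm = 1, seed = 7,
                         pose_jitter = TRUE)
  for (s in coh) {
    expect_s3_class(s$applied_transform, "rigid_transform")
    # the recorded pose maps the canonical landmarks onto the subject's
    back <- transform_landmarks(s$landmarks,
                                invert_transform(s$applied_transform))
    expect_equal(back$AC, base$landmarks$AC, tolerance = 1e-9)
    expect_equal(back$PC, base$landmarks$PC, tolerance = 1e-9)
  }
})

test_that("saturated peak displacement warns and keeps the base origin", {
  base <- straight_spec()
  w <- capture_warnings(coh <- generate_cohort(base, 2, peak_sd_mm = 500,
                                               seed = 3,
                                               pose_jitter = FALSE))
  expect_true(any(grepl("clamped", w)))
  # the base origin is retained when every redraw saturates
  expect_equal(coh[[1]]$truth_peaks_mm$motor, c(8, 8, 8))
})

test_that("phantom specifications survive a YAML round trip", {
  spec <- phantom_spec()
  f <- tempfile(fileext = ".yaml")
  write_phantom_spec(spec, f)
  spec2 <- read_phantom_spec(f)
  expect_equal(spec2$grid_shape, spec$grid_shape)
  expect_equal(spec2$thalamus_center_mm, spec$thalamus_center_mm)
  expect_equal(length(spec2$bundles), length(spec$bundles))
  expect_equal(spec2$bundles[[1]]$thalamic_origin_mm,
               spec$bundles[[1]]$thalamic_origin_mm)
  expect_equal(unclass(spec2$landmarks), unclass(spec$landmarks))
})
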