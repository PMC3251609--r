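test_that("zero-noise propagation follows a straight bundle to its end", {
  s <- generate_subject(straight_spec(dispersion_deg = 0))
  cfg <- tracking_config(n_samples_per_voxel = 1, rng_seed = 1)
  path <- propagate_streamline(c(8, 8, 8), s$orientation_field,
                               s$brain_mask, cfg)
  expect_gte(nrow(path), 10)
  # straight +y bundle: x and z never move, y is monotone increasing
  expect_true(all(abs(path[, 1] - 8) < 1e-12))
  expect_true(all(abs(path[, 3] - 8) < 1e-12))
  expect_true(all(diff(path[, 2]) > 0))
  # the polyline reaches the cortical patch (centre y = 13, radius 2)
  expect_gte(max(path[, 2]), 11)
})

test_that("propagation stops immediately in isotropic voxels and respects the brain mask", {
  s <- generate_subject(straight_spec(dispersion_deg = 0))
  cfg <- tracking_config(n_samples_per_voxel = 1, rng_seed = 1)
  # (2,2,2) is far from the bundle: no stored direction there
  path <- propagate_streamline(c(2, 2, 2), s$orientation_field,
                               s$brain_mask, cfg)
  expect_identical(nrow(path), 1L)
  expect_error(propagate_streamline(c(-50, 0, 0), s$orientation_field,
                                    s$brain_mask, cfg),
               "outside the brain mask")
})

test_that("propagation is reproducible under a fixed seed", {
  s <- generate_subject(straight_spec(dispersion_deg = 10))
  cfg <- tracking_config(n_samples_per_voxel = 1, rng_seed = 42)
  p1 <- propagate_streamline(c(8, 8, 8), s$orientation_field,
                             s$brain_mask, cfg)
  p2 <- propagate_streamline(c(8, 8, 8), s$orientation_field,
                             s$brain_mask, cfg)
  expect_identical(p1, p2)
  expect_gt(nrow(p1), 2)
  # with dispersion the path is genuinely stochastic across seeds
  cfg2 <- tracking_config(n_samples_per_voxel = 1, rng_seed = 43)
  p3 <- propagate_streamline(c(8, 8, 8), s$orientation_field,
                             s$brain_mask, cfg2)
  expect_false(isTRUE(all.equal(dim(p1), dim(p3))) &&
                 isTRUE(all.equal(p1, p3)))
})

test_that("connectivity counting obeys its contracts on a deterministic bundle", {
  s <- generate_subject(straight_spec(dispersion_deg = 0))
  cfg <- tracking_config(n_samples_per_voxel = 25, rng_seed = 1)
  res <- track_from_mask(s$thalamus_mask, s$target_masks,
                         s$orientation_field, s$brain_mask, cfg)
  cm <- result_count_matrix(res)

  # straight tube: every on-bundle seed voxel connects with probability 1,
  # every off-bundle (isotropic) seed voxel with probability 0
  on <- s$orientation_field$ndirs[which(s$thalamus_mask$data != 0)] > 0
  expect_true(all(cm[on, "motor"] == 25))
  expect_true(all(cm[!on, "motor"] == 0))

  # counts bounded by n_samples and zero outside the seed mask
  expect_true(all(res$counts$motor$data >= 0 &
                    res$counts$motor$data <= 25))
  expect_true(all(res$counts$motor$data[s$thalamus_mask$data == 0] == 0))

  # bit-identical on rerun with the same configuration
  res2 <- track_from_mask(s$thalamus_mask, s$target_masks,
                          s$orientation_field, s$brain_mask, cfg)
  expect_identical(res$counts$motor$data, res2$counts$motor$data)
})

test_that("tracking input validation catches empty and overlapping masks", {
  s <- generate_subject(straight_spec(dispersion_deg = 0))
  cfg <- tracking_config(n_samples_per_voxel = 1, rng_seed = 1)
  empty <- grid_like(s$brain_mask, array(0L, dim = dim(s$brain_mask)))
  expect_error(track_from_mask(empty, s$target_masks, s$orientation_field,
                               s$brain_mask, cfg), "empty")
  expect_error(track_from_mask(s$thalamus_mask,
                               list(motor = s$thalamus_mask),
                               s$orientation_field, s$brain_mask, cfg),
               "overlaps the seed mask")
  expect_error(track_from_lesion(empty, s$orientation_field, s$brain_mask,
                                 cfg), "empty")
  expect_error(tracking_config(step_mm = -1), "positive")
})

test_that("mean on-bundle connection probability is non-increasing in dispersion", {
  probs <- vapply(c(0, 5, 15), function(d) {
    s <- generate_subject(two_bundle_spec(dispersion_deg = d))
    cfg <- tracking_config(n_samples_per_voxel = 200, rng_seed = 3)
    res <- track_from_mask(s$thalamus_mask, s$target_masks,
                           s$orientation_field, s$brain_mask, cfg)
    on <- which(s$orientation_field$ndirs > 0 & s$thalamus_mask$data > 0)
    mean(pmax(connection_probability(res, "premotor")$data[on],
              connection_probability(res, "motor")$data[on]))
  }, numeric(1))
  expect_true(all(diff(probs) <= 0))
  expect_lt(probs[3], probs[2])   # 15 deg strictly below 5 deg
})

test_that("lesion-seeded visitation maps count each streamline once per voxel", {
  s <- generate_subject(straight_spec(dispersion_deg = 0))
  # 4-voxel lesion stacked along the bundle axis (0-based y = 8..11)
  les <- array(0L, dim = dim(s$brain_mask))
  les[8 + 1, 8:11 + 1, 8 + 1] <- 1L
  lesion <- grid_like(s$brain_mask, les)
  cfg <- tracking_config(n_samples_per_voxel = 100, rng_seed = 1)
  vis <- track_from_lesion(lesion, s$orientation_field, s$brain_mask, cfg)
  # every streamline from the 4 seeds passes through the downstream axis
  # voxels, so those accumulate 4 x 100 visits
  expect_identical(vis$data[8 + 1, 12 + 1, 8 + 1], 400L)
  expect_identical(vis$data[8 + 1, 13 + 1, 8 + 1], 400L)
  # and nothing is ever counted twice per streamline
  expect_lte(max(vis$data), 400L)

  # a lesion in an isotropic region visits only itself
  les2 <- array(0L, dim = dim(s$brain_mask))
  les2[3, 3, 3] <- 1L
  vis2 <- track_from_lesion(grid_like(s$brain_mask, les2),
                            s$orientation_field, s$brain_mask, cfg)
  expect_identical(sum(vis2$data > 0), 1L)
  expect_identical(vis2$data[3, 3, 3], 100L)
})
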