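test_that("the Euclidean distance satisfies its worked examples and the metric axioms", {
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(1, 2, 2), c(0, 0, 0)), 3)
  expect_equal(euclidean_distance(c(2, 3, 6), c(0, 0, 0)), 7)
  set.seed(8)
  for (i in 1:25) {
    p <- rnorm(3, sd = 20); q <- rnorm(3, sd = 20); r <- rnorm(3, sd = 20)
    expect_equal(euclidean_distance(p, q), euclidean_distance(q, p))
    expect_gte(euclidean_distance(p, q) + euclidean_distance(q, r),
               euclidean_distance(p, r) - 1e-12)
    expect_gte(euclidean_distance(p, q), 0)
  }
})

test_that("mean pairwise distance summarises all unordered pairs", {
  two <- rbind(c(0, 0, 0), c(0, 5, 0))
  mp <- mean_pairwise_distance(two)
  expect_equal(mp$mean, 5)
  expect_equal(mp$min, 5)
  expect_equal(mp$max, 5)
  expect_equal(mp$n_pairs, 1L)

  collinear <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  mp3 <- mean_pairwise_distance(collinear)
  expect_setequal(round(mp3$values, 12), c(1, 1, 2))
  expect_equal(mp3$mean, 4 / 3)
  expect_equal(mp3$sd, sd(c(1, 1, 2)))
  expect_equal(mp3$n_pairs, choose(3, 2))

  expect_error(mean_pairwise_distance(rbind(c(0, 0, 0))), "two points")
})

test_that("Gaussian point clouds match the closed-form mean norms", {
  set.seed(12)
  sigma <- 1.7
  pts <- matrix(rnorm(3000 * 3, sd = sigma), ncol = 3)
  # mean distance to the cloud centre: sigma * 2 * sqrt(2/pi)
  dr <- distance_to_reference(pts, c(0, 0, 0))
  expect_equal(dr$mean, sigma * 2 * sqrt(2 / pi), tolerance = 0.03)
  # mean pairwise distance: 4 * sigma / sqrt(pi)
  mp <- mean_pairwise_distance(pts[1:600, ])
  expect_equal(mp$mean, 4 * sigma / sqrt(pi), tolerance = 0.03)
})

test_that("reference distances summarise per-subject values", {
  pts <- rbind(c(5, 5, 5), c(5, 5, 5))
  expect_equal(distance_to_reference(pts, c(5, 5, 5))$mean, 0)
  pts2 <- rbind(c(3, 0, 0), c(0, 4, 0), c(0, 0, 5))
  dr <- distance_to_reference(pts2, c(0, 0, 0))
  expect_equal(dr$values, c(3, 4, 5))
  expect_equal(dr$mean, 4)
  expect_equal(dr$min, 3)
  expect_equal(dr$max, 5)
})

test_that("the Tanimoto coefficient counts intersection over union", {
  base <- voxel_grid(array(0L, dim = c(16, 16, 16)), spacing = 1)
  A <- base; A$data[1:30] <- 1L
  B <- base; B$data[11:40] <- 1L           # |A|=|B|=30, overlap 20
  expect_equal(tanimoto(A, B), 20 / 40)
  expect_equal(tanimoto(B, A), tanimoto(A, B))
  expect_equal(tanimoto(A, A), 1)
  C <- base; C$data[101:110] <- 1L
  expect_equal(tanimoto(A, C), 0)
  expect_error(tanimoto(base, base), "empty")
  shifted <- voxel_grid(A$data, spacing = 2)
  expect_error(tanimoto(A, shifted), "geometry")

  # monotone under a growing intersection at fixed union
  union_mask <- base; union_mask$data[1:40] <- 1L
  tc <- vapply(c(10, 20, 30), function(k) {
    Ak <- base; Ak$data[1:(10 + k)] <- 1L   # grows inside the fixed union
    tanimoto(Ak, union_mask)
  }, numeric(1))
  expect_true(all(diff(tc) > 0))
})

test_that("stereotactic targets are built on the AC-PC plane from PC", {
  lm <- landmark_set(AC = c(0, 12.45, 0), PC = c(0, -12.45, 0),
                     IH = c(0, 0, 40))
  tgt <- stereotactic_target(lm, anterior_from_pc_mm = 8,
                             lateral_mm = 12.7, side = "right")
  expect_equal(tgt, c(-12.7, -4.45, 0), tolerance = 1e-12)
  left <- stereotactic_target(lm, 8, 12.7, side = "left")
  expect_equal(left, c(12.7, -4.45, 0), tolerance = 1e-12)

  expect_equal(stereotactic_target(lm, 0, 0), lm$PC)

  # the anterior offset projects exactly onto the PC-to-AC direction
  dir_ac <- (lm$AC - lm$PC) / euclidean_distance(lm$AC, lm$PC)
  expect_equal(sum((tgt - lm$PC) * dir_ac), 8)

  # fractional mode: anterior offset as a fraction of the AC-PC length
  frac <- stereotactic_target(lm, lateral_mm = 0, side = "right",
                              anterior_fraction = 0.5)
  expect_equal(frac, (lm$AC + lm$PC) / 2)
})

test_that("cohort reports are internally consistent", {
  base <- voxel_grid(array(0L, dim = c(16, 16, 16)), spacing = 1)
  m1 <- base; m1$data[1:25] <- 1L
  peaks <- list(premotor = rbind(c(1, 2, 3), c(1, 2, 3)),
                motor = rbind(c(4, 5, 6), c(4, 5, 6)))
  masks <- list(premotor = list(m1, m1), motor = list(m1, m1))
  rep2 <- build_cohort_report(peaks, masks,
                              references = list(atlas = c(1, 2, 3)))
  expect_equal(rep2$by_target$premotor$pairwise$values, 0)
  expect_equal(rep2$by_target$premotor$overlaps$values, 1)
  expect_equal(rep2$by_target$premotor$reference_distances$atlas$mean, 0)

  set.seed(3)
  pk9 <- list(premotor = matrix(rnorm(9 * 3), ncol = 3),
              motor = matrix(rnorm(9 * 3), ncol = 3))
  rep9 <- build_cohort_report(pk9)
  for (tn in rep9$targets) {
    pw <- rep9$by_target[[tn]]$pairwise
    expect_length(pw$values, choose(9, 2))
    expect_true(pw$min <= pw$mean && pw$mean <= pw$max)
    expect_true(all(pw$values >= 0))
  }
  tabs <- report_tables(rep9)
  expect_equal(nrow(tabs$pairwise), 2 * choose(9, 2))

  expect_error(build_cohort_report(list(premotor = rbind(c(0, 0, 0)))),
               "two subjects")
})
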