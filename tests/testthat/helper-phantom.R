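# Shared phantom builders and the independent deterministic tracking oracle.

# Small phantom with a single straight bundle along +y: the analytic
# geometry (parallel offset lines stay inside the tube) makes zero-noise
# behaviour predictable by hand.
straight_spec <- function(dispersion_deg = 0, bundle_radius_mm = 1.2) {
  phantom_spec(
    grid_shape = c(16L, 16L, 16L),
    voxel_size_mm = 1,
    thalamus_center_mm = c(8, 6, 8),
    thalamus_radius_mm = 3,
    bundles = list(bundle_spec("motor",
                               thalamic_origin_mm = c(8, 8, 8),
                               cortical_patch_center_mm = c(8, 13, 8),
                               cortical_patch_radius_mm = 2,
                               bundle_radius_mm = bundle_radius_mm,
                               dispersion_deg = dispersion_deg,
                               bend_mm = c(0, 0, 0))),
    landmarks = landmark_set(AC = c(8, 12, 7), PC = c(8, 2, 7),
                             IH = c(8, 7, 14)))
}

# The default two-bundle phantom with every bundle forced to a given
# dispersion.
two_bundle_spec <- function(dispersion_deg = 10) {
  spec <- phantom_spec()
  for (i in seq_along(spec$bundles))
    spec$bundles[[i]]$dispersion_deg <- dispersion_deg
  spec
}

# Independent deterministic path-following oracle for zero-dispersion
# fields with at most one fibre per voxel: follows the stored direction from
# every seed-voxel centre with the same stepping contract as the tracker
# (nearest voxel, half-way rounded away from zero; sign flip within 90
# degrees of the previous step; stop on isotropic voxel, brain exit,
# curvature breach or max_steps) and returns per-seed, per-target counts of
# n_samples times the reached indicator.
oracle_track <- function(subject, n_samples, step, max_steps = 2000,
                         curvature_limit_deg = 80) {
  field <- subject$orientation_field
  stopifnot(all(field$dispersion_deg[field$ndirs > 0] == 0),
            all(field$ndirs <= 1L))
  shp <- dim(field$ndirs)
  nvox <- prod(shp)
  dirs <- matrix(field$dirs, nvox, 6L)
  targets <- subject$target_masks
  labels <- array(0L, dim = shp)
  for (k in seq_along(targets)) labels[targets[[k]]$data != 0] <- k
  brain <- subject$brain_mask$data
  ndirs <- field$ndirs
  inv <- solve(field$affine)
  aff <- field$affine
  curv_cos <- cos(curvature_limit_deg * pi / 180)
  vox_of <- function(p) {
    fx <- inv[1, 1] * p[1] + inv[1, 2] * p[2] + inv[1, 3] * p[3] + inv[1, 4]
    fy <- inv[2, 1] * p[1] + inv[2, 2] * p[2] + inv[2, 3] * p[3] + inv[2, 4]
    fz <- inv[3, 1] * p[1] + inv[3, 2] * p[2] + inv[3, 3] * p[3] + inv[3, 4]
    # nearest voxel, halves away from zero (the tracker's convention)
    rnd <- function(f) trunc(f + sign(f) * 0.5)
    ix <- rnd(fx); iy <- rnd(fy); iz <- rnd(fz)
    if (ix < 0 || ix >= shp[1] || iy < 0 || iy >= shp[2] ||
        iz < 0 || iz >= shp[3]) return(NA_integer_)
    as.integer(ix + shp[1] * (iy + shp[2] * iz)) + 1L
  }
  seeds <- which(subject$thalamus_mask$data != 0, arr.ind = TRUE) - 1L
  counts <- matrix(0L, nrow(seeds), length(targets),
                   dimnames = list(NULL, names(targets)))
  for (s in seq_len(nrow(seeds))) {
    p <- as.numeric(aff[1:3, 1:3] %*% seeds[s, ] + aff[1:3, 4])
    v <- vox_of(p)
    prev <- NULL
    hit <- rep(FALSE, ncol(counts))
    for (it in seq_len(max_steps)) {
      if (ndirs[v] == 0L) break
      d <- dirs[v, 1:3]
      if (!is.null(prev)) {
        if (sum(d * prev) < 0) d <- -d
        if (sum(d * prev) < curv_cos) break
      }
      p <- p + step * d
      prev <- d
      v <- vox_of(p)
      if (is.na(v) || brain[v] == 0) break
      l <- labels[v]
      if (l > 0L && !hit[l]) {
        hit[l] <- TRUE
        counts[s, l] <- counts[s, l] + n_samples
      }
    }
  }
  counts
}

# the tracker's effective step length for a config/subject pair
resolve_step_for_test <- function(cfg, subject) {
  if (is.null(cfg$step_mm)) min(subject$orientation_field$spacing) / 2
  else cfg$step_mm
}

# counts of a connectivity_result as a seed-voxel x target matrix, in the
# same seed order as oracle_track
result_count_matrix <- function(result) {
  idx <- which(result$seed_mask$data != 0, arr.ind = TRUE)
  m <- vapply(result$counts, function(g) g$data[idx], numeric(nrow(idx)))
  matrix(m, nrow = nrow(idx), dimnames = list(NULL, names(result$counts)))
}

# fabricate a connectivity_result from explicit per-target count arrays
fake_result <- function(counts_list, seed_mask, n_samples) {
  structure(list(counts = lapply(counts_list, grid_like, grid = seed_mask),
                 n_samples = n_samples, seed_mask = seed_mask,
                 config = NULL),
            class = "connectivity_result")
}
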