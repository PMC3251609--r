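#' Describe one synthetic thalamo-cortical bundle
#'
#' A bundle is a curved tube of coherent fibre orientations running from a
#' ground-truth origin inside the thalamus to the centre of a spherical
#' cortical target patch. The centreline is a quadratic Bezier curve whose
#' control point is the midpoint of the endpoints displaced by `bend_mm`,
#' giving a gently curved trajectory. Voxels whose centres lie within
#' `bundle_radius_mm` of the centreline carry the local tangent as their
#' fibre orientation; `dispersion_deg` is the angular SD of the orientation
#' uncertainty sampled during tracking.
#'
#' @param target_name Name of the cortical target (e.g. `"premotor"`,
#'   `"motor"`).
#' @param thalamic_origin_mm Ground-truth peak location inside the thalamus
#'   (mm).
#' @param cortical_patch_center_mm Centre of the spherical cortical patch
#'   (mm).
#' @param cortical_patch_radius_mm Patch radius (mm).
#' @param bundle_radius_mm Tube radius of the bundle (mm).
#' @param dispersion_deg Angular SD of orientation noise, in `[0, 90)`
#'   degrees.
#' @param bend_mm Length-3 displacement of the Bezier control point (mm);
#'   `c(0,0,0)` gives a straight bundle.
#' @return An object of class `bundle_spec`.
#' @export
bundle_spec <- function(target_name, thalamic_origin_mm,
                        cortical_patch_center_mm,
                        cortical_patch_radius_mm = 2.5,
                        bundle_radius_mm = 1.2,
                        dispersion_deg = 10,
                        bend_mm = c(0, 0, 0)) {
  stopifnot(is.character(target_name), nchar(target_name) > 0,
            length(thalamic_origin_mm) == 3L,
            length(cortical_patch_center_mm) == 3L,
            cortical_patch_radius_mm > 0, bundle_radius_mm > 0,
            length(bend_mm) == 3L)
  if (dispersion_deg < 0 || dispersion_deg >= 90)
    stop("dispersion_deg must lie in [0, 90)")
  structure(list(target_name = target_name,
                 thalamic_origin_mm = as.numeric(thalamic_origin_mm),
                 cortical_patch_center_mm = as.numeric(cortical_patch_center_mm),
                 cortical_patch_radius_mm = cortical_patch_radius_mm,
                 bundle_radius_mm = bundle_radius_mm,
                 dispersion_deg = dispersion_deg,
                 bend_mm = as.numeric(bend_mm)),
            class = "bundle_spec")
}

#' Specify a digital fibre phantom
#'
#' Defines a synthetic "head": an isotropic voxel grid fully covered by the
#' brain mask, a spherical thalamus, one curved fibre bundle per cortical
#' target, and AC/PC/interhemispheric landmarks. The defaults give a
#' 32-voxel cube at 1 mm with a premotor (Vop-like) and a motor (Vim-like)
#' bundle leaving the thalamus towards two disjoint cortical patches.
#'
#' @param grid_shape Integer triple of grid dimensions (each >= 16).
#' @param voxel_size_mm Isotropic voxel size (mm).
#' @param thalamus_center_mm,thalamus_radius_mm Thalamus sphere (mm).
#' @param bundles List of [bundle_spec()] objects.
#' @param landmarks A [landmark_set()] (AC, PC, interhemispheric point).
#' @param seed Integer seed associated with the subject.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         voxel_size_mm = 1,
                         thalamus_center_mm = c(16, 13, 16),
                         thalamus_radius_mm = 6.5,
                         bundles = default_bundles(),
                         landmarks = landmark_set(AC = c(16, 24, 14),
                                                  PC = c(16, 4, 14),
                                                  IH = c(16, 14, 28)),
                         seed = 1L) {
  spec <- structure(list(grid_shape = as.integer(grid_shape),
                         voxel_size_mm = voxel_size_mm,
                         thalamus_center_mm = as.numeric(thalamus_center_mm),
                         thalamus_radius_mm = thalamus_radius_mm,
                         bundles = bundles,
                         landmarks = landmarks,
                         seed = as.integer(seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' @rdname phantom_spec
#' @export
default_bundles <- function() {
  list(
    bundle_spec("premotor",
                thalamic_origin_mm = c(13.5, 16, 17.5),
                cortical_patch_center_mm = c(12, 28, 20),
                bend_mm = c(0, 0, 2.5)),
    bundle_spec("motor",
                thalamic_origin_mm = c(18.5, 16, 14.5),
                cortical_patch_center_mm = c(20, 28, 12),
                bend_mm = c(0, 0, -2.5)))
}

validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(spec$grid_shape) != 3L || any(spec$grid_shape < 16L))
    stop("invalid phantom spec: grid_shape components must be >= 16")
  if (spec$voxel_size_mm <= 0)
    stop("invalid phantom spec: voxel_size_mm must be positive")
  if (spec$thalamus_radius_mm <= 0)
    stop("invalid phantom spec: thalamus_radius_mm must be positive")
  if (!length(spec$bundles) || !all(vapply(spec$bundles, inherits,
                                           logical(1), "bundle_spec")))
    stop("invalid phantom spec: bundles must be a list of bundle_spec")
  nm <- vapply(spec$bundles, `[[`, character(1), "target_name")
  if (anyDuplicated(nm))
    stop("invalid phantom spec: duplicated bundle target names")
  if (!inherits(spec$landmarks, "landmark_set"))
    stop("invalid phantom spec: landmarks must be a landmark_set")
  ext_lo <- -0.5 * spec$voxel_size_mm
  ext_hi <- (spec$grid_shape - 0.5) * spec$voxel_size_mm
  inside_grid <- function(p) all(p > ext_lo) && all(p < ext_hi)
  for (b in spec$bundles) {
    if (euclidean_distance(b$thalamic_origin_mm, spec$thalamus_center_mm) >=
        spec$thalamus_radius_mm)
      stop(sprintf("invalid phantom spec: origin of bundle '%s' lies outside the thalamus",
                   b$target_name))
    if (!inside_grid(b$thalamic_origin_mm) ||
        !inside_grid(b$cortical_patch_center_mm))
      stop(sprintf("invalid phantom spec: bundle '%s' endpoint outside the grid",
                   b$target_name))
    if (euclidean_distance(b$cortical_patch_center_mm,
                           spec$thalamus_center_mm) <=
        b$cortical_patch_radius_mm + spec$thalamus_radius_mm)
      stop(sprintf("invalid phantom spec: cortical patch of '%s' intersects the thalamus",
                   b$target_name))
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s voxels @ %g mm, thalamus r=%g mm, %d bundle(s): %s (seed %d)\n",
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm,
              x$thalamus_radius_mm, length(x$bundles),
              paste(vapply(x$bundles, `[[`, character(1), "target_name"),
                    collapse = ", "),
              x$seed))
  invisible(x)
}

#' Generate one synthetic subject from a phantom specification
#'
#' Builds the brain mask (whole grid), the spherical thalamus mask, one
#' binary cortical target mask per bundle, the per-voxel fibre orientation
#' field (bundle tangents; up to two directions where bundles cross;
#' isotropic elsewhere) and the landmark set. The ground-truth peak of each
#' bundle is its thalamic origin. Generation is deterministic for a given
#' spec.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `synthetic_subject` with elements
#'   `brain_mask`, `thalamus_mask`, `target_masks` (named list),
#'   `orientation_field`, `landmarks`, `truth_peaks_mm` (named list),
#'   `spec` and `applied_transform` (NULL until posed).
#' @export
generate_subject <- function(spec) {
  validate_phantom_spec(spec)
  shp <- spec$grid_shape
  vs <- spec$voxel_size_mm
  ref <- voxel_grid(array(1L, dim = shp), spacing = vs)

  idx <- as.matrix(expand.grid(i = seq_len(shp[1]) - 1L,
                               j = seq_len(shp[2]) - 1L,
                               k = seq_len(shp[3]) - 1L))
  centers <- idx * vs
  d2 <- function(p) rowSums(sweep(centers, 2, p)^2)

  thal <- array(as.integer(d2(spec$thalamus_center_mm) <=
                             spec$thalamus_radius_mm^2), dim = shp)
  thalamus_mask <- grid_like(ref, thal)

  target_masks <- list()
  for (b in spec$bundles) {
    tm <- array(as.integer(d2(b$cortical_patch_center_mm) <=
                             b$cortical_patch_radius_mm^2), dim = shp)
    if (any(tm & thal))
      stop(sprintf("invalid phantom spec: target mask '%s' overlaps the thalamus",
                   b$target_name))
    if (!any(tm))
      stop(sprintf("invalid phantom spec: target mask '%s' is empty on this grid",
                   b$target_name))
    target_masks[[b$target_name]] <- grid_like(ref, tm)
  }

  nvox <- prod(shp)
  dirs <- array(0, dim = c(shp, 6L))
  ndirs <- array(0L, dim = shp)
  disp <- array(0, dim = shp)
  owner <- integer(nvox)   # bundle index that claimed slot 1

  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    vox <- voxelise_bundle(b, shp, vs)
    for (r in seq_len(nrow(vox$idx))) {
      v <- vox$lin[r]
      tg <- vox$tangents[r, ]
      if (owner[v] == 0L) {
        owner[v] <- bi
        ndirs[v] <- 1L
        dirs[v] <- tg[1]; dirs[v + nvox] <- tg[2]; dirs[v + 2 * nvox] <- tg[3]
        disp[v] <- b$dispersion_deg
      } else if (owner[v] != bi && ndirs[v] == 1L) {
        ndirs[v] <- 2L
        dirs[v + 3 * nvox] <- tg[1]
        dirs[v + 4 * nvox] <- tg[2]
        dirs[v + 5 * nvox] <- tg[3]
        disp[v] <- max(disp[v], b$dispersion_deg)
      }
    }
  }

  field <- orientation_field(dirs, ndirs, disp, affine = ref$affine)
  truth <- lapply(spec$bundles, `[[`, "thalamic_origin_mm")
  names(truth) <- vapply(spec$bundles, `[[`, character(1), "target_name")

  structure(list(brain_mask = ref,
                 thalamus_mask = thalamus_mask,
                 target_masks = target_masks,
                 orientation_field = field,
                 landmarks = spec$landmarks,
                 truth_peaks_mm = truth,
                 spec = spec,
                 applied_transform = NULL),
            class = "synthetic_subject")
}

# Mark voxels within bundle_radius of the Bezier centreline; each voxel gets
# the tangent of the nearest centreline sample. Returns 0-based voxel
# indices, linear indices (1-based) and unit tangents.
voxelise_bundle <- function(b, shp, vs) {
  A <- b$thalamic_origin_mm
  B <- b$cortical_patch_center_mm
  C <- (A + B) / 2 + b$bend_mm
  len <- euclidean_distance(A, C) + euclidean_distance(C, B)
  nt <- max(8L, ceiling(6 * len / vs))
  t <- seq(0, 1, length.out = nt)
  pts <- outer((1 - t)^2, A) + outer(2 * t * (1 - t), C) + outer(t^2, B)
  tan <- outer(2 * (1 - t), C - A) + outer(2 * t, B - C)
  tan <- tan / sqrt(rowSums(tan^2))

  m <- ceiling(b$bundle_radius_mm / vs + 0.5)
  offs <- as.matrix(expand.grid(-m:m, -m:m, -m:m))
  no <- nrow(offs)

  base <- round(pts / vs)
  cand_idx <- base[rep(seq_len(nt), each = no), ] + offs[rep(seq_len(no), nt), ]
  cand_sample <- rep(seq_len(nt), each = no)
  ok <- cand_idx[, 1] >= 0 & cand_idx[, 1] < shp[1] &
    cand_idx[, 2] >= 0 & cand_idx[, 2] < shp[2] &
    cand_idx[, 3] >= 0 & cand_idx[, 3] < shp[3]
  cand_idx <- cand_idx[ok, , drop = FALSE]
  cand_sample <- cand_sample[ok]
  d <- sqrt(rowSums((cand_idx * vs - pts[cand_sample, , drop = FALSE])^2))
  keep <- d <= b$bundle_radius_mm
  cand_idx <- cand_idx[keep, , drop = FALSE]
  cand_sample <- cand_sample[keep]
  d <- d[keep]

  lin <- 1L + cand_idx[, 1] + shp[1] * (cand_idx[, 2] + shp[2] * cand_idx[, 3])
  ord <- order(lin, d)
  first <- !duplicated(lin[ord])
  sel <- ord[first]
  list(idx = cand_idx[sel, , drop = FALSE],
       lin = lin[sel],
       tangents = tan[cand_sample[sel], , drop = FALSE])
}

#' Generate a synthetic cohort with displaced truth peaks
#'
#' Each subject is a copy of the base phantom whose bundle origins (the
#' ground-truth peaks) receive an independent 3D Gaussian offset with
#' per-axis SD `peak_sd_mm`. Offsets that would push an origin outside the
#' thalamus are redrawn (up to 100 attempts) so that, when the SD is small
#' relative to the thalamus radius, the offset distribution stays Gaussian
#' and the closed-form mean pairwise distance 4*sigma/sqrt(pi) applies.
#' Optionally every subject also receives a random rigid head pose (recorded
#' in `applied_transform`, the ground truth for registration).
#'
#' @param base A [phantom_spec()].
#' @param n_subjects Number of subjects (>= 2).
#' @param peak_sd_mm Per-axis SD of the truth-peak displacement (mm, >= 0).
#' @param seed Integer seed for the whole cohort.
#' @param pose_jitter Apply a random rigid transform per subject?
#' @param max_rotation_deg,max_translation_mm Pose jitter bounds.
#' @return List of [generate_subject()] results (class `phantom_cohort`),
#'   with the base spec and generation parameters in attributes.
#' @export
generate_cohort <- function(base, n_subjects, peak_sd_mm, seed = 1L,
                            pose_jitter = TRUE, max_rotation_deg = 8,
                            max_translation_mm = 4) {
  validate_phantom_spec(base)
  if (n_subjects < 2L) stop("a cohort needs at least 2 subjects")
  if (peak_sd_mm < 0) stop("peak_sd_mm must be >= 0")
  set.seed(seed)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    spec_i <- base
    for (bi in seq_along(spec_i$bundles)) {
      b <- spec_i$bundles[[bi]]
      origin <- b$thalamic_origin_mm
      placed <- FALSE
      for (try in seq_len(100L)) {
        cand <- origin + rnorm(3L, sd = peak_sd_mm)
        if (euclidean_distance(cand, base$thalamus_center_mm) <
            base$thalamus_radius_mm) {
          spec_i$bundles[[bi]]$thalamic_origin_mm <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed)
        warning(sprintf(
          "subject %d, bundle '%s': peak displacement clamped (peak_sd_mm=%g saturates the thalamus radius)",
          i, b$target_name, peak_sd_mm))
    }
    spec_i$seed <- sample.int(.Machine$integer.max - 1L, 1L)
    subj <- generate_subject(spec_i)
    if (pose_jitter) {
      pose <- random_rigid_transform(max_rotation_deg, max_translation_mm)
      subj <- transform_subject(subj, pose)
    }
    subjects[[i]] <- subj
  }
  structure(subjects, class = "phantom_cohort",
            base_spec = base, peak_sd_mm = peak_sd_mm, seed = seed,
            pose_jitter = pose_jitter)
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects, peak SD %g mm, seed %d\n",
              length(x), attr(x, "peak_sd_mm"), attr(x, "seed")))
  invisible(x)
}

#' Move a synthetic subject into a new head pose
#'
#' Applies a rigid transform to the subject's world frame: all grid affines
#' are composed with the transform, stored fibre directions are rotated, and
#' landmarks and truth peaks are mapped. Voxel data are untouched (no
#' resampling).
#'
#' @param subject A [generate_subject()] result.
#' @param transform A [rigid_transform()].
#' @return The transformed `synthetic_subject`; `applied_transform` records
#'   the cumulative pose.
#' @export
transform_subject <- function(subject, transform) {
  stopifnot(inherits(subject, "synthetic_subject"),
            inherits(transform, "rigid_transform"))
  subject$brain_mask <- transform_grid(subject$brain_mask, transform)
  subject$thalamus_mask <- transform_grid(subject$thalamus_mask, transform)
  subject$target_masks <- lapply(subject$target_masks, transform_grid,
                                 transform = transform)
  subject$orientation_field <-
    transform_orientation_field(subject$orientation_field, transform)
  subject$landmarks <- transform_landmarks(subject$landmarks, transform)
  subject$truth_peaks_mm <- lapply(subject$truth_peaks_mm,
                                   function(p) apply_transform(transform, p))
  subject$applied_transform <-
    if (is.null(subject$applied_transform)) transform
    else compose_transforms(transform, subject$applied_transform)
  subject
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("<synthetic_subject> %s voxels, targets: %s; %d thalamic voxels\n",
              paste(dim(x$brain_mask), collapse = "x"),
              paste(names(x$target_masks), collapse = ", "),
              sum(x$thalamus_mask$data)))
  invisible(x)
}
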