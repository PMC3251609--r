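#' Per-voxel fibre orientation field
#'
#' Stores up to two unit fibre directions per voxel (the multi-fibre case,
#' e.g. where two bundles cross) together with a per-voxel angular
#' dispersion. Voxels with zero directions are isotropic: streamlines cannot
#' propagate through them.
#'
#' @param dirs Numeric array of dimension `c(nx, ny, nz, 6)`: components
#'   1--3 are the first direction, 4--6 the second (zeros where absent).
#' @param ndirs Integer array `c(nx, ny, nz)` with values 0, 1 or 2.
#' @param dispersion_deg Numeric array `c(nx, ny, nz)`: angular SD (degrees)
#'   of the orientation uncertainty at each voxel.
#' @param affine 4x4 grid-to-world matrix (0-based voxel index to mm).
#' @param tol Unit-norm tolerance for stored directions.
#' @return An object of class `orientation_field`.
#' @export
orientation_field <- function(dirs, ndirs, dispersion_deg, affine,
                              tol = 1e-6) {
  stopifnot(length(dim(dirs)) == 4L, dim(dirs)[4] == 6L)
  shp <- dim(dirs)[1:3]
  stopifnot(all(dim(ndirs) == shp), all(dim(dispersion_deg) == shp),
            all(ndirs %in% 0:2), all(dispersion_deg >= 0))
  nvox <- prod(shp)
  dm <- matrix(dirs, nvox, 6L)
  n1 <- sqrt(rowSums(dm[, 1:3, drop = FALSE]^2))
  n2 <- sqrt(rowSums(dm[, 4:6, drop = FALSE]^2))
  if (any(abs(n1[ndirs >= 1L] - 1) > tol) ||
      any(abs(n2[ndirs == 2L] - 1) > tol))
    stop("stored fibre directions must be unit vectors")
  affine <- matrix(as.numeric(affine), 4L, 4L)
  structure(list(dirs = dirs, ndirs = ndirs,
                 dispersion_deg = dispersion_deg, affine = affine,
                 spacing = sqrt(colSums(affine[1:3, 1:3]^2))),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %s voxels; %d single-fibre, %d two-fibre; dispersion %g-%g deg\n",
              paste(dim(x$ndirs), collapse = "x"),
              sum(x$ndirs == 1L), sum(x$ndirs == 2L),
              min(x$dispersion_deg[x$ndirs > 0L]),
              max(x$dispersion_deg)))
  invisible(x)
}

# rotate the stored directions and the affine of a field
transform_orientation_field <- function(field, transform) {
  stopifnot(inherits(field, "orientation_field"))
  shp <- dim(field$ndirs)
  nvox <- prod(shp)
  dm <- matrix(field$dirs, nvox, 6L)
  R <- transform$rotation
  dm[, 1:3] <- dm[, 1:3, drop = FALSE] %*% t(R)
  dm[, 4:6] <- dm[, 4:6, drop = FALSE] %*% t(R)
  orientation_field(array(dm, dim = c(shp, 6L)), field$ndirs,
                    field$dispersion_deg,
                    as_matrix4(transform) %*% field$affine)
}

#' Tracking configuration
#'
#' Parameters of the probabilistic streamline sampler. The default of 5000
#' samples per seed voxel matches standard connectivity-mapping practice;
#' the step defaults to half the voxel size and propagation stops when the
#' per-step turning angle exceeds `curvature_limit_deg`.
#'
#' @param n_samples_per_voxel Streamlines launched per seed voxel (>= 1).
#' @param step_mm Step length (mm); `NULL` means half the voxel size of the
#'   orientation field at tracking time. Must not exceed the voxel size.
#' @param max_steps Maximum steps per streamline.
#' @param curvature_limit_deg Per-step turning-angle limit, in (0, 180].
#' @param rng_seed Integer seed; every tracking call is deterministic given
#'   the configuration.
#' @return An object of class `tracking_config`.
#' @export
tracking_config <- function(n_samples_per_voxel = 5000L, step_mm = NULL,
                            max_steps = 2000L, curvature_limit_deg = 80,
                            rng_seed = 1L) {
  stopifnot(n_samples_per_voxel >= 1L, max_steps >= 1L,
            curvature_limit_deg > 0, curvature_limit_deg <= 180)
  if (!is.null(step_mm) && step_mm <= 0) stop("step_mm must be positive")
  structure(list(n_samples_per_voxel = as.integer(n_samples_per_voxel),
                 step_mm = step_mm, max_steps = as.integer(max_steps),
                 curvature_limit_deg = curvature_limit_deg,
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_config")
}

resolve_step <- function(config, field) {
  step <- config$step_mm
  if (is.null(step)) step <- min(field$spacing) / 2
  if (step > min(field$spacing) + 1e-9)
    stop("step_mm must not exceed the voxel size")
  step
}

check_field_geometry <- function(field, grid, what) {
  if (!all(dim(field$ndirs) == dim(grid)) ||
      max(abs(field$affine - grid$affine)) > 1e-6)
    stop(sprintf("%s must share the orientation field's grid geometry", what))
}

#' Propagate a single streamline
#'
#' Stochastic streamline propagation: at each step one of the voxel's stored
#' directions is chosen uniformly, perturbed by a Gaussian angular deviate
#' with the voxel's dispersion (on the tangent plane of the unit sphere),
#' sign-flipped to within 90 degrees of the previous step, and followed for
#' `step_mm`. Propagation stops on leaving the brain mask, entering an
#' isotropic voxel, exceeding `max_steps`, or turning more than the
#' curvature limit in one step. The first step follows the stored direction
#' sign.
#'
#' @param start_mm Seed point (mm), inside the brain mask.
#' @param field An [orientation_field()].
#' @param brain_mask Binary `voxel_grid` on the same geometry.
#' @param config A [tracking_config()]. Its `rng_seed` is applied before
#'   propagation (set it to `NULL` to consume the current RNG stream, e.g.
#'   inside a caller that manages seeding).
#' @return n x 3 matrix of visited mm positions (first row = start).
#' @export
propagate_streamline <- function(start_mm, field, brain_mask, config) {
  stopifnot(inherits(field, "orientation_field"))
  assert_binary_mask(brain_mask, "brain_mask")
  check_field_geometry(field, brain_mask, "brain_mask")
  step <- resolve_step(config, field)
  fr <- world_to_voxel(brain_mask, start_mm)
  v <- round(fr)
  shp <- dim(brain_mask)
  if (any(v < 0) || any(v >= shp) ||
      brain_mask$data[matrix(v + 1, nrow = 1)] == 0)
    stop("start_mm lies outside the brain mask")
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  cpp_propagate(as.numeric(start_mm), dim(field$ndirs), solve(field$affine),
                field$dirs, field$ndirs, field$dispersion_deg * pi / 180,
                as.integer(brain_mask$data), step, config$max_steps,
                cos(config$curvature_limit_deg * pi / 180))
}

#' Probabilistic tractography from a seed mask with target counters
#'
#' Launches `n_samples_per_voxel` streamlines from the centre of every voxel
#' of the seed mask. A per-target counter at the seed voxel is incremented
#' the first time a streamline enters that target mask (at most once per
#' streamline and target), so `counts / n_samples` estimates the probability
#' that the seed voxel is connected to the target.
#'
#' @param seed_mask Binary `voxel_grid` (nonempty), e.g. the thalamus.
#' @param targets Named list of binary `voxel_grid` target masks, disjoint
#'   from the seed mask.
#' @param field An [orientation_field()].
#' @param brain_mask Binary `voxel_grid` on the same geometry.
#' @param config A [tracking_config()].
#' @return An object of class `connectivity_result`: `counts` (named list of
#'   integer `voxel_grid`s over the seed mask), `n_samples`, `seed_mask`,
#'   `config`.
#' @export
track_from_mask <- function(seed_mask, targets, field, brain_mask,
                            config = tracking_config()) {
  assert_binary_mask(seed_mask, "seed_mask")
  assert_binary_mask(brain_mask, "brain_mask")
  check_field_geometry(field, seed_mask, "seed_mask")
  check_field_geometry(field, brain_mask, "brain_mask")
  if (!sum(seed_mask$data)) stop("seed mask is empty")
  if (!is.list(targets) || !length(targets) || is.null(names(targets)))
    stop("targets must be a nonempty named list of masks")
  labels <- array(0L, dim = dim(seed_mask))
  for (k in seq_along(targets)) {
    assert_binary_mask(targets[[k]], names(targets)[k])
    check_field_geometry(field, targets[[k]], names(targets)[k])
    if (!sum(targets[[k]]$data))
      stop(sprintf("target '%s' is empty", names(targets)[k]))
    if (any(targets[[k]]$data & seed_mask$data))
      stop(sprintf("target '%s' overlaps the seed mask", names(targets)[k]))
    labels[targets[[k]]$data != 0] <- k
  }
  step <- resolve_step(config, field)
  seeds <- mask_indices(seed_mask)
  seeds_mm <- voxel_to_world(seed_mask, seeds)
  set.seed(config$rng_seed)
  cm <- cpp_track_mask(seeds_mm, length(targets), labels, dim(field$ndirs),
                       solve(field$affine), field$dirs, field$ndirs,
                       field$dispersion_deg * pi / 180,
                       as.integer(brain_mask$data),
                       config$n_samples_per_voxel, step, config$max_steps,
                       cos(config$curvature_limit_deg * pi / 180))
  counts <- lapply(seq_along(targets), function(k) {
    a <- array(0L, dim = dim(seed_mask))
    a[seeds + 1L] <- cm[, k]
    grid_like(seed_mask, a)
  })
  names(counts) <- names(targets)
  tt_log("tracked %d seed voxels x %d samples towards %d target(s)",
         nrow(seeds), config$n_samples_per_voxel, length(targets))
  structure(list(counts = counts,
                 n_samples = config$n_samples_per_voxel,
                 seed_mask = seed_mask, config = config),
            class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity_result> %d seed voxels, %d samples/voxel, targets: %s\n",
              sum(x$seed_mask$data), x$n_samples,
              paste(names(x$counts), collapse = ", ")))
  invisible(x)
}

#' Connection probability map for one target
#'
#' @param result A [track_from_mask()] result.
#' @param target Target name.
#' @return `voxel_grid` of counts / n_samples over the seed mask.
#' @export
connection_probability <- function(result, target) {
  stopifnot(inherits(result, "connectivity_result"))
  cg <- result$counts[[target]]
  if (is.null(cg)) stop(sprintf("unknown target '%s'", target))
  grid_like(cg, cg$data / result$n_samples)
}

#' Whole-brain visitation map from a lesion seed
#'
#' Launches `n_samples_per_voxel` streamlines from every lesion voxel and
#' counts, for each brain voxel, the number of distinct streamlines that
#' entered it (each streamline contributes at most 1 per voxel). The result
#' is suitable for display thresholding at a particle count, e.g. 10% of
#' the launched samples.
#'
#' @param lesion_mask Binary `voxel_grid` inside the brain mask, nonempty.
#' @param field An [orientation_field()].
#' @param brain_mask Binary `voxel_grid`.
#' @param config A [tracking_config()].
#' @return Integer `voxel_grid` of visitation counts.
#' @export
track_from_lesion <- function(lesion_mask, field, brain_mask,
                              config = tracking_config()) {
  assert_binary_mask(lesion_mask, "lesion_mask")
  assert_binary_mask(brain_mask, "brain_mask")
  check_field_geometry(field, lesion_mask, "lesion_mask")
  check_field_geometry(field, brain_mask, "brain_mask")
  if (!sum(lesion_mask$data)) stop("lesion mask is empty")
  if (any(lesion_mask$data & !brain_mask$data))
    stop("lesion mask must lie inside the brain mask")
  step <- resolve_step(config, field)
  seeds_mm <- voxel_to_world(lesion_mask, mask_indices(lesion_mask))
  set.seed(config$rng_seed)
  vis <- cpp_track_lesion(seeds_mm, dim(field$ndirs), solve(field$affine),
                          field$dirs, field$ndirs,
                          field$dispersion_deg * pi / 180,
                          as.integer(brain_mask$data),
                          config$n_samples_per_voxel, step, config$max_steps,
                          cos(config$curvature_limit_deg * pi / 180))
  grid_like(brain_mask, array(vis, dim = dim(brain_mask)))
}
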