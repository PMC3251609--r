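#' Read and write volumes as NIfTI
#'
#' Volumes are stored in NIfTI-1 format with the grid-to-world affine in the
#' sform (mm, RAS). Integer data are written as int32 and floating point as
#' float64, so a write/read round trip preserves both values and geometry
#' exactly.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume()`: a [voxel_grid()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such volume file: '%s'", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf(
                    "malformed volume '%s': %s", path, conditionMessage(e))))
  a <- strip_nifti_attrs(as.array(img))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L)
    a <- array(a, dim = dim(a)[1:3])
  if (length(dim(a)) != 3L)
    stop(sprintf("malformed volume '%s': expected a 3D image", path))
  voxel_grid(a, affine = unclass(RNifti::xform(img)))
}

#' @rdname read_volume
#' @param grid A [voxel_grid()] (`write_volume`) or 4D array
#'   (`write_volume_4d`).
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("parent directory does not exist: '%s'", dirname(path)))
  dt <- if (is.integer(grid$data)) "int" else "double"
  img <- RNifti::asNifti(grid$data, datatype = dt)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read a volume that must be a binary mask
#'
#' @rdname read_volume
#' @export
read_mask <- function(path) {
  g <- read_volume(path)
  if (!all(g$data %in% c(0, 1)))
    stop(sprintf("'%s' is not a binary mask (values outside {0,1})", path))
  grid_like(g, array(as.integer(g$data), dim = dim(g)))
}

strip_nifti_attrs <- function(a) {
  d <- dim(a)
  array(as.vector(unclass(a)), dim = d)
}

# 4D helper used for orientation fields
write_volume_4d <- function(data, affine, path) {
  img <- RNifti::asNifti(data, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Write and read an orientation field
#'
#' The field is stored as two NIfTI volumes: a 4D 6-component direction
#' volume (two 3-vectors per voxel, zeros where absent) and a 3D angular
#' dispersion volume (degrees). The per-voxel direction count is recovered
#' from the non-zero direction norms.
#'
#' @param field An [orientation_field()].
#' @param prefix Path prefix; `<prefix>_orient.nii.gz` and
#'   `<prefix>_dispersion.nii.gz` are written.
#' @return `read_orientation_field()`: an `orientation_field`.
#' @export
write_orientation_field <- function(field, prefix) {
  stopifnot(inherits(field, "orientation_field"))
  write_volume_4d(field$dirs, field$affine,
                  paste0(prefix, "_orient.nii.gz"))
  write_volume(voxel_grid(field$dispersion_deg, affine = field$affine),
               paste0(prefix, "_dispersion.nii.gz"))
  invisible(prefix)
}

#' @rdname write_orientation_field
#' @export
read_orientation_field <- function(prefix) {
  op <- paste0(prefix, "_orient.nii.gz")
  if (!file.exists(op)) stop(sprintf("no such orientation file: '%s'", op))
  img <- RNifti::readNifti(op)
  dirs <- strip_nifti_attrs(as.array(img))
  if (length(dim(dirs)) != 4L || dim(dirs)[4] != 6L)
    stop(sprintf("malformed orientation volume '%s': expected 6 components", op))
  disp <- read_volume(paste0(prefix, "_dispersion.nii.gz"))
  shp <- dim(dirs)[1:3]
  nvox <- prod(shp)
  dm <- matrix(dirs, nvox, 6L)
  ndirs <- array((sqrt(rowSums(dm[, 1:3, drop = FALSE]^2)) > 0.5) +
                   (sqrt(rowSums(dm[, 4:6, drop = FALSE]^2)) > 0.5),
                 dim = shp)
  storage.mode(ndirs) <- "integer"
  orientation_field(dirs, ndirs, disp$data,
                    unclass(RNifti::xform(img)))
}

#' Landmark JSON I/O
#'
#' Landmarks are stored as `{"AC": [x,y,z], "PC": ..., "IH": ...}` in
#' millimetres (RAS template convention).
#'
#' @param lm A [landmark_set()].
#' @param path JSON file path.
#' @return `read_landmarks()`: a `landmark_set`.
#' @export
write_landmarks <- function(lm, path) {
  stopifnot(inherits(lm, "landmark_set"))
  jsonlite::write_json(unclass(lm), path, digits = NA)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such landmark file: '%s'", path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!all(c("AC", "PC", "IH") %in% names(x)))
    stop(sprintf("malformed landmark file '%s': needs AC, PC and IH", path))
  landmark_set(x$AC, x$PC, x$IH)
}

#' Rigid transform text I/O
#'
#' Transforms are stored as whitespace-separated 4x4 homogeneous matrices
#' (world mm to world mm).
#'
#' @param transform A [rigid_transform()].
#' @param path Text file path.
#' @return `read_transform()`: a `rigid_transform`.
#' @export
write_transform <- function(transform, path) {
  m <- as_matrix4(transform)
  utils::write.table(format(m, digits = 17), path, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such transform file: '%s'", path))
  m <- as.matrix(utils::read.table(path))
  if (!all(dim(m) == c(4L, 4L)))
    stop(sprintf("malformed transform file '%s': expected a 4x4 matrix", path))
  rigid_transform(m[1:3, 1:3], m[1:3, 4], tol = 1e-6)
}

#' Write a synthetic subject as a BIDS-flavoured directory
#'
#' Writes `sub-<k>_brain.nii.gz`, `sub-<k>_thalamus.nii.gz`, one
#' `sub-<k>_target-<name>.nii.gz` per cortical target, the orientation
#' field, `sub-<k>_landmarks.json` and `sub-<k>_truth.json` (ground-truth
#' peaks and, when posed, the applied rigid transform).
#'
#' @param subject A [generate_subject()] result.
#' @param dir Output directory (created if missing).
#' @param id Subject number used in the `sub-<k>` prefix.
#' @return `read_subject()`: a `synthetic_subject` (without the generating
#'   spec).
#' @export
write_subject <- function(subject, dir, id = 1L) {
  stopifnot(inherits(subject, "synthetic_subject"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(dir, sprintf("sub-%d", id))
  write_volume(subject$brain_mask, paste0(pre, "_brain.nii.gz"))
  write_volume(subject$thalamus_mask, paste0(pre, "_thalamus.nii.gz"))
  for (tn in names(subject$target_masks))
    write_volume(subject$target_masks[[tn]],
                 sprintf("%s_target-%s.nii.gz", pre, tn))
  write_orientation_field(subject$orientation_field, pre)
  write_landmarks(subject$landmarks, paste0(pre, "_landmarks.json"))
  truth <- list(truth_peaks_mm = subject$truth_peaks_mm)
  if (!is.null(subject$applied_transform))
    truth$applied_transform <- as_matrix4(subject$applied_transform)
  jsonlite::write_json(truth, paste0(pre, "_truth.json"), digits = NA)
  invisible(pre)
}

#' @rdname write_subject
#' @export
read_subject <- function(dir, id = 1L) {
  pre <- file.path(dir, sprintf("sub-%d", id))
  brain <- read_mask(paste0(pre, "_brain.nii.gz"))
  thal <- read_mask(paste0(pre, "_thalamus.nii.gz"))
  tfiles <- list.files(dir, sprintf("^sub-%d_target-.*\\.nii\\.gz$", id),
                       full.names = TRUE)
  targets <- lapply(tfiles, read_mask)
  names(targets) <- sub(sprintf("^sub-%d_target-(.*)\\.nii\\.gz$", id), "\\1",
                        basename(tfiles))
  field <- read_orientation_field(pre)
  lm <- read_landmarks(paste0(pre, "_landmarks.json"))
  truth <- jsonlite::read_json(paste0(pre, "_truth.json"),
                               simplifyVector = TRUE)
  applied <- NULL
  if (!is.null(truth$applied_transform)) {
    m <- matrix(unlist(truth$applied_transform), 4L, 4L, byrow = FALSE)
    applied <- rigid_transform(m[1:3, 1:3], m[1:3, 4], tol = 1e-6)
  }
  structure(list(brain_mask = brain, thalamus_mask = thal,
                 target_masks = targets, orientation_field = field,
                 landmarks = lm,
                 truth_peaks_mm = lapply(truth$truth_peaks_mm, as.numeric),
                 spec = NULL, applied_transform = applied),
            class = "synthetic_subject")
}

#' Phantom specification YAML I/O
#'
#' @param spec A [phantom_spec()].
#' @param path YAML file path.
#' @return `read_phantom_spec()`: a `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  validate_phantom_spec(spec)
  x <- list(grid_shape = spec$grid_shape,
            voxel_size_mm = spec$voxel_size_mm,
            thalamus_center_mm = spec$thalamus_center_mm,
            thalamus_radius_mm = spec$thalamus_radius_mm,
            landmarks = lapply(unclass(spec$landmarks), as.numeric),
            seed = spec$seed,
            bundles = lapply(spec$bundles, unclass))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such spec file: '%s'", path))
  x <- yaml::read_yaml(path)
  phantom_spec(grid_shape = x$grid_shape,
               voxel_size_mm = x$voxel_size_mm,
               thalamus_center_mm = x$thalamus_center_mm,
               thalamus_radius_mm = x$thalamus_radius_mm,
               bundles = lapply(x$bundles, function(b)
                 bundle_spec(b$target_name, b$thalamic_origin_mm,
                             b$cortical_patch_center_mm,
                             b$cortical_patch_radius_mm,
                             b$bundle_radius_mm, b$dispersion_deg,
                             b$bend_mm)),
               landmarks = landmark_set(x$landmarks$AC, x$landmarks$PC,
                                        x$landmarks$IH),
               seed = x$seed)
}
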