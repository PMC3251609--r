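#' Create a voxel grid
#'
#' A `voxel_grid` is the basic carrier for 3D volumes: probability and count
#' maps, binary masks and integer label images. It couples a 3D array with a
#' grid-to-world affine so that every voxel has well-defined millimetre
#' coordinates. Voxel indices are 0-based internally; the affine maps the
#' 0-based index of a voxel to the millimetre position of its centre
#' (RAS-style world convention, as in NIfTI).
#'
#' @param data 3D numeric, integer or logical array.
#' @param spacing Voxel edge lengths in mm (length 1 or 3). Ignored when
#'   `affine` is given.
#' @param origin World coordinates (mm) of the centre of voxel (0,0,0).
#'   Ignored when `affine` is given.
#' @param affine Optional 4x4 matrix mapping homogeneous 0-based voxel indices
#'   to world mm.
#' @return An object of class `voxel_grid` with elements `data`, `affine` and
#'   `spacing` (the per-axis voxel sizes derived from the affine).
#' @export
voxel_grid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("voxel_grid data must be a 3D array")
  if (is.logical(data)) data <- array(as.integer(data), dim = dim(data))
  if (is.null(affine)) {
    if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
    stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
    affine[1:3, 4] <- origin
  }
  if (!all(dim(as.matrix(affine)) == c(4L, 4L)))
    stop("affine must be a 4x4 homogeneous matrix")
  affine <- matrix(as.numeric(affine), 4L, 4L)
  if (any(affine[4, ] != c(0, 0, 0, 1)))
    stop("affine must be a 4x4 homogeneous matrix")
  structure(
    list(data = data,
         affine = affine,
         spacing = sqrt(colSums(affine[1:3, 1:3]^2))),
    class = "voxel_grid")
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s voxels, spacing %s mm, range [%g, %g]\n",
              paste(dim(x), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Replace the data of a grid, keeping its geometry
#'
#' @param grid A `voxel_grid` providing geometry.
#' @param data Replacement array with the same dimensions.
#' @return A `voxel_grid`.
#' @export
grid_like <- function(grid, data) {
  stopifnot(inherits(grid, "voxel_grid"), all(dim(data) == dim(grid)))
  voxel_grid(data, affine = grid$affine)
}

#' Convert 0-based voxel indices to world millimetres
#'
#' @param grid A `voxel_grid`.
#' @param idx Integer matrix (n x 3) or length-3 vector of 0-based indices.
#' @return n x 3 matrix (or length-3 vector) of mm coordinates of voxel
#'   centres.
#' @export
voxel_to_world <- function(grid, idx) {
  vec <- is.null(dim(idx))
  idx <- rbind_pts(idx)
  mm <- t(grid$affine[1:3, 1:3] %*% t(idx) + grid$affine[1:3, 4])
  if (vec) drop(mm) else mm
}

#' Convert world millimetres to fractional 0-based voxel indices
#'
#' @param grid A `voxel_grid`.
#' @param mm n x 3 matrix or length-3 vector of world coordinates.
#' @return Fractional 0-based indices (round to get the nearest voxel).
#' @export
world_to_voxel <- function(grid, mm) {
  vec <- is.null(dim(mm))
  mm <- rbind_pts(mm)
  inv <- solve(grid$affine)
  idx <- t(inv[1:3, 1:3] %*% t(mm) + inv[1:3, 4])
  if (vec) drop(idx) else idx
}

#' Test whether two grids share dimensions and affine
#'
#' @param a,b `voxel_grid` objects.
#' @param tol Tolerance on affine entries (mm).
#' @return Logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a) == dim(b)) && max(abs(a$affine - b$affine)) <= tol
}

#' Apply a rigid transform to a grid's world frame
#'
#' The voxel data are untouched; only the grid-to-world affine is composed
#' with the transform, so the same voxels acquire new world coordinates. This
#' is how phantom subjects are given distinct head poses without resampling.
#'
#' @param grid A `voxel_grid`.
#' @param transform A [rigid_transform()].
#' @return A `voxel_grid` with updated affine.
#' @export
transform_grid <- function(grid, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  voxel_grid(grid$data, affine = as_matrix4(transform) %*% grid$affine)
}

# 0-based indices of nonzero voxels, as an n x 3 integer matrix
mask_indices <- function(mask) {
  stopifnot(inherits(mask, "voxel_grid"))
  w <- which(mask$data != 0, arr.ind = TRUE)
  w - 1L
}

# accept a length-3 vector or an n x 3 matrix; always return a matrix
rbind_pts <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    matrix(as.numeric(x), nrow = 1L)
  } else {
    stopifnot(ncol(x) == 3L)
    x <- as.matrix(x)
    storage.mode(x) <- "double"
    x
  }
}

assert_binary_mask <- function(grid, what = "mask") {
  if (!inherits(grid, "voxel_grid"))
    stop(sprintf("%s must be a voxel_grid", what))
  if (!all(grid$data %in% c(0, 1)))
    stop(sprintf("%s must be binary (0/1); found other values", what))
  invisible(grid)
}
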