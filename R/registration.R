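#' Landmark set defining the AC-PC head frame
#'
#' Three millimetre-space points determine a six degree-of-freedom head frame:
#' the anterior commissure (AC), the posterior commissure (PC) and any
#' interhemispheric point off the AC-PC line (IH; the apex of the corpus
#' callosum works well). AC and PC fix the AC-PC line, IH fixes the
#' midsagittal plane.
#'
#' @param AC,PC,IH Length-3 numeric vectors, world mm (RAS convention).
#' @param tol Minimum triangle "thickness": the component of IH - AC
#'   orthogonal to the AC-PC line must exceed this (mm).
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(AC, PC, IH, tol = 1e-6) {
  lm <- list(AC = as.numeric(AC), PC = as.numeric(PC), IH = as.numeric(IH))
  if (!all(lengths(lm) == 3L)) stop("AC, PC and IH must be length-3 vectors")
  ab <- lm$PC - lm$AC
  if (sqrt(sum(ab^2)) <= tol) stop("degenerate landmarks: AC and PC coincide")
  u <- ab / sqrt(sum(ab^2))
  w <- lm$IH - lm$AC
  perp <- w - sum(w * u) * u
  if (sqrt(sum(perp^2)) <= tol)
    stop("degenerate landmarks: IH is collinear with the AC-PC line")
  structure(lm, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  fmt <- function(p) paste(sprintf("%.2f", p), collapse = ", ")
  cat(sprintf("<landmark_set> AC (%s)  PC (%s)  IH (%s) mm; AC-PC %.2f mm\n",
              fmt(x$AC), fmt(x$PC), fmt(x$IH),
              sqrt(sum((x$PC - x$AC)^2))))
  invisible(x)
}

#' Orthonormal AC-PC frame from a landmark set
#'
#' The frame has its origin at AC. Axis 1 points from AC towards PC, axis 2
#' is the component of IH - AC orthogonal to axis 1 (in-plane "up" within the
#' midsagittal plane), and axis 3 = axis1 x axis2 completes a right-handed
#' basis (the lateral axis, normal to the midsagittal plane).
#'
#' @param lm A [landmark_set()].
#' @return List with `origin` (AC, mm) and `axes` (3x3 matrix, axes in
#'   columns).
#' @export
acpc_frame <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  e1 <- lm$PC - lm$AC
  e1 <- e1 / sqrt(sum(e1^2))
  w <- lm$IH - lm$AC
  e2 <- w - sum(w * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- cross3(e1, e2)
  list(origin = lm$AC, axes = cbind(e1, e2, e3, deparse.level = 0))
}

#' Construct a rigid (6-DOF) transform
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1).
#' @param translation Length-3 translation, mm.
#' @param tol Orthonormality tolerance.
#' @return An object of class `rigid_transform` mapping p to R p + t.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            tol = 1e-8) {
  R <- unname(as.matrix(rotation))
  stopifnot(all(dim(R) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("rotation must be orthonormal with det +1")
  structure(list(rotation = R, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation (%s) mm\n",
              ang, paste(sprintf("%.2f", x$translation), collapse = ", ")))
  invisible(x)
}

#' @rdname rigid_transform
#' @param transform A `rigid_transform`.
#' @return `as_matrix4()`: the 4x4 homogeneous matrix.
#' @export
as_matrix4 <- function(transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  m <- diag(4)
  m[1:3, 1:3] <- transform$rotation
  m[1:3, 4] <- transform$translation
  m
}

#' Apply a rigid transform to points
#'
#' @param transform A [rigid_transform()].
#' @param points Length-3 vector or n x 3 matrix of mm coordinates.
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(points))
  p <- rbind_pts(points)
  out <- t(transform$rotation %*% t(p) + transform$translation)
  if (vec) drop(out) else out
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b)` returns the transform "apply b, then a".
#'
#' @param a,b,transform `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  drop(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  rigid_transform(Rt, -drop(Rt %*% transform$translation))
}

#' AC-fixed rigid normalisation from landmarks
#'
#' Computes the distance-preserving (rotation + translation only) transform
#' that takes a subject's head frame into a template frame: the subject's AC
#' is mapped exactly onto the template AC, the subject's AC-PC line onto the
#' template AC-PC line, and the subject's midsagittal plane onto the template
#' midsagittal plane. No scaling is applied, so when the two AC-PC lengths
#' differ the transformed subject PC lies on the template AC-PC line at the
#' subject's own AC-PC distance from AC.
#'
#' @param subject,template [landmark_set()] objects.
#' @return A [rigid_transform()] mapping subject world mm to template world
#'   mm.
#' @export
register_landmarks <- function(subject, template) {
  fs <- acpc_frame(subject)
  ft <- acpc_frame(template)
  R <- ft$axes %*% t(fs$axes)
  rigid_transform(R, ft$origin - drop(R %*% fs$origin), tol = 1e-6)
}

#' Apply a rigid transform to a landmark set
#'
#' @param lm A [landmark_set()].
#' @param transform A [rigid_transform()].
#' @return A transformed `landmark_set`.
#' @export
transform_landmarks <- function(lm, transform) {
  landmark_set(apply_transform(transform, lm$AC),
               apply_transform(transform, lm$PC),
               apply_transform(transform, lm$IH))
}

#' Per-landmark displacement between two point lists
#'
#' Quality-control comparison of nominally identical landmarks localised in
#' two images (e.g. the structural scan and the undistorted b=0 diffusion
#' volume): per-landmark displacement vectors and magnitudes, plus a
#' mean +/- SD summary across landmarks.
#'
#' @param a,b Named lists of length-3 mm points (same names), or
#'   `landmark_set` objects.
#' @return List with `per_landmark` (data frame: landmark, dx, dy, dz,
#'   magnitude_mm) and `summary` (mean, sd over landmarks; sample SD,
#'   n - 1 denominator).
#' @export
landmark_discrepancy <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (is.null(names(a)) || is.null(names(b)) ||
      !setequal(names(a), names(b)) || anyDuplicated(names(a)))
    stop("landmark lists must carry matching unique names")
  nm <- names(a)
  d <- t(vapply(nm, function(k) as.numeric(b[[k]]) - as.numeric(a[[k]]),
                numeric(3)))
  mag <- sqrt(rowSums(d^2))
  per <- data.frame(landmark = nm, dx = d[, 1], dy = d[, 2], dz = d[, 3],
                    magnitude_mm = mag, row.names = NULL,
                    stringsAsFactors = FALSE)
  list(per_landmark = per,
       summary = c(mean = mean(mag),
                   sd = if (length(mag) > 1L) sd(mag) else NA_real_))
}

#' Draw a random rigid transform
#'
#' Rotation drawn uniformly up to `max_angle_deg` about a uniform random
#' axis; translation components uniform in +/- `max_translation_mm`. Used to
#' give phantom subjects distinct head poses and to probe registration
#' recovery.
#'
#' @param max_angle_deg Maximum rotation angle (degrees).
#' @param max_translation_mm Maximum per-axis translation (mm).
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(max_angle_deg = 10,
                                   max_translation_mm = 5) {
  ax <- rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, max_angle_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, runif(3, -max_translation_mm, max_translation_mm),
                  tol = 1e-6)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
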