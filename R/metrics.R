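#' Euclidean distance between two millimetre points
#'
#' @param p,q Length-3 numeric vectors (mm).
#' @return Distance in mm.
#' @export
euclidean_distance <- function(p, q) {
  stopifnot(length(p) == 3L, length(q) == 3L)
  sqrt(sum((as.numeric(p) - as.numeric(q))^2))
}

#' Mean pairwise distance across subjects
#'
#' Computes the Euclidean distance between all C(n, 2) unordered pairs of
#' points (one point per subject, e.g. each subject's peak-connectivity voxel
#' in template space) and summarises them. The SD is the sample SD (n - 1
#' denominator) over the pairwise values.
#'
#' @param points n x 3 matrix of mm coordinates, n >= 2.
#' @return List with `values` (all pairwise distances), `mean`, `sd`, `min`,
#'   `max` and `n_pairs`.
#' @export
mean_pairwise_distance <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (is.null(n) || n < 2L) stop("at least two points are required")
  v <- as.numeric(dist(points))
  list(values = v, mean = mean(v),
       sd = if (length(v) > 1L) sd(v) else NA_real_,
       min = min(v), max = max(v), n_pairs = length(v))
}

#' Distances from per-subject points to a fixed reference point
#'
#' Used for distances to an atlas connectivity peak or to a stereotactic
#' target point, both supplied as template-space mm coordinates.
#'
#' @param points n x 3 matrix of mm coordinates.
#' @param reference Length-3 mm point in the same (template) space.
#' @return List with per-subject `values`, `mean`, `sd`, `min`, `max`.
#' @export
distance_to_reference <- function(points, reference) {
  points <- rbind_pts(points)
  stopifnot(length(reference) == 3L)
  v <- sqrt(rowSums(sweep(points, 2, as.numeric(reference))^2))
  list(values = v, mean = mean(v),
       sd = if (length(v) > 1L) sd(v) else NA_real_,
       min = min(v), max = max(v))
}

#' Tanimoto overlap coefficient of two binary masks
#'
#' The ratio of the number of voxels in the intersection of two regions to
#' the number in their union (identical to the Jaccard index). Both masks
#' must live on the same grid.
#'
#' @param a,b Binary `voxel_grid` masks with identical geometry.
#' @return Overlap in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  assert_binary_mask(a, "a"); assert_binary_mask(b, "b")
  if (!same_geometry(a, b)) stop("masks must share grid geometry")
  A <- a$data != 0
  B <- b$data != 0
  uni <- sum(A | B)
  if (uni == 0L) stop("overlap undefined: both masks are empty")
  sum(A & B) / uni
}

#' Stereotactic target point on the AC-PC plane
#'
#' Constructs a classical geometric (Guiot-style) target from the AC-PC
#' landmarks: starting at PC, move `anterior_from_pc_mm` along the PC-to-AC
#' direction and `lateral_mm` away from the midsagittal plane along the
#' lateral axis of the AC-PC frame, staying on the AC-PC plane by
#' construction. The worked clinical default (8 mm anterior of PC, 12.7 mm
#' lateral) targets the Vop/Vim border.
#'
#' The lateral axis is axis3 of [acpc_frame()]; with RAS landmarks, AC
#' anterior of PC and IH above, `side = "right"` gives a negative first
#' coordinate. Flip `side` (or negate `lateral_mm`) for the opposite
#' convention.
#'
#' @param lm A [landmark_set()].
#' @param anterior_from_pc_mm Offset from PC towards AC, mm. Ignored when
#'   `anterior_fraction` is given.
#' @param lateral_mm Distance from the midsagittal plane, mm.
#' @param side `"right"` or `"left"`.
#' @param anterior_fraction Optional: anterior offset as a fraction of the
#'   AC-PC length instead of an absolute distance.
#' @return Length-3 mm point.
#' @export
stereotactic_target <- function(lm, anterior_from_pc_mm = 8,
                                lateral_mm = 12.7,
                                side = c("right", "left"),
                                anterior_fraction = NULL) {
  side <- match.arg(side)
  fr <- acpc_frame(lm)
  acpc_len <- euclidean_distance(lm$AC, lm$PC)
  if (!is.null(anterior_fraction))
    anterior_from_pc_mm <- anterior_fraction * acpc_len
  towards_ac <- -fr$axes[, 1]                 # axis1 points AC -> PC
  lateral <- fr$axes[, 3] * if (side == "right") 1 else -1
  lm$PC + anterior_from_pc_mm * towards_ac + lateral_mm * lateral
}

#' Assemble the cohort variability report
#'
#' Collects, per cortical target, the template-space peak coordinates of all
#' subjects and summarises inter-subject variability: all pairwise peak
#' distances, distances to any supplied reference points (atlas peak,
#' stereotactic target), and pairwise Tanimoto overlaps of the thresholded
#' connectivity masks.
#'
#' @param peaks Named list (one entry per target) of n x 3 matrices of
#'   template-space peak coordinates (mm), subjects in rows.
#' @param masks Optional named list (same targets) of length-n lists of
#'   binary `voxel_grid` masks, all on the template grid.
#' @param references Optional named list of length-3 mm reference points.
#' @return An object of class `cohort_report`: per target, `peaks`,
#'   `pairwise` (see [mean_pairwise_distance()]), `overlaps` (pairwise
#'   Tanimoto values with mean/min/max) and `reference_distances` (per
#'   reference, see [distance_to_reference()]); plus `n_subjects` and
#'   `targets`.
#' @export
build_cohort_report <- function(peaks, masks = NULL, references = NULL) {
  stopifnot(is.list(peaks), length(peaks) >= 1L, !is.null(names(peaks)))
  n <- unique(vapply(peaks, nrow, integer(1)))
  if (length(n) != 1L) stop("all targets must have the same subject count")
  if (n < 2L) stop("at least two subjects are required")
  targets <- names(peaks)
  per_target <- lapply(targets, function(tn) {
    p <- as.matrix(peaks[[tn]])
    out <- list(peaks = p, pairwise = mean_pairwise_distance(p))
    if (!is.null(masks)) {
      mk <- masks[[tn]]
      if (length(mk) != n) stop("mask list length must match subject count")
      prs <- combn(n, 2L)
      tc <- apply(prs, 2L, function(ij) tanimoto(mk[[ij[1]]], mk[[ij[2]]]))
      out$overlaps <- list(values = tc, mean = mean(tc),
                           min = min(tc), max = max(tc),
                           n_pairs = length(tc))
    }
    if (!is.null(references) && length(references)) {
      out$reference_distances <-
        lapply(references, function(r) distance_to_reference(p, r))
    }
    out
  })
  names(per_target) <- targets
  structure(list(targets = targets, n_subjects = n, by_target = per_target),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects, targets: %s\n",
              x$n_subjects, paste(x$targets, collapse = ", ")))
  for (tn in x$targets) {
    b <- x$by_target[[tn]]
    pw <- b$pairwise
    cat(sprintf("  %s: mean pairwise peak distance %.2f +/- %.2f mm (range %.2f-%.2f)\n",
                tn, pw$mean, pw$sd, pw$min, pw$max))
    if (!is.null(b$overlaps))
      cat(sprintf("      mean pairwise Tanimoto overlap %.1f%% (range %.1f%%-%.1f%%)\n",
                  100 * b$overlaps$mean, 100 * b$overlaps$min,
                  100 * b$overlaps$max))
    for (rn in names(b$reference_distances)) {
      rd <- b$reference_distances[[rn]]
      cat(sprintf("      distance to %s: %.2f +/- %.2f mm (range %.2f-%.2f)\n",
                  rn, rd$mean, rd$sd, rd$min, rd$max))
    }
  }
  invisible(x)
}

#' Tidy tables from a cohort report
#'
#' @param report A [build_cohort_report()] result.
#' @return Named list of data frames: `pairwise` (one row per subject pair
#'   per target), `overlaps` (idem, when masks were given) and
#'   `reference_distances` (one row per subject per reference).
#' @export
report_tables <- function(report) {
  stopifnot(inherits(report, "cohort_report"))
  n <- report$n_subjects
  prs <- combn(n, 2L)
  rows <- function(tn, vals) {
    data.frame(target = tn, subject_a = prs[1, ], subject_b = prs[2, ],
               value = vals, stringsAsFactors = FALSE)
  }
  pw <- do.call(rbind, lapply(report$targets, function(tn)
    rows(tn, report$by_target[[tn]]$pairwise$values)))
  ov <- NULL
  if (!is.null(report$by_target[[1]]$overlaps))
    ov <- do.call(rbind, lapply(report$targets, function(tn)
      rows(tn, report$by_target[[tn]]$overlaps$values)))
  rf <- NULL
  refs <- names(report$by_target[[1]]$reference_distances)
  if (length(refs))
    rf <- do.call(rbind, lapply(report$targets, function(tn)
      do.call(rbind, lapply(refs, function(rn)
        data.frame(target = tn, reference = rn, subject = seq_len(n),
                   distance_mm =
                     report$by_target[[tn]]$reference_distances[[rn]]$values,
                   stringsAsFactors = FALSE)))))
  list(pairwise = pw, overlaps = ov, reference_distances = rf)
}
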