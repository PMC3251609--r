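#' Winner-take-all connectivity parcellation of the seed region
#'
#' Labels each seed voxel with the cortical target having the highest
#' connection count at that voxel. Voxels whose counts are zero for every
#' target remain unassigned (label 0). Ties are broken deterministically in
#' favour of the earlier-listed target; tied voxels are recorded in the
#' `ties` attribute (0-based indices) and logged.
#'
#' @param result A [track_from_mask()] result with at least one target.
#' @return An object of class `parcellation`: `labels` (integer
#'   `voxel_grid`, 0 = unassigned), `target_names`, `ties` (matrix of
#'   0-based voxel indices) and `n_samples`.
#' @export
winner_take_all <- function(result) {
  stopifnot(inherits(result, "connectivity_result"),
            length(result$counts) >= 1L)
  seed <- result$seed_mask
  idx <- mask_indices(seed)
  cm <- vapply(result$counts, function(g) g$data[idx + 1L],
               numeric(nrow(idx)))
  cm <- matrix(cm, nrow = nrow(idx))
  best <- max.col(cm, ties.method = "first")
  mx <- cm[cbind(seq_len(nrow(cm)), best)]
  best[mx == 0] <- 0L
  n_best <- rowSums(cm == mx & mx > 0)
  ties <- idx[n_best > 1L, , drop = FALSE]
  if (nrow(ties))
    tt_log("winner-take-all: %d tied voxel(s), assigned to the earlier-listed target",
           nrow(ties))
  lab <- array(0L, dim = dim(seed))
  lab[idx + 1L] <- best
  structure(list(labels = grid_like(seed, lab),
                 target_names = names(result$counts),
                 ties = ties,
                 n_samples = result$n_samples),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  tab <- tabulate(x$labels$data[x$labels$data > 0],
                  nbins = length(x$target_names))
  cat(sprintf("<parcellation> %s; %d tie(s)\n",
              paste(sprintf("%s: %d", x$target_names, tab), collapse = ", "),
              nrow(x$ties)))
  invisible(x)
}

#' Threshold a connectivity map at a fraction of its maximum and binarise
#'
#' Retains voxels whose value is at least `fraction` times the map maximum
#' (inclusive, so the maximum itself always survives). With the standard
#' 5000 samples per seed voxel and a fully connected maximum, a fraction of
#' 0.10 corresponds to a 500-particle cutoff.
#'
#' @param prob_map `voxel_grid` of counts or probabilities with a strictly
#'   positive maximum.
#' @param fraction Fraction of the maximum, in (0, 1].
#' @return Binary `voxel_grid`; attributes `threshold` (the cutoff value)
#'   and `n_voxels` (surviving voxel count).
#' @export
threshold_and_binarise <- function(prob_map, fraction = 0.10) {
  stopifnot(inherits(prob_map, "voxel_grid"))
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  mx <- max(prob_map$data)
  if (mx <= 0) stop("degenerate map: no positive values to threshold")
  thr <- fraction * mx
  out <- grid_like(prob_map, array(as.integer(prob_map$data >= thr),
                                   dim = dim(prob_map)))
  attr(out, "threshold") <- thr
  attr(out, "n_voxels") <- sum(out$data)
  tt_log("threshold %g x max(%g) = %g: %d voxel(s) retained",
         fraction, mx, thr, attr(out, "n_voxels"))
  out
}

#' Peak-connectivity voxel of a map
#'
#' Finds the voxel with the maximal value within a mask and returns the
#' world coordinates of its centre. Ties are broken by the lowest
#' lexicographic voxel index (x, then y, then z) and recorded in the `ties`
#' attribute.
#'
#' @param prob_map `voxel_grid` of counts or probabilities.
#' @param mask Optional binary `voxel_grid` restricting the search (same
#'   geometry); default: whole grid.
#' @return Length-3 mm coordinates; attributes `voxel` (0-based index),
#'   `value` and `ties` (matrix of all tied 0-based indices).
#' @export
peak_voxel <- function(prob_map, mask = NULL) {
  stopifnot(inherits(prob_map, "voxel_grid"))
  if (is.null(mask)) {
    sel <- array(TRUE, dim = dim(prob_map))
  } else {
    assert_binary_mask(mask, "mask")
    if (!same_geometry(prob_map, mask))
      stop("mask must share the map's grid geometry")
    sel <- mask$data != 0
    if (!any(sel)) stop("mask is empty")
  }
  vals <- prob_map$data[sel]
  mx <- max(vals)
  if (mx <= 0) stop("degenerate map: no positive values within the mask")
  w <- which(sel & prob_map$data == mx, arr.ind = TRUE) - 1L
  ord <- order(w[, 1], w[, 2], w[, 3])
  w <- w[ord, , drop = FALSE]
  if (nrow(w) > 1L)
    tt_log("peak_voxel: %d tied maxima, lowest lexicographic index chosen",
           nrow(w))
  out <- voxel_to_world(prob_map, w[1, ])
  attr(out, "voxel") <- w[1, ]
  attr(out, "value") <- mx
  attr(out, "ties") <- w
  out
}
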