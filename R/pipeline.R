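#' Configure the end-to-end phantom pipeline
#'
#' Bundles every knob of the simulate - track - parcellate - register -
#' report pipeline. The defaults reproduce the package's standard study
#' conditions: a nine-subject cohort whose ground-truth peaks are displaced
#' with a per-axis SD of 3.25 mm, tracked with 5000 samples per seed voxel
#' and thresholded at 10% of the individual connectivity maximum.
#'
#' @param phantom A [phantom_spec()] serving as cohort template; its
#'   landmark set is the registration template.
#' @param n_subjects Number of synthetic subjects (>= 2).
#' @param peak_sd_mm Per-axis SD of truth-peak displacement (mm).
#' @param tracking A [tracking_config()].
#' @param threshold_fraction Connectivity threshold as a fraction of each
#'   subject's maximum, in (0, 1].
#' @param references Named list of template-space mm points (e.g. an atlas
#'   connectivity peak or a stereotactic target) to which peak distances are
#'   reported.
#' @param pose_jitter Give each subject a random rigid head pose?
#' @param seed Global integer seed; all per-stage seeds derive from it.
#' @param out_dir Optional output directory; when set, all stage outputs and
#'   a checksum manifest are written.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = phantom_spec(),
                            n_subjects = 9L,
                            peak_sd_mm = 3.25,
                            tracking = tracking_config(),
                            threshold_fraction = 0.10,
                            references = list(),
                            pose_jitter = TRUE,
                            seed = 1L,
                            out_dir = NULL) {
  validate_phantom_spec(phantom)
  stopifnot(inherits(tracking, "tracking_config"))
  if (threshold_fraction <= 0 || threshold_fraction > 1)
    stop("threshold_fraction must lie in (0, 1]")
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  if (peak_sd_mm < 0) stop("peak_sd_mm must be >= 0")
  if (length(references) && is.null(names(references)))
    stop("references must be a named list of mm points")
  structure(list(phantom = phantom, n_subjects = as.integer(n_subjects),
                 peak_sd_mm = peak_sd_mm, tracking = tracking,
                 threshold_fraction = threshold_fraction,
                 references = references, pose_jitter = pose_jitter,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Resample a binary mask into a template grid
#'
#' Nearest-neighbour pullback: each template voxel centre is mapped through
#' the inverse of `transform` (subject-to-template, world mm) and looks up
#' the nearest subject voxel. Appropriate for the rigid, like-spaced grids
#' this pipeline produces.
#'
#' @param mask Binary `voxel_grid` in subject space.
#' @param transform [rigid_transform()] from subject world mm to template
#'   world mm.
#' @param template `voxel_grid` providing the output geometry.
#' @return Binary `voxel_grid` on the template grid.
#' @export
resample_mask <- function(mask, transform, template) {
  assert_binary_mask(mask, "mask")
  stopifnot(inherits(template, "voxel_grid"))
  shp <- dim(template)
  idx <- as.matrix(expand.grid(i = seq_len(shp[1]) - 1L,
                               j = seq_len(shp[2]) - 1L,
                               k = seq_len(shp[3]) - 1L))
  mm_t <- voxel_to_world(template, idx)
  mm_s <- apply_transform(invert_transform(transform), mm_t)
  vs <- round(world_to_voxel(mask, mm_s))
  shp_s <- dim(mask)
  ok <- vs[, 1] >= 0 & vs[, 1] < shp_s[1] &
    vs[, 2] >= 0 & vs[, 2] < shp_s[2] &
    vs[, 3] >= 0 & vs[, 3] < shp_s[3]
  val <- integer(nrow(vs))
  val[ok] <- mask$data[vs[ok, , drop = FALSE] + 1L]
  grid_like(template, array(val, dim = shp))
}

#' Run the full phantom analysis pipeline
#'
#' Generates a synthetic cohort, runs probabilistic tractography from each
#' subject's thalamus to its cortical targets, extracts peak-connectivity
#' voxels and 10%-of-maximum masks, computes each subject's AC-fixed rigid
#' normalisation into the template frame, and aggregates the cohort
#' variability report (pairwise peak distances, reference distances,
#' Tanimoto overlaps). All RNG seeds derive from `config$seed`, so a rerun
#' with an identical configuration is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: `report` (the
#'   [build_cohort_report()] in template space), `truth` (same summaries for
#'   the ground-truth peaks), `peaks`, `truth_peaks`, `parcellations`,
#'   `transforms`, `subjects` and, when `out_dir` is set, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  cohort_seed <- sample.int(.Machine$integer.max - 1L, 1L)
  track_seeds <- sample.int(.Machine$integer.max - 1L, config$n_subjects)

  tt_log("stage simulate: %d subjects, peak SD %g mm (seed %d)",
         config$n_subjects, config$peak_sd_mm, cohort_seed)
  cohort <- generate_cohort(config$phantom, config$n_subjects,
                            config$peak_sd_mm, seed = cohort_seed,
                            pose_jitter = config$pose_jitter)

  template <- generate_subject(config$phantom)
  template_lm <- config$phantom$landmarks
  targets <- vapply(config$phantom$bundles, `[[`, character(1), "target_name")

  peaks <- lapply(targets, function(.) matrix(NA_real_, config$n_subjects, 3))
  truth_peaks <- lapply(targets, function(.) matrix(NA_real_,
                                                    config$n_subjects, 3))
  names(peaks) <- names(truth_peaks) <- targets
  masks <- setNames(lapply(targets, function(.) vector("list",
                                                       config$n_subjects)),
                    targets)
  parcellations <- vector("list", config$n_subjects)
  transforms <- vector("list", config$n_subjects)

  for (i in seq_len(config$n_subjects)) {
    subj <- cohort[[i]]
    tc <- config$tracking
    tc$rng_seed <- track_seeds[i]
    tt_log("stage track: subject %d (rng %d)", i, tc$rng_seed)
    res <- track_from_mask(subj$thalamus_mask, subj$target_masks,
                           subj$orientation_field, subj$brain_mask, tc)
    parcellations[[i]] <- winner_take_all(res)
    tr <- register_landmarks(subj$landmarks, template_lm)
    transforms[[i]] <- tr
    for (tn in targets) {
      pm <- connection_probability(res, tn)
      pk <- peak_voxel(pm, subj$thalamus_mask)
      peaks[[tn]][i, ] <- apply_transform(tr, as.numeric(pk))
      truth_peaks[[tn]][i, ] <- apply_transform(tr, subj$truth_peaks_mm[[tn]])
      thr <- threshold_and_binarise(pm, config$threshold_fraction)
      masks[[tn]][[i]] <- resample_mask(thr, tr, template$brain_mask)
    }
  }

  report <- build_cohort_report(peaks, masks, config$references)
  truth <- build_cohort_report(truth_peaks, references = config$references)

  result <- structure(list(report = report, truth = truth, peaks = peaks,
                           truth_peaks = truth_peaks,
                           parcellations = parcellations,
                           transforms = transforms, subjects = cohort,
                           config = config),
                      class = "pipeline_result")
  if (!is.null(config$out_dir))
    result$manifest <- write_pipeline_outputs(result, config$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d subjects (peak SD %g mm, seed %d)\n",
              x$config$n_subjects, x$config$peak_sd_mm, x$config$seed))
  print(x$report)
  invisible(x)
}

# write all stage outputs and return a checksum manifest
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- result$config
  targets <- names(result$peaks)
  for (i in seq_along(result$subjects)) {
    write_subject(result$subjects[[i]], file.path(out_dir, "subjects"),
                  id = i)
    write_transform(result$transforms[[i]],
                    file.path(out_dir, sprintf("sub-%d_to-template.mat", i)))
    write_volume(result$parcellations[[i]]$labels,
                 file.path(out_dir, sprintf("sub-%d_parcellation.nii", i)))
  }
  legend <- setNames(as.list(seq_along(targets)), targets)
  jsonlite::write_json(legend, file.path(out_dir, "parcellation_legend.json"),
                       auto_unbox = TRUE)
  pk <- do.call(rbind, lapply(targets, function(tn)
    data.frame(subject = seq_len(cfg$n_subjects), target = tn,
               x_mm = result$peaks[[tn]][, 1],
               y_mm = result$peaks[[tn]][, 2],
               z_mm = result$peaks[[tn]][, 3], stringsAsFactors = FALSE)))
  utils::write.table(pk, file.path(out_dir, "peaks.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  tabs <- report_tables(result$report)
  for (nm in names(tabs))
    if (!is.null(tabs[[nm]]))
      utils::write.table(tabs[[nm]], file.path(out_dir,
                                               paste0(nm, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report_summaries(result$report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- setdiff(list.files(out_dir, recursive = TRUE,
                              full.names = TRUE),
                   file.path(out_dir, "manifest.tsv"))
  manifest <- data.frame(file = sub(paste0("^", out_dir, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         bytes = file.size(files), stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  manifest
}

#' Plain-list summaries of a cohort report
#'
#' @param report A [build_cohort_report()] result.
#' @return Nested list of numeric summaries, convenient for JSON export.
#' @export
report_summaries <- function(report) {
  stopifnot(inherits(report, "cohort_report"))
  out <- lapply(report$targets, function(tn) {
    b <- report$by_target[[tn]]
    s <- list(pairwise_distance_mm = b$pairwise[c("mean", "sd", "min",
                                                 "max")])
    if (!is.null(b$overlaps))
      s$tanimoto <- b$overlaps[c("mean", "min", "max")]
    if (!is.null(b$reference_distances))
      s$reference_distance_mm <-
        lapply(b$reference_distances, `[`, c("mean", "sd", "min", "max"))
    s
  })
  names(out) <- report$targets
  c(list(n_subjects = report$n_subjects), out)
}
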