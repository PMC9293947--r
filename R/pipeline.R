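# End-to-end orchestration: materialize synthetic fixtures to disk, extract
# marker tables from landmark/frame inputs, and run the cohort analysis.
# These functions back the thin command-line script in inst/cli/facekin.R.

#' Default run configuration
#'
#' Every pipeline parameter with its documented default; unknown keys in
#' `...` are rejected.
#'
#' @param ... overrides of the defaults.
#' @return named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    fps = 25, max_gap = 1.0, fill = "interpolate",
    patch_px = 64L, n_bins = 64L,
    alpha = 0.05, cutoff_prob = 0.05, cutoff_direction = "lower",
    min_controls = 20L,
    lilliefors = FALSE,
    lambda = 1e-4, fpr_bound = 0.05, search = FALSE,
    candidates = marker_catalogue()$marker,
    seed = 1L, verbose = TRUE
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (k in names(x))
    cat(sprintf("  %-16s %s\n", k, paste(format(unlist(x[[k]])), collapse = ", ")))
  invisible(x)
}

#' Materialize a synthetic cohort as a fixture tree
#'
#' Writes one landmark file per subject, the cohort and ground-truth tables,
#' and (optionally) per-subject PNG frame directories in the formats the
#' readers consume.
#'
#' @param config a [synth_config()].
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing directory.
#' @param write_frames also write rendered frames as PNG (slow and large;
#'   meant for small fixture configurations).
#' @return invisibly, the simulation result of [simulate_cohort()].
#' @export
cmd_simulate <- function(config, out_dir, overwrite = FALSE,
                         write_frames = FALSE) {
  if (dir.exists(out_dir) && !overwrite &&
      length(list.files(out_dir)))
    stop("output directory exists; use overwrite = TRUE")
  dir.create(file.path(out_dir, "landmarks"), recursive = TRUE,
             showWarnings = FALSE)
  sim <- simulate_cohort(config, compute_markers = FALSE)
  for (id in names(sim$sequences))
    write_landmark_series(sim$sequences[[id]],
                          file.path(out_dir, "landmarks", paste0(id, ".csv")))
  utils::write.csv(sim$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(sim$truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  if (write_frames && isTRUE(config$render)) {
    for (i in seq_along(sim$sequences)) {
      id <- names(sim$sequences)[i]
      src <- render_frames(sim$sequences[[i]], sim$ground_truth_detail[[i]],
                           config, seed = subject_seed(config$seed, i))
      fdir <- file.path(out_dir, "frames", id)
      dir.create(fdir, recursive = TRUE, showWarnings = FALSE)
      for (t in seq_len(src$n_frames))
        png::writePNG(src$get(t - 1L),
                      file.path(fdir, sprintf("frame_%05d.png", t - 1L)))
    }
  }
  invisible(sim)
}

#' Extract the marker table for a directory of recordings
#'
#' Reads every landmark file under `landmark_dir` (one per subject, subject
#' id = file stem), pairs it with a frame directory of the same stem under
#' `frames_dir` when given, and computes the marker vector. Per-subject
#' failures are recorded and the run continues.
#'
#' @param landmark_dir directory of landmark CSV files.
#' @param frames_dir optional directory of per-subject PNG frame directories.
#' @param out_file optional path for the delimited marker table.
#' @param config a [run_config()].
#' @return the marker table; failures in attribute `failures`.
#' @export
cmd_extract <- function(landmark_dir, frames_dir = NULL, out_file = NULL,
                        config = run_config()) {
  files <- sort(list.files(landmark_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no landmark files in ", landmark_dir)
  vectors <- list(); failures <- character()
  cfg <- roi_config(patch_px = config$patch_px)
  for (f in files) {
    id <- sub("\\.[^.]*$", "", basename(f))
    res <- tryCatch({
      seq <- read_landmark_series(f, fps = config$fps)
      frames <- NULL
      if (!is.null(frames_dir) && dir.exists(file.path(frames_dir, id)))
        frames <- frame_source_directory(file.path(frames_dir, id))
      compute_marker_vector(seq, frames, max_gap = config$max_gap,
                            fill = config$fill, cfg = cfg,
                            n_bins = config$n_bins)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      if (config$verbose) message("  FAILED ", id, ": ", conditionMessage(res))
    } else {
      vectors[[id]] <- res
      if (config$verbose)
        message(sprintf("  %s: %d frames used", id, res$n_frames_used))
    }
  }
  if (!length(vectors)) stop("all subjects failed marker extraction")
  tab <- marker_table(vectors)
  if (!is.null(out_file))
    utils::write.csv(tab, out_file, row.names = FALSE)
  attr(tab, "failures") <- failures
  tab
}

#' Run the full cohort analysis
#'
#' Chains the statistics and classification stages: sided group-difference
#' tests with the Bonferroni flag, age-controlled correlation table,
#' control-based abnormality profiles, and the LOSO classification report.
#'
#' @param markers marker table (or path to one).
#' @param cohort cohort table (or path).
#' @param config a [run_config()].
#' @param out_dir optional directory for delimited-text reports.
#' @return list: `group_tests`, `correlations`, `cutoffs`, `profile`,
#'   `classification`.
#' @export
cmd_analyze <- function(markers, cohort, config = run_config(),
                        out_dir = NULL) {
  if (is.character(markers)) markers <- as.data.frame(data.table::fread(markers))
  if (is.character(cohort)) cohort <- read_cohort_table(cohort)
  orphans <- c(setdiff(markers$subject_id, cohort$subject_id),
               setdiff(cohort$subject_id, markers$subject_id))
  if (length(orphans))
    stop("subject ids present in only one table: ",
         paste(orphans, collapse = ", "))
  gt <- group_difference_table(markers, cohort, alpha = config$alpha,
                               lilliefors = config$lilliefors)
  ct <- correlation_table(markers, cohort)
  ctrl <- markers[markers$subject_id %in%
                    cohort$subject_id[cohort$group == "HC"], , drop = FALSE]
  cuts <- control_cutoffs(ctrl, prob = config$cutoff_prob,
                          direction = config$cutoff_direction,
                          min_controls = config$min_controls)
  prof <- abnormality_profile(markers, cuts)
  clf <- classify_cohort(markers, cohort, candidates = config$candidates,
                         search = config$search, lambda = config$lambda,
                         fpr_bound = config$fpr_bound)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(gt, file.path(out_dir, "group_differences.csv"),
                     row.names = FALSE)
    utils::write.csv(ct, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE)
    utils::write.csv(prof, file.path(out_dir, "abnormality_profile.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(subject_id = clf$subject_id,
                                group = clf$group, score = clf$scores),
                     file.path(out_dir, "loso_scores.csv"), row.names = FALSE)
    utils::write.csv(roc_points(clf$scores, clf$group),
                     file.path(out_dir, "roc_points.csv"), row.names = FALSE)
  }
  list(group_tests = gt, correlations = ct, cutoffs = cuts, profile = prof,
       classification = clf)
}
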