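# The twelve hypomimia markers. Each marker is the sample standard deviation
# over frames of a per-frame facial quantity: Euclidean markers are
# landmark-derived distances/angles/areas (IED-normalized where applicable),
# surface markers are edge-highlighted image entropies of landmark-anchored
# regions of interest. All variability is pooled across gated segments; any
# quantity defined on consecutive frames never straddles a segment boundary.

#' The marker catalogue
#'
#' Twelve facial-dynamics markers covering eight facial regions; seven have
#' left/right variants, giving 19 sided values per recording. Surface markers
#' need video frames in addition to landmarks.
#'
#' @return `data.frame` with columns `marker`, `region`, `bilateral`,
#'   `surface`.
#' @export
marker_catalogue <- function() {
  data.frame(
    marker = c("forehead_lines", "nose_root_lines", "eyebrow_elevation",
               "eyebrow_tilt", "eyebrow_shape", "palpebral_aperture",
               "lateral_canthal_lines", "cheek_surface", "upper_lip",
               "lower_lip", "mouth_corner", "jaw"),
    region = c("forehead", "nose_root", "eyebrows", "eyebrows", "eyebrows",
               "eyes", "lateral_canthal", "cheeks", "mouth", "mouth", "mouth",
               "jaw"),
    bilateral = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE,
                  FALSE, TRUE, FALSE),
    surface = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE,
                FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Sided marker names
#'
#' Expands the catalogue into the 19 per-side marker names (`_L`/`_R`
#' suffixes for bilateral markers).
#'
#' @return character vector of length 19.
#' @export
sided_marker_names <- function() {
  cat <- marker_catalogue()
  unlist(lapply(seq_len(nrow(cat)), function(i)
    if (cat$bilateral[i]) paste0(cat$marker[i], c("_L", "_R"))
    else cat$marker[i]), use.names = FALSE)
}

# sample SD, n-1 denominator; NA when fewer than 2 observations
sample_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  sd(x)
}

ied_per_frame <- function(seq) {
  d <- seq$coords[, lm_idx(IBUG$eye_inner_R), ] -
       seq$coords[, lm_idx(IBUG$eye_inner_L), ]
  ied <- sqrt(rowSums(d^2))
  if (any(ied <= 0)) stop("degenerate geometry: zero inner-eye-corner distance")
  ied
}

# concatenate a per-frame series over all gated segments
pooled_series <- function(segs, fn) {
  if (!length(segs)) return(numeric())
  unlist(lapply(segs, fn), use.names = FALSE)
}

#' Normalized landmark-distance marker
#'
#' Per frame, the Euclidean distance between two landmarks divided by the
#' inner-eye-corner distance (landmarks 39 and 42); the marker is the sample
#' standard deviation of that series pooled over all gated segments. Invariant
#' to uniform scaling and rigid translation of the coordinates.
#'
#' @param segs list of fully valid `landmark_sequence` segments (from
#'   [gated_segments()]), or a single sequence.
#' @param point_a,point_b 0-based iBUG landmark indices.
#' @return nonnegative marker value (`NA` if fewer than 2 usable frames).
#' @export
normalized_distance_marker <- function(segs, point_a, point_b) {
  segs <- as_segments(segs)
  s <- pooled_series(segs, function(seq) {
    d <- seq$coords[, lm_idx(point_a), ] - seq$coords[, lm_idx(point_b), ]
    sqrt(rowSums(d^2)) / ied_per_frame(seq)
  })
  sample_sd(s)
}

as_segments <- function(x) {
  if (inherits(x, "landmark_sequence")) list(x) else x
}

# acute angle in degrees between two direction vectors
acute_angle_deg <- function(u, v) {
  cosv <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
}

#' Eyebrow tilt marker
#'
#' Per frame, a straight line is fitted by total least squares (principal
#' axis) through the five eyebrow landmarks; the per-frame quantity is the
#' unsigned acute angle in degrees between that line and the line through the
#' medial eye corners. The marker is the sample SD over frames. Invariant to
#' rigid rotation of the face (both lines co-rotate).
#'
#' @inheritParams normalized_distance_marker
#' @param side `"L"` or `"R"` (subject's anatomical side).
#' @return marker value in degrees.
#' @export
eyebrow_tilt_marker <- function(segs, side = c("L", "R")) {
  side <- match.arg(side)
  brow <- if (side == "R") IBUG$brow_R else IBUG$brow_L
  segs <- as_segments(segs)
  s <- pooled_series(segs, function(seq) {
    vapply(seq_len(n_frames(seq)), function(t) {
      pts <- seq$coords[t, lm_idx(brow), ]
      ctr <- sweep(pts, 2L, colMeans(pts))
      cv <- crossprod(ctr)
      if (sum(diag(cv)) < .Machine$double.eps) return(NA_real_)  # degenerate
      axis <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
      canthal <- seq$coords[t, lm_idx(IBUG$eye_inner_L), ] -
                 seq$coords[t, lm_idx(IBUG$eye_inner_R), ]
      acute_angle_deg(axis, canthal)
    }, numeric(1))
  })
  sample_sd(s)
}

#' Eyebrow shape marker
#'
#' Per frame, the apex angle (degrees) at the eyebrow centre of the triangle
#' formed with the eyebrow endpoints; a straight eyebrow gives 180 degrees.
#' The marker is the sample SD over frames; frames where the apex coincides
#' with an endpoint are dropped.
#'
#' @inheritParams eyebrow_tilt_marker
#' @return marker value in degrees.
#' @export
eyebrow_shape_marker <- function(segs, side = c("L", "R")) {
  side <- match.arg(side)
  if (side == "R") { apex <- IBUG$brow_apex_R; ends <- c(17L, 21L) }
  else             { apex <- IBUG$brow_apex_L; ends <- c(22L, 26L) }
  segs <- as_segments(segs)
  s <- pooled_series(segs, function(seq) {
    a <- seq$coords[, lm_idx(apex), ]
    e1 <- seq$coords[, lm_idx(ends[1L]), ]
    e2 <- seq$coords[, lm_idx(ends[2L]), ]
    u <- e1 - a; v <- e2 - a
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    cosv <- rowSums(u * v) / (nu * nv)
    ang <- acos(pmin(pmax(cosv, -1), 1)) * 180 / pi
    ang[nu == 0 | nv == 0] <- NA_real_
    ang
  })
  sample_sd(s)
}

# signed shoelace area of an ordered polygon (n x 2 matrix)
shoelace_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]) / 2
}

#' Palpebral aperture marker
#'
#' Per frame, the polygon (shoelace) area of the six eye-contour landmarks,
#' normalized by the squared inner-eye-corner distance (areas scale as
#' length squared); the marker is the sample SD over frames. Self-intersecting
#' contours contribute their absolute area.
#'
#' @inheritParams eyebrow_tilt_marker
#' @return dimensionless marker value.
#' @export
palpebral_aperture_marker <- function(segs, side = c("L", "R")) {
  side <- match.arg(side)
  eye <- if (side == "R") IBUG$eye_R else IBUG$eye_L
  segs <- as_segments(segs)
  s <- pooled_series(segs, function(seq) {
    ied2 <- ied_per_frame(seq)^2
    vapply(seq_len(n_frames(seq)), function(t)
      abs(shoelace_area(seq$coords[t, lm_idx(eye), ])), numeric(1)) / ied2
  })
  sample_sd(s)
}

# per-segment, per-frame entropy of the edge-highlighted region patch;
# NA for frames with coverage < 0.5. Edge magnitudes live in [0, sqrt(2)].
segment_edge_entropy <- function(frames, seg, region, cfg, n_bins) {
  off <- attr(seg, "frame_offset") %||% 0L
  vapply(seq_len(n_frames(seg)), function(t) {
    patch <- extract_patch(get_frame(frames, off + t - 1L), seg, t - 1L,
                           region, cfg)
    if (is.null(patch)) return(NA_real_)
    patch_entropy(edge_highlight(patch), n_bins = n_bins, range_max = sqrt(2))
  }, numeric(1))
}

#' Wrinkle-line surface marker
#'
#' Per frame, the Shannon entropy of the edge-highlighted ROI patch (forehead,
#' nose root, or a lateral canthal area); the marker is the sample SD of that
#' entropy over frames. Captures the appearance and disappearance of wrinkle
#' lines (frontalis activation, glabellar frowning, Duchenne crow's feet).
#'
#' @param frames a [frame_source()] paired with the gated segments.
#' @inheritParams normalized_distance_marker
#' @param region `"forehead"`, `"nose_root"`, `"lateral_canthal_L"` or
#'   `"lateral_canthal_R"`.
#' @param cfg a [roi_config()].
#' @param n_bins entropy histogram bins.
#' @return marker value in bits (`NA` if fewer than 2 covered frames).
#' @export
entropy_line_marker <- function(frames, segs, region, cfg = roi_config(),
                                n_bins = 64L) {
  segs <- as_segments(segs)
  s <- pooled_series(segs, function(seg)
    segment_edge_entropy(frames, seg, region, cfg, n_bins))
  sample_sd(s)
}

#' Cheek surface variability marker
#'
#' For consecutive frames within a segment, both cheek patches are resampled
#' to the canonical grid and the Shannon entropy of their absolute difference
#' is computed; the marker is the sample SD of that entropy over frame pairs.
#' Pairs never straddle a segment boundary, so excluded gaps cannot fabricate
#' motion.
#'
#' @inheritParams entropy_line_marker
#' @param side `"L"` or `"R"`.
#' @return marker value in bits (`NA` if fewer than 2 usable pairs).
#' @export
cheek_surface_marker <- function(frames, segs, side = c("L", "R"),
                                 cfg = roi_config(), n_bins = 64L) {
  side <- match.arg(side)
  region <- paste0("cheek_", side)
  segs <- as_segments(segs)
  s <- pooled_series(segs, function(seg) {
    off <- attr(seg, "frame_offset") %||% 0L
    T <- n_frames(seg)
    if (T < 3L) return(numeric())
    patches <- lapply(seq_len(T) - 1L, function(t)
      extract_patch(get_frame(frames, off + t), seg, t, region, cfg))
    vapply(seq_len(T - 1L), function(t) {
      a <- patches[[t]]; b <- patches[[t + 1L]]
      if (is.null(a) || is.null(b)) return(NA_real_)
      patch_entropy(abs(b - a), n_bins = n_bins, range_max = 1)
    }, numeric(1))
  })
  sample_sd(s)
}

#' Compute the full marker vector for one recording
#'
#' Gates the recording by the one-second rule, computes every computable sided
#' marker, and side-averages the bilateral ones. Surface markers require a
#' frame source; without one they are reported as missing (`NA`), never as
#' zeros.
#'
#' @param seq a [landmark_sequence()].
#' @param frames optional [frame_source()] paired with `seq`.
#' @param max_gap retained-gap limit in seconds (see [gate_gaps()]).
#' @param fill `"interpolate"` or `"drop"` for sub-`max_gap` gaps.
#' @param cfg a [roi_config()].
#' @param n_bins entropy histogram bins.
#' @return object of class `marker_vector`: list with `sided` (19 named
#'   values), `averaged` (12 named values), `n_frames_used`.
#' @export
compute_marker_vector <- function(seq, frames = NULL, max_gap = 1.0,
                                  fill = "interpolate", cfg = roi_config(),
                                  n_bins = 64L) {
  segs <- gated_segments(seq, max_gap = max_gap, fill = fill)
  sided <- setNames(rep(NA_real_, 19L), sided_marker_names())
  n_used <- sum(vapply(segs, n_frames, integer(1)))
  if (length(segs)) {
    tip <- IBUG$nose_tip
    sided["eyebrow_elevation_L"] <- normalized_distance_marker(segs, IBUG$brow_apex_L, tip)
    sided["eyebrow_elevation_R"] <- normalized_distance_marker(segs, IBUG$brow_apex_R, tip)
    sided["eyebrow_tilt_L"]  <- eyebrow_tilt_marker(segs, "L")
    sided["eyebrow_tilt_R"]  <- eyebrow_tilt_marker(segs, "R")
    sided["eyebrow_shape_L"] <- eyebrow_shape_marker(segs, "L")
    sided["eyebrow_shape_R"] <- eyebrow_shape_marker(segs, "R")
    sided["palpebral_aperture_L"] <- palpebral_aperture_marker(segs, "L")
    sided["palpebral_aperture_R"] <- palpebral_aperture_marker(segs, "R")
    sided["upper_lip"] <- normalized_distance_marker(segs, IBUG$upper_lip, tip)
    sided["lower_lip"] <- normalized_distance_marker(segs, IBUG$lower_lip, tip)
    sided["mouth_corner_L"] <- normalized_distance_marker(segs, IBUG$mouth_corner_L, tip)
    sided["mouth_corner_R"] <- normalized_distance_marker(segs, IBUG$mouth_corner_R, tip)
    sided["jaw"] <- normalized_distance_marker(segs, IBUG$chin, tip)
    if (!is.null(frames)) {
      sided["forehead_lines"]  <- entropy_line_marker(frames, segs, "forehead", cfg, n_bins)
      sided["nose_root_lines"] <- entropy_line_marker(frames, segs, "nose_root", cfg, n_bins)
      sided["lateral_canthal_lines_L"] <- entropy_line_marker(frames, segs, "lateral_canthal_L", cfg, n_bins)
      sided["lateral_canthal_lines_R"] <- entropy_line_marker(frames, segs, "lateral_canthal_R", cfg, n_bins)
      sided["cheek_surface_L"] <- cheek_surface_marker(frames, segs, "L", cfg, n_bins)
      sided["cheek_surface_R"] <- cheek_surface_marker(frames, segs, "R", cfg, n_bins)
    }
  }
  structure(list(sided = sided, averaged = average_sided(sided),
                 n_frames_used = n_used),
            class = "marker_vector")
}

#' Side-average a sided marker vector
#'
#' Bilateral markers are represented by the mean of their left and right
#' values for cohort-level analysis; with one side missing the available side
#' is used.
#'
#' @param sided named numeric vector over [sided_marker_names()].
#' @return named numeric vector over the 12 catalogue marker names.
#' @export
average_sided <- function(sided) {
  cat <- marker_catalogue()
  out <- setNames(rep(NA_real_, nrow(cat)), cat$marker)
  for (i in seq_len(nrow(cat))) {
    m <- cat$marker[i]
    if (cat$bilateral[i]) {
      v <- sided[paste0(m, c("_L", "_R"))]
      out[m] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    } else out[m] <- sided[[m]]
  }
  out
}

#' @export
print.marker_vector <- function(x, ...) {
  cat(sprintf("<marker_vector> %d frames used\n", x$n_frames_used))
  print(round(x$averaged, 5))
  invisible(x)
}

#' Assemble per-subject marker vectors into a cohort marker table
#'
#' @param vectors named list of `marker_vector` objects (names = subject ids).
#' @return `data.frame`: `subject_id`, 19 sided columns, 12 averaged columns
#'   (prefixed `avg_`), `n_frames_used`.
#' @export
marker_table <- function(vectors) {
  rows <- lapply(names(vectors), function(id) {
    v <- vectors[[id]]
    c(list(subject_id = id), as.list(v$sided),
      as.list(setNames(v$averaged, paste0("avg_", names(v$averaged)))),
      list(n_frames_used = v$n_frames_used))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}
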