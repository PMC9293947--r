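#' @importFrom stats approx sd quantile lm resid cor pt ks.test kruskal.test
#'   oneway.test rnorm runif rpois rbinom setNames complete.cases coef
#' @importFrom utils head tail
NULL

# iBUG 300-W landmark indices, 0-based as in the convention's documentation.
# "Right"/"left" refer to the subject's anatomical side, assuming a frontal,
# non-mirrored view (subject right appears on the image left).
IBUG <- list(
  jaw            = 0:16,  chin = 8L,
  brow_R         = 17:21, brow_L = 22:26,
  brow_apex_R    = 19L,   brow_apex_L = 24L,
  brow_med_R     = 21L,   brow_med_L = 22L,
  nose_bridge    = 27:30, nose_tip = 30L,
  nose_wing_R    = 31L,   nose_wing_L = 35L,
  eye_R          = 36:41, eye_L = 42:47,
  eye_outer_R    = 36L,   eye_outer_L = 45L,
  eye_inner_R    = 39L,   eye_inner_L = 42L,
  mouth_corner_R = 48L,   mouth_corner_L = 54L,
  upper_lip      = 51L,   lower_lip = 57L
)

# 1-based column/row index into the 68-point array for a 0-based landmark id
lm_idx <- function(i) i + 1L

#' Construct a facial landmark time series
#'
#' A `landmark_sequence` holds the per-frame 68-point facial landmark
#' coordinates of one recording, in the iBUG 300-W convention (x rightward,
#' y downward, origin at the top-left pixel), together with a per-landmark
#' validity mask marking obscured or out-of-frame points.
#'
#' @param coords numeric `T x 68 x 2` array of pixel coordinates.
#' @param fps frames per second (> 0); monologue recordings default to 25.
#' @param subject_id subject identifier.
#' @param valid logical `T x 68` matrix, `FALSE` where a landmark is missing;
#'   rows of `coords` containing `NA` are marked invalid automatically.
#' @param width,height frame dimensions in pixels.
#' @return an object of class `landmark_sequence`.
#' @export
landmark_sequence <- function(coords, fps = 25, subject_id = "subject",
                              valid = NULL, width = 1440L, height = 1080L) {
  if (length(dim(coords)) != 3L || dim(coords)[2] != 68L || dim(coords)[3] != 2L)
    stop("coords must be a T x 68 x 2 array")
  if (dim(coords)[1] < 2L) stop("need at least 2 frames")
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) stop("fps must be > 0")
  T <- dim(coords)[1]
  if (is.null(valid)) valid <- matrix(TRUE, T, 68L)
  storage.mode(valid) <- "logical"
  nas <- is.na(coords[, , 1L]) | is.na(coords[, , 2L])
  valid <- valid & !nas
  structure(list(subject_id = subject_id, fps = fps, coords = coords,
                 valid = valid, width = as.integer(width),
                 height = as.integer(height)),
            class = "landmark_sequence")
}

#' @export
print.landmark_sequence <- function(x, ...) {
  T <- dim(x$coords)[1]
  cat(sprintf("<landmark_sequence> %s: %d frames @ %g fps (%.1f s), %dx%d px, %d invalid landmark-frames\n",
              x$subject_id, T, x$fps, T / x$fps, x$width, x$height,
              sum(!x$valid)))
  invisible(x)
}

n_frames <- function(seq) dim(seq$coords)[1]

#' Read a landmark time series from delimited text
#'
#' One row per frame: `frame,x0,y0,...,x67,y67`, optional header, empty fields
#' for invalid (obscured/out-of-frame) landmarks. Comment lines of the form
#' `# fps: 25`, `# width: 1440`, `# height: 1080`, `# subject: id` may precede
#' the data and override the corresponding arguments.
#'
#' @param path file path.
#' @param fps frames per second, used when the file carries no metadata.
#' @param subject_id default subject id (file stem if `NULL`).
#' @param width,height default frame size when not in the file metadata.
#' @return a [landmark_sequence()].
#' @export
read_landmark_series <- function(path, fps = 25, subject_id = NULL,
                                 width = 1440L, height = 1080L) {
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0")
  lines <- readLines(path)
  meta_ln <- grepl("^\\s*#", lines)
  meta <- lines[meta_ln]
  grab <- function(key, cur, cast = as.numeric) {
    m <- grep(sprintf("^\\s*#\\s*%s\\s*:", key), meta, value = TRUE)
    if (!length(m)) return(cur)
    cast(trimws(sub(sprintf("^\\s*#\\s*%s\\s*:", key), "", m[1L])))
  }
  fps        <- grab("fps", fps)
  width      <- grab("width", width)
  height     <- grab("height", height)
  subject_id <- grab("subject", subject_id %||% sub("\\.[^.]*$", "", basename(path)),
                     cast = identity)
  body <- lines[!meta_ln & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path)
  first <- strsplit(body[1L], ",", fixed = TRUE)[[1L]]
  if (any(is.na(suppressWarnings(as.numeric(first[nzchar(trimws(first))])))))
    body <- body[-1L]  # header row
  # sentinel keeps trailing empty fields that strsplit would otherwise drop
  cells <- lapply(strsplit(paste0(body, ",\1"), ",", fixed = TRUE),
                  function(x) x[-length(x)])
  ncol_exp <- 1L + 68L * 2L
  nc <- lengths(cells)
  bad <- which(nc != ncol_exp)
  if (length(bad))
    stop(sprintf("malformed landmark row (data row %d): %d fields, expected %d (frame + 68 x,y pairs)",
                 bad[1L], nc[bad[1L]], ncol_exp))
  m <- matrix(suppressWarnings(as.numeric(unlist(cells))), nrow = length(cells),
              ncol = ncol_exp, byrow = TRUE)
  T <- nrow(m)
  coords <- array(NA_real_, c(T, 68L, 2L))
  coords[, , 1L] <- m[, seq(2L, ncol_exp, by = 2L), drop = FALSE]
  coords[, , 2L] <- m[, seq(3L, ncol_exp, by = 2L), drop = FALSE]
  landmark_sequence(coords, fps = fps, subject_id = subject_id,
                    width = width, height = height)
}

#' Write a landmark time series as delimited text
#'
#' Inverse of [read_landmark_series()]; invalid landmarks are written as empty
#' fields and full-precision coordinates round-trip bit-exactly.
#'
#' @param seq a [landmark_sequence()].
#' @param path output file path.
#' @export
write_landmark_series <- function(seq, path) {
  T <- n_frames(seq)
  m <- matrix("", T, 1L + 136L)
  m[, 1L] <- as.character(seq_len(T) - 1L)
  xs <- format(seq$coords[, , 1L], digits = 17, trim = TRUE, scientific = FALSE)
  ys <- format(seq$coords[, , 2L], digits = 17, trim = TRUE, scientific = FALSE)
  xs[!seq$valid] <- ""; ys[!seq$valid] <- ""
  m[, seq(2L, 137L, by = 2L)] <- xs
  m[, seq(3L, 137L, by = 2L)] <- ys
  hdr <- c(sprintf("# subject: %s", seq$subject_id),
           sprintf("# fps: %s", format(seq$fps, digits = 17)),
           sprintf("# width: %d", seq$width),
           sprintf("# height: %d", seq$height),
           paste(c("frame", paste0(rep(c("x", "y"), 68L),
                                   rep(0:67, each = 2L))), collapse = ","))
  writeLines(c(hdr, apply(m, 1L, paste, collapse = ",")), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a recording into usable segments by the one-second gap rule
#'
#' Frames in which any landmark is invalid form gaps. Gaps no longer than
#' `max_gap` seconds are retained and flagged for linear interpolation; longer
#' gaps (and gaps at the start or end of the recording, which have no valid
#' neighbour on one side) are excluded and split the recording. Segments
#' shorter than 2 frames are dropped. The retain/exclude decision depends only
#' on gap duration in seconds, not on the frame rate.
#'
#' @param seq a [landmark_sequence()].
#' @param max_gap maximum retained gap duration in seconds (default 1).
#' @return list of segments, each `list(start, end, interpolated)` with a
#'   0-based half-open frame interval `[start, end)` and the 0-based indices of
#'   frames to be filled by interpolation. Empty list if no usable segment.
#' @export
gate_gaps <- function(seq, max_gap = 1.0) {
  stopifnot(seq$fps > 0)
  T <- n_frames(seq)
  bad <- rowSums(!seq$valid) > 0L
  if (all(bad)) return(list())
  r <- rle(bad)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  # splitting gaps: too long, or touching either end of the recording
  split_gap <- r$values & (r$lengths / seq$fps > max_gap | starts == 1L | ends == T)
  cuts <- c(0L, unlist(Map(function(s, e) c(s - 1L, e), starts[split_gap],
                           ends[split_gap])), T)
  segs <- list()
  for (k in seq(1L, length(cuts) - 1L, by = 2L)) {
    s <- cuts[k]; e <- cuts[k + 1L]       # 0-based half-open
    if (e - s < 2L) next
    interp <- which(bad[(s + 1L):e]) + s - 1L   # 0-based
    segs[[length(segs) + 1L]] <- list(start = s, end = e,
                                      interpolated = as.integer(interp))
  }
  segs
}

#' Extract one gated segment with short gaps linearly interpolated
#'
#' Each invalid landmark coordinate inside the segment is filled by linear
#' interpolation in time between its nearest valid neighbours; segment
#' endpoints are valid by construction of [gate_gaps()].
#'
#' @param seq a [landmark_sequence()].
#' @param segment one element of the [gate_gaps()] result.
#' @return a [landmark_sequence()] restricted to the segment, fully valid,
#'   with attribute `frame_offset` giving the 0-based index of its first frame
#'   in the original recording.
#' @export
interpolate_segment <- function(seq, segment) {
  idx <- (segment$start + 1L):segment$end          # 1-based rows
  co <- seq$coords[idx, , , drop = FALSE]
  va <- seq$valid[idx, , drop = FALSE]
  if (!all(va[1L, ]) || !all(va[nrow(va), ]))
    stop("segment endpoints must be valid (contract of gate_gaps)")
  if (!all(va)) {
    t <- seq_len(nrow(va))
    for (j in which(colSums(!va) > 0L)) {
      ok <- va[, j]
      for (d in 1:2)
        co[!ok, j, d] <- approx(t[ok], co[ok, j, d], xout = t[!ok])$y
    }
  }
  out <- landmark_sequence(co, fps = seq$fps, subject_id = seq$subject_id,
                           width = seq$width, height = seq$height)
  attr(out, "frame_offset") <- segment$start
  out
}

#' Gate and interpolate a recording in one step
#'
#' Convenience wrapper: applies [gate_gaps()] then [interpolate_segment()] to
#' every retained segment. Set `fill = "drop"` to discard short-gap frames
#' instead of interpolating them (each run of valid frames then becomes its
#' own segment).
#'
#' @inheritParams gate_gaps
#' @param fill `"interpolate"` (default) or `"drop"`.
#' @return list of fully valid `landmark_sequence` segments (possibly empty).
#' @export
gated_segments <- function(seq, max_gap = 1.0, fill = c("interpolate", "drop")) {
  fill <- match.arg(fill)
  segs <- gate_gaps(seq, max_gap)
  if (fill == "interpolate")
    return(lapply(segs, function(s) interpolate_segment(seq, s)))
  out <- list()
  for (s in segs) {
    bad <- c(s$interpolated)
    keep <- setdiff(s$start:(s$end - 1L), bad)
    runs <- split(keep, cumsum(c(1L, diff(keep) != 1L)))
    for (r in runs) {
      if (length(r) < 2L) next
      sub <- list(start = r[1L], end = r[length(r)] + 1L, interpolated = integer())
      out[[length(out) + 1L]] <- interpolate_segment(seq, sub)
    }
  }
  out
}

#' Read a cohort metadata table
#'
#' Delimited text with one row per subject: `subject_id`, `group` (PD/HC) and
#' optional `age`, `sex`, clinical sub-scores (`mds_updrs_iii`,
#' `brady_rigidity`, `pigd`, `moca`, `bdi_ii`), binding ratios (`caudate_sbr`,
#' `putamen_sbr`) and the 0-3 `perceptual` rating.
#'
#' @param path file path (comma- or tab-delimited, with header).
#' @return a `data.frame` with `group` as a factor with levels `HC`, `PD`.
#' @export
read_cohort_table <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  if (!all(c("subject_id", "group") %in% names(df)))
    stop("cohort table needs subject_id and group columns")
  if (!all(df$group %in% c("PD", "HC")))
    stop("group must be PD or HC")
  if ("perceptual" %in% names(df) &&
      !all(is.na(df$perceptual) | df$perceptual %in% 0:3))
    stop("perceptual rating must be in 0..3")
  df$group <- factor(df$group, levels = c("HC", "PD"))
  df$subject_id <- as.character(df$subject_id)
  df
}
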