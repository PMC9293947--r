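#' Frame sources
#'
#' A `frame_source` yields, for any 0-based frame index, a `height x width`
#' luminance matrix with levels in `[0, 1]`. Sources can wrap an in-memory
#' array, a directory of numbered still images (PNG), or a generator function
#' (used by the synthetic renderer). When paired with a [landmark_sequence()]
#' the frame count must match.
#'
#' @param get function of one 0-based frame index returning the luminance
#'   matrix.
#' @param n_frames total number of frames.
#' @param width,height frame size in pixels.
#' @return an object of class `frame_source`.
#' @export
frame_source <- function(get, n_frames, width, height) {
  stopifnot(is.function(get), n_frames >= 1L)
  structure(list(get = get, n_frames = as.integer(n_frames),
                 width = as.integer(width), height = as.integer(height)),
            class = "frame_source")
}

#' @export
print.frame_source <- function(x, ...) {
  cat(sprintf("<frame_source> %d frames, %dx%d px\n", x$n_frames, x$width,
              x$height))
  invisible(x)
}

#' Fetch one luminance frame
#'
#' @param src a [frame_source()].
#' @param t 0-based frame index.
#' @return `height x width` matrix in `[0, 1]`.
#' @export
get_frame <- function(src, t) {
  if (t < 0L || t >= src$n_frames) stop("frame index out of range")
  src$get(t)
}

#' @rdname frame_source
#' @param frames `height x width x T` numeric array, values in `[0, 1]`.
#' @export
frame_source_array <- function(frames) {
  d <- dim(frames)
  if (length(d) != 3L) stop("frames must be height x width x T")
  frame_source(function(t) frames[, , t + 1L], d[3L], d[2L], d[1L])
}

#' @rdname frame_source
#' @param dir directory containing numbered `.png` frames (lexicographic
#'   order = temporal order); images are converted to `[0, 1]` luminance via
#'   [luminance_normalize()].
#' @export
frame_source_directory <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no .png frames in ", dir)
  first <- luminance_normalize(png::readPNG(files[1L]))
  frame_source(function(t) luminance_normalize(png::readPNG(files[t + 1L])),
               length(files), ncol(first), nrow(first))
}
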