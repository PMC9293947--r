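# Surface-marker regions of interest: placement from landmarks, luminance
# normalization, edge highlighting, and per-frame scalar image entropy.

#' Default region-of-interest geometry
#'
#' All extents are dimensionless multiples of the inner-eye-corner distance
#' (IED), so region size tracks apparent face size. Regions are axis-aligned;
#' the canonical patch is square.
#'
#' @param patch_px side of the canonical resampled patch in pixels (>= 8).
#' @param forehead_w,forehead_h forehead rectangle width/height (x IED).
#' @param forehead_gap distance between eyebrow apices and the forehead
#'   rectangle's lower edge (x IED).
#' @param square_side side of the nose-root and lateral-canthal squares
#'   (x IED).
#' @param canthal_offset lateral offset of the canthal square's centre from
#'   the outer eye corner (x IED).
#' @param cheek_w,cheek_h cheek rectangle width/height (x IED).
#' @param cheek_drop distance from the lower-eyelid midpoint to the cheek
#'   rectangle's top edge (x IED).
#' @return list of geometry parameters consumed by [extract_patch()].
#' @export
roi_config <- function(patch_px = 64L, forehead_w = 1.6, forehead_h = 0.8,
                       forehead_gap = 0.15, square_side = 0.5,
                       canthal_offset = 0.35, cheek_w = 0.7, cheek_h = 0.9,
                       cheek_drop = 0.25) {
  stopifnot(patch_px >= 8L, forehead_w > 0, forehead_h > 0, square_side > 0,
            cheek_w > 0, cheek_h > 0)
  as.list(environment())
}

REGION_NAMES <- c("forehead", "nose_root", "lateral_canthal_L",
                  "lateral_canthal_R", "cheek_L", "cheek_R")

#' Convert a frame to normalized luminance
#'
#' Grayscale frames are divided by the maximum representable level (255 for
#' 8-bit integer input); colour frames first undergo the Rec. 709 luminance
#' transform. Normalization is by the representable maximum, never per-frame
#' min-max, so temporal contrast changes remain visible downstream.
#'
#' @param img matrix (grayscale) or `H x W x 3` array (RGB); integer values
#'   are assumed 8-bit, floating-point values are assumed already in `[0, 1]`
#'   unless they exceed 1.
#' @param max_level representable maximum; `NULL` auto-detects (255 when any
#'   value exceeds 1, else 1).
#' @return `H x W` matrix in `[0, 1]`.
#' @export
luminance_normalize <- function(img, max_level = NULL) {
  if (length(img) == 0L) stop("empty image")
  if (length(dim(img)) == 3L) {
    if (dim(img)[3L] >= 3L)
      img <- 0.2126 * img[, , 1L] + 0.7152 * img[, , 2L] + 0.0722 * img[, , 3L]
    else img <- img[, , 1L]
  }
  if (is.null(max_level))
    max_level <- if (is.integer(img) || max(img, na.rm = TRUE) > 1) 255 else 1
  out <- img / max_level
  pmin(pmax(out, 0), 1)
}

# Region rectangle (xmin, xmax, ymin, ymax in pixels) from the landmarks of
# one frame. pts: 68 x 2 matrix.
region_rect <- function(pts, region, cfg) {
  ied <- sqrt(sum((pts[lm_idx(IBUG$eye_inner_R), ] -
                   pts[lm_idx(IBUG$eye_inner_L), ])^2))
  if (ied <= 0) stop("degenerate geometry: zero inner-eye-corner distance")
  ap_R <- pts[lm_idx(IBUG$brow_apex_R), ]; ap_L <- pts[lm_idx(IBUG$brow_apex_L), ]
  if (region == "forehead") {
    cx <- (ap_R[1L] + ap_L[1L]) / 2
    y1 <- min(ap_R[2L], ap_L[2L]) - cfg$forehead_gap * ied
    return(c(cx - cfg$forehead_w / 2 * ied, cx + cfg$forehead_w / 2 * ied,
             y1 - cfg$forehead_h * ied, y1))
  }
  if (region == "nose_root") {
    c0 <- (pts[lm_idx(IBUG$brow_med_R), ] + pts[lm_idx(IBUG$brow_med_L), ]) / 2
    h <- cfg$square_side / 2 * ied
    return(c(c0[1L] - h, c0[1L] + h, c0[2L] - h, c0[2L] + h))
  }
  if (region %in% c("lateral_canthal_L", "lateral_canthal_R")) {
    side <- sub(".*_", "", region)
    outer <- pts[lm_idx(if (side == "R") IBUG$eye_outer_R else IBUG$eye_outer_L), ]
    inner <- pts[lm_idx(if (side == "R") IBUG$eye_inner_R else IBUG$eye_inner_L), ]
    u <- outer - inner; u <- u / sqrt(sum(u^2))   # unit vector, medial -> lateral
    c0 <- outer + cfg$canthal_offset * ied * u
    h <- cfg$square_side / 2 * ied
    return(c(c0[1L] - h, c0[1L] + h, c0[2L] - h, c0[2L] + h))
  }
  if (region %in% c("cheek_L", "cheek_R")) {
    side <- sub(".*_", "", region)
    lower_lid <- if (side == "R") c(40L, 41L) else c(46L, 47L)
    lid_mid <- colMeans(pts[lm_idx(lower_lid), , drop = FALSE])
    wing <- pts[lm_idx(if (side == "R") IBUG$nose_wing_R else IBUG$nose_wing_L), ]
    y1 <- lid_mid[2L] + cfg$cheek_drop * ied
    # medial edge at the nose wing, extending laterally
    if (side == "R") xr <- c(wing[1L] - cfg$cheek_w * ied, wing[1L])
    else             xr <- c(wing[1L], wing[1L] + cfg$cheek_w * ied)
    return(c(xr[1L], xr[2L], y1, y1 + cfg$cheek_h * ied))
  }
  stop("unknown region: ", region)
}

#' Extract a canonical ROI patch from one frame
#'
#' Positions the region rectangle from its anchor landmarks at frame `t`,
#' scales it by the inner-eye-corner distance, and resamples it by bilinear
#' interpolation onto the canonical square grid. Sample points falling outside
#' the frame are clamped; the fraction of in-frame sample points is recorded
#' as the patch's `coverage` attribute, and coverage below 0.5 marks the
#' frame unusable for this region (`NULL` return).
#'
#' @param frame `H x W` luminance matrix in `[0, 1]`.
#' @param seq a fully valid [landmark_sequence()] (gated segment).
#' @param t 0-based frame index within `seq`.
#' @param region one of `"forehead"`, `"nose_root"`, `"lateral_canthal_L"`,
#'   `"lateral_canthal_R"`, `"cheek_L"`, `"cheek_R"`.
#' @param cfg a [roi_config()].
#' @return `patch_px x patch_px` matrix with attribute `coverage`, or `NULL`
#'   when coverage < 0.5.
#' @export
extract_patch <- function(frame, seq, t, region, cfg = roi_config()) {
  pts <- seq$coords[t + 1L, , ]
  rect <- region_rect(pts, region, cfg)
  P <- cfg$patch_px
  gx <- seq.int(rect[1L], rect[2L], length.out = P)
  gy <- seq.int(rect[3L], rect[4L], length.out = P)
  H <- nrow(frame); W <- ncol(frame)
  inside <- outer(gy >= 0 & gy <= H - 1, gx >= 0 & gx <= W - 1, "&")
  coverage <- mean(inside)
  if (coverage < 0.5) return(NULL)
  patch <- bilinear_sample(frame, gx, gy)
  attr(patch, "coverage") <- coverage
  patch
}

# Bilinear sampling of frame at the grid gy (rows) x gx (cols), pixel-center
# coordinates, clamped to the frame.
bilinear_sample <- function(frame, gx, gy) {
  H <- nrow(frame); W <- ncol(frame)
  gx <- pmin(pmax(gx, 0), W - 1); gy <- pmin(pmax(gy, 0), H - 1)
  x0 <- floor(gx); y0 <- floor(gy)
  x1 <- pmin(x0 + 1, W - 1); y1 <- pmin(y0 + 1, H - 1)
  fx <- gx - x0; fy <- gy - y0
  P <- length(gy); Q <- length(gx)
  ix0 <- rep(x0 + 1, each = P); ix1 <- rep(x1 + 1, each = P)
  iy0 <- rep(y0 + 1, times = Q); iy1 <- rep(y1 + 1, times = Q)
  FX <- rep(fx, each = P); FY <- rep(fy, times = Q)
  v <- (1 - FX) * (1 - FY) * frame[cbind(iy0, ix0)] +
       FX * (1 - FY) * frame[cbind(iy0, ix1)] +
       (1 - FX) * FY * frame[cbind(iy1, ix0)] +
       FX * FY * frame[cbind(iy1, ix1)]
  matrix(v, nrow = P, ncol = Q)
}

#' Highlight edges in a patch
#'
#' Gradient magnitude from 3x3 horizontal/vertical difference (Sobel) kernels
#' with replicate border padding, rescaled by 1/4 so a unit step edge maps to
#' approximately 1. Deterministic; a constant patch yields all zeros, and the
#' output is invariant to adding a constant to the patch.
#'
#' @param patch numeric matrix in `[0, 1]`.
#' @return edge-magnitude matrix of the same size.
#' @export
edge_highlight <- function(patch) {
  H <- nrow(patch); W <- ncol(patch)
  up <- patch[c(1L, 1L:(H - 1L)), , drop = FALSE]
  dn <- patch[c(2L:H, H), , drop = FALSE]
  sh <- function(m, dir) {  # horizontal shift with replicate padding
    if (dir == "l") m[, c(1L, 1L:(W - 1L)), drop = FALSE]
    else m[, c(2L:W, W), drop = FALSE]
  }
  gx <- (sh(up, "r") + 2 * sh(patch, "r") + sh(dn, "r")) -
        (sh(up, "l") + 2 * sh(patch, "l") + sh(dn, "l"))
  gy <- (sh(dn, "l") + 2 * dn + sh(dn, "r")) -
        (sh(up, "l") + 2 * up + sh(up, "r"))
  sqrt(gx^2 + gy^2) / 4
}

#' Shannon entropy of a patch
#'
#' Entropy in bits of the fixed-range histogram of the values: `n_bins` equal
#' bins over `[0, range_max]` (values above `range_max` fall in the top bin),
#' with the `0 * log(0) = 0` convention. Permutation-invariant and bounded by
#' `log2(n_bins)`.
#'
#' @param values nonempty numeric vector/matrix of nonnegative values.
#' @param n_bins histogram bins (default 64).
#' @param range_max upper end of the fixed histogram range (default 1).
#' @return entropy in bits.
#' @export
patch_entropy <- function(values, n_bins = 64L, range_max = 1) {
  if (length(values) == 0L) stop("empty value array")
  bin <- pmin(pmax(floor(as.numeric(values) / range_max * n_bins), 0L),
              n_bins - 1L)
  p <- tabulate(bin + 1L, nbins = n_bins) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}
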