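# Synthetic face-motion generator: animated 68-point landmark recordings,
# procedurally rendered grayscale frames, and full cohorts with ground-truth
# hypomimia severity. Severity acts multiplicatively on movement amplitude
# (effective amplitude = base x (1 - severity x reduction weight)), matching
# the construct of reduced-amplitude facial movements; every region's marker
# is therefore expected to decrease with severity.

#' Synthetic cohort configuration
#'
#' Movement amplitudes are expressed as multiples of the inner-eye-corner
#' distance (IED) so that recordings are geometrically self-similar across
#' resolutions; the IED in pixels is `width * ied_frac`. Signal defaults:
#' sparse upper-face events (eyebrow raises, frowns, blinks, smiles as
#' Poisson event trains at 0.15-0.35 events/s) and band-limited 2-7 Hz
#' speech-like lower-face motion. The covariate model links severity linearly
#' to clinical scores (positive) and binding ratios (negative) with additive
#' Gaussian noise, reproducing the cohort structure of a de-novo PD study
#' population (91 patients, 75 controls, ages ~61 +/- 12).
#'
#' @param n_controls,n_patients group sizes (>= 2 each).
#' @param duration recording length in seconds.
#' @param fps frame rate (monologue recordings: 25).
#' @param width,height frame size in pixels.
#' @param ied_frac inner-eye-corner distance as a fraction of frame width.
#' @param amplitudes named base movement amplitudes: `brow`, `frown` (IED
#'   units), `blink`, `aperture` (dimensionless modulation depths), `smile`,
#'   `jaw`, `upper_lip`, `lower_lip`, `corner` (IED units).
#' @param reduction named per-signal severity reduction weights in `[0, 1]`.
#' @param severity_dist function of `n` drawing patient severities in
#'   `[0, 1]`.
#' @param jitter_sd white landmark-tracking jitter SD (IED units).
#' @param head_amp,head_freq slow rigid head-translation amplitude (IED
#'   units) and frequency (Hz).
#' @param gap_rate expected occlusion gaps per second; `gap_short`,
#'   `gap_long` duration ranges (s); `gap_long_prob` probability a gap is
#'   long (> 1 s, hence excluded by gating).
#' @param gap_short,gap_long numeric length-2 duration ranges in seconds.
#' @param gap_long_prob probability of drawing from `gap_long`.
#' @param render logical: generate frames for the surface markers.
#' @param wrinkle_contrast peak darkening of wrinkle lines (luminance units).
#' @param seed integer master seed; subject `i` uses the documented substream
#'   seed `(seed + 1000003 * i) mod (2^31 - 1)`.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_controls = 75L, n_patients = 91L, duration = 60,
                         fps = 25, width = 1440L, height = 1080L,
                         ied_frac = 1 / 9,
                         amplitudes = c(brow = 0.15, frown = 0.06,
                                        blink = 0.9, aperture = 0.1,
                                        smile = 0.25, jaw = 0.3,
                                        upper_lip = 0.07, lower_lip = 0.1,
                                        corner = 0.08),
                         reduction = c(brow = 0.8, frown = 0.8, blink = 0.8,
                                       smile = 0.8, speech = 0.8),
                         severity_dist = function(n) stats::rbeta(n, 2, 2),
                         jitter_sd = 0.01, head_amp = 0.05, head_freq = 0.2,
                         gap_rate = 1 / 30, gap_short = c(0.2, 0.8),
                         gap_long = c(1.2, 2.5), gap_long_prob = 0.3,
                         render = TRUE, wrinkle_contrast = 0.35, seed = 1L) {
  stopifnot(n_controls >= 2L, n_patients >= 2L, duration > 0, fps > 0,
            all(amplitudes >= 0), all(reduction >= 0 & reduction <= 1))
  structure(as.list(environment()), class = "synth_config")
}

subject_seed <- function(seed, i) as.integer((seed + 1000003 * i) %% (2^31 - 1))

# Neutral 68-point face template in IED units, origin midway between the
# inner eye corners, x rightward (subject's left), y downward.
face_template <- function() {
  p <- matrix(NA_real_, 68L, 2L)
  set_pt <- function(i0, x, y) p[lm_idx(i0), ] <<- c(x, y)
  jaw_x <- c(-2.3, -2.25, -2.1, -1.85, -1.5, -1.05, -0.6, -0.3, 0)
  jaw_y <- c(0, 0.6, 1.2, 1.75, 2.3, 2.75, 3.05, 3.22, 3.3)
  for (k in 1:9) set_pt(k - 1L, jaw_x[k], jaw_y[k])          # 0..8 (chin 8)
  for (k in 1:8) set_pt(8L + k, -jaw_x[9 - k], jaw_y[9 - k]) # 9..16
  bx <- c(1.7, 1.4, 1.05, 0.7, 0.45); by <- c(-0.45, -0.55, -0.6, -0.55, -0.45)
  for (k in 1:5) set_pt(16L + k, -bx[k], by[k])              # right brow 17..21
  for (k in 1:5) set_pt(21L + k, bx[6 - k], by[6 - k])       # left brow 22..26
  set_pt(27L, 0, -0.1); set_pt(28L, 0, 0.35)
  set_pt(29L, 0, 0.8);  set_pt(30L, 0, 1.2)                  # nose tip
  set_pt(31L, -0.35, 1.35); set_pt(32L, -0.18, 1.4); set_pt(33L, 0, 1.45)
  set_pt(34L, 0.18, 1.4);   set_pt(35L, 0.35, 1.35)
  ex <- c(1.5, 1.17, 0.83, 0.5)                              # outer -> inner
  set_pt(36L, -ex[1], 0); set_pt(37L, -ex[2], -0.12); set_pt(38L, -ex[3], -0.12)
  set_pt(39L, -ex[4], 0); set_pt(40L, -ex[3], 0.12);  set_pt(41L, -ex[2], 0.12)
  set_pt(42L, ex[4], 0);  set_pt(43L, ex[3], -0.12);  set_pt(44L, ex[2], -0.12)
  set_pt(45L, ex[1], 0);  set_pt(46L, ex[2], 0.12);   set_pt(47L, ex[3], 0.12)
  mo_x <- c(-0.8, -0.5, -0.2, 0, 0.2, 0.5, 0.8)
  mo_yu <- c(2.1, 1.95, 1.88, 1.9, 1.88, 1.95, 2.1)
  for (k in 1:7) set_pt(47L + k, mo_x[k], mo_yu[k])          # 48..54
  set_pt(55L, 0.5, 2.3); set_pt(56L, 0.25, 2.4); set_pt(57L, 0, 2.42)
  set_pt(58L, -0.25, 2.4); set_pt(59L, -0.5, 2.3)
  set_pt(60L, -0.65, 2.1); set_pt(61L, -0.25, 2.02); set_pt(62L, 0, 2.04)
  set_pt(63L, 0.25, 2.02); set_pt(64L, 0.65, 2.1)
  set_pt(65L, 0.25, 2.2); set_pt(66L, 0, 2.22); set_pt(67L, -0.25, 2.2)
  p
}

# band-limited noise, SD 1, as a sum of random-phase sinusoids in [f_lo, f_hi]
bandlimited_noise <- function(tt, f_lo = 2, f_hi = 7, k = 16L) {
  f <- runif(k, f_lo, f_hi); ph <- runif(k, 0, 2 * pi); a <- abs(rnorm(k))
  s <- colSums(a * sin(outer(f, tt, function(f, t) 2 * pi * f * t) +
                       ph))
  if (sd(s) == 0) return(s)
  (s - mean(s)) / sd(s)
}

# sparse smooth event train: sum of Gaussian bumps, peak ~1 per event
event_train <- function(tt, rate, width, duration) {
  n <- rpois(1L, rate * duration)
  s <- numeric(length(tt))
  if (n > 0L) {
    ctr <- runif(n, 0, duration)
    for (c0 in ctr) s <- s + exp(-(tt - c0)^2 / (2 * width^2))
  }
  pmin(s, 1.2)
}

#' Animate a synthetic landmark recording
#'
#' Deforms the neutral 68-point template over time with per-region
#' band-limited oscillations and sparse expression events, scaled by the
#' subject's effective amplitudes (base amplitude x (1 - severity x reduction
#' weight)), plus optional slow rigid head motion, white landmark jitter, and
#' an occlusion-gap model. Deterministic per seed.
#'
#' @param config a [synth_config()].
#' @param severity hypomimia severity in `[0, 1]` (controls: 0).
#' @param seed integer seed for this recording.
#' @param subject_id subject identifier.
#' @return list with elements `seq` (a [landmark_sequence()]) and `truth`
#'   (severity, effective signal factors, per-frame expression signals used
#'   by the renderer).
#' @export
animate_landmarks <- function(config, severity, seed = 1L,
                              subject_id = "synthetic") {
  if (severity < 0 || severity > 1) stop("severity must be in [0, 1]")
  set.seed(seed)
  T <- max(2L, round(config$duration * config$fps))
  tt <- (seq_len(T) - 1L) / config$fps
  ied <- config$width * config$ied_frac
  A <- config$amplitudes; w <- config$reduction
  eff <- c(brow  = 1 - severity * w[["brow"]],
           frown = 1 - severity * w[["frown"]],
           blink = 1 - severity * w[["blink"]],
           smile = 1 - severity * w[["smile"]],
           speech = 1 - severity * w[["speech"]])
  # raw (unit-scale) expression signals; renderer consumes signal * eff
  sig <- list(
    brow  = event_train(tt, 0.30, 0.35, config$duration),
    frown = event_train(tt, 0.20, 0.45, config$duration),
    blink = event_train(tt, 0.25, 0.06, config$duration),
    aperture = bandlimited_noise(tt, 0.2, 0.6),
    smile = event_train(tt, 0.15, 0.80, config$duration),
    jaw   = bandlimited_noise(tt, 2, 7),
    ulip  = bandlimited_noise(tt, 2, 7),
    llip  = bandlimited_noise(tt, 2, 7),
    corner = bandlimited_noise(tt, 2, 7)
  )
  base <- face_template() * ied
  ctr <- c(config$width / 2, config$height * 0.38)
  co <- array(0, c(T, 68L, 2L))
  co[, , 1L] <- matrix(base[, 1L], T, 68L, byrow = TRUE) + ctr[1L]
  co[, , 2L] <- matrix(base[, 2L], T, 68L, byrow = TRUE) + ctr[2L]

  add_y <- function(ids0, series) {
    j <- lm_idx(ids0)
    co[, j, 2L] <<- co[, j, 2L] + matrix(series, T, length(j))
  }
  add_x <- function(ids0, series) {
    j <- lm_idx(ids0)
    co[, j, 1L] <<- co[, j, 1L] + matrix(series, T, length(j))
  }
  # eyebrow raise: both brows up, slight left/right asymmetry
  raise <- A[["brow"]] * eff[["brow"]] * ied * sig$brow
  add_y(IBUG$brow_R, -raise)
  add_y(IBUG$brow_L, -0.9 * raise)
  # frown: medial brow ends down and inward
  fr <- A[["frown"]] * eff[["frown"]] * ied * sig$frown
  add_y(c(20L, 21L, 22L, 23L), fr)
  add_x(c(20L, 21L), 0.5 * fr); add_x(c(22L, 23L), -0.5 * fr)
  # eyelids: aperture factor scales the template's vertical eye offsets
  ap <- pmax(0, 1 - A[["blink"]] * eff[["blink"]] * pmin(sig$blink, 1) +
                A[["aperture"]] * eff[["blink"]] * 0.5 * sig$aperture)
  for (ids in list(c(37L, 38L, 40L, 41L), c(43L, 44L, 46L, 47L))) {
    j <- lm_idx(ids)
    rel <- matrix(base[j, 2L], T, length(j), byrow = TRUE)  # +/-0.12 IED
    co[, j, 2L] <- co[, j, 2L] - rel + rel * ap
  }
  # smile: mouth corners lateral + up, cheeks raise (renderer signal)
  sm <- A[["smile"]] * eff[["smile"]] * ied * sig$smile
  add_x(IBUG$mouth_corner_R, -sm); add_x(IBUG$mouth_corner_L, sm)
  add_y(c(IBUG$mouth_corner_R, IBUG$mouth_corner_L), -0.5 * sm)
  # speech-like jaw/lip motion
  jawm <- A[["jaw"]] * eff[["speech"]] * ied * sig$jaw
  add_y(5:11, 0.8 * jawm); add_y(IBUG$chin, 0)  # chin in 5:11 already
  add_y(55:59, 0.6 * jawm)
  add_y(IBUG$lower_lip, A[["lower_lip"]] * eff[["speech"]] * ied * sig$llip)
  add_y(IBUG$upper_lip, A[["upper_lip"]] * eff[["speech"]] * ied * sig$ulip)
  add_x(IBUG$mouth_corner_R,
        -A[["corner"]] * eff[["speech"]] * ied * sig$corner)
  add_x(IBUG$mouth_corner_L,
        A[["corner"]] * eff[["speech"]] * ied * sig$corner)
  # rigid head motion (translation, slow)
  if (config$head_amp > 0) {
    hx <- config$head_amp * ied * sin(2 * pi * config$head_freq * tt +
                                      runif(1, 0, 2 * pi))
    hy <- 0.6 * config$head_amp * ied * sin(2 * pi * 0.7 * config$head_freq *
                                            tt + runif(1, 0, 2 * pi))
    co[, , 1L] <- co[, , 1L] + hx
    co[, , 2L] <- co[, , 2L] + hy
  }
  if (config$jitter_sd > 0)
    co <- co + array(rnorm(length(co), 0, config$jitter_sd * ied), dim(co))
  co[, , 1L] <- pmin(pmax(co[, , 1L], 0), config$width - 1e-6)
  co[, , 2L] <- pmin(pmax(co[, , 2L], 0), config$height - 1e-6)
  # occlusion gaps: runs of frames with some landmarks invalid
  valid <- matrix(TRUE, T, 68L)
  n_gaps <- rpois(1L, config$gap_rate * config$duration)
  if (n_gaps > 0L) {
    for (g in seq_len(n_gaps)) {
      long <- runif(1) < config$gap_long_prob
      dur <- if (long) runif(1, config$gap_long[1], config$gap_long[2])
             else runif(1, config$gap_short[1], config$gap_short[2])
      len <- max(1L, round(dur * config$fps))
      st <- sample.int(max(1L, T - len), 1L)
      valid[st:min(T, st + len - 1L), lm_idx(c(IBUG$brow_R, IBUG$brow_L))] <- FALSE
    }
  }
  seq <- landmark_sequence(co, fps = config$fps, subject_id = subject_id,
                           valid = valid, width = config$width,
                           height = config$height)
  list(seq = seq,
       truth = list(subject_id = subject_id, severity = severity, eff = eff,
                    effective_amplitudes = c(
                      brow = A[["brow"]] * eff[["brow"]],
                      frown = A[["frown"]] * eff[["frown"]],
                      blink = A[["blink"]] * eff[["blink"]],
                      smile = A[["smile"]] * eff[["smile"]],
                      jaw = A[["jaw"]] * eff[["speech"]]),
                    signals = sig, seed = seed))
}

#' Render procedural grayscale frames for a synthetic recording
#'
#' Low-fidelity face rendering sufficient to exercise the surface markers:
#' smooth base shading anchored to the per-frame face position, procedural
#' forehead/glabellar/lateral-canthal wrinkle curves whose contrast is
#' modulated by the corresponding instantaneous expression signal, and a
#' cheek texture displaced by the cheek-raise signal. Deterministic per seed;
#' at severity 1 with unit reduction weights (and no head motion/jitter) the
#' frames are temporally constant.
#'
#' @param seq the [landmark_sequence()] from [animate_landmarks()].
#' @param truth the matching ground-truth element (carries the signals).
#' @param config the [synth_config()].
#' @param seed seed for the static texture phases.
#' @return a lazy [frame_source()].
#' @export
render_frames <- function(seq, truth, config, seed = 1L) {
  W <- seq$width; H <- seq$height
  ied <- config$width * config$ied_frac
  set.seed(seed)
  ph <- runif(6, 0, 2 * pi)                     # static texture phases
  sig <- truth$signals; eff <- truth$eff
  contrast <- config$wrinkle_contrast
  # texture modulation scales with the effective movement amplitude, so
  # halving a base amplitude halves the corresponding texture drive; the
  # denominators are the default base amplitudes (drive 1 at defaults)
  A <- config$amplitudes
  drv_brow <- A[["brow"]] / 0.15 * eff[["brow"]]
  drv_frown <- A[["frown"]] / 0.06 * eff[["frown"]]
  drv_smile <- A[["smile"]] / 0.25 * eff[["smile"]]
  xg <- seq_len(W) - 1; yg <- seq_len(H) - 1
  gauss_line <- function(img, x0, x1, ycurve, sigma, depth) {
    # darken along y = ycurve(x) for x in [x0, x1]
    cols <- which(xg >= x0 & xg <= x1)
    if (!length(cols)) return(img)
    yc <- ycurve(xg[cols])
    rows <- which(yg >= min(yc) - 3 * sigma & yg <= max(yc) + 3 * sigma)
    if (!length(rows)) return(img)
    img[rows, cols] <- img[rows, cols] -
      depth * exp(-outer(yg[rows], yc, "-")^2 / (2 * sigma^2))
    img
  }
  gauss_vline <- function(img, y0, y1, x0, sigma, depth) {
    rows <- which(yg >= y0 & yg <= y1)
    cols <- which(xg >= x0 - 3 * sigma & xg <= x0 + 3 * sigma)
    if (!length(rows) || !length(cols)) return(img)
    img[rows, cols] <- img[rows, cols] -
      depth * matrix(exp(-(xg[cols] - x0)^2 / (2 * sigma^2)),
                     length(rows), length(cols), byrow = TRUE)
    img
  }
  get <- function(t) {
    pts <- seq$coords[t + 1L, , ]
    fc <- colMeans(pts)
    # base shading: bright face oval on mid-gray background
    img <- 0.35 + 0.3 * exp(-(outer(rep(1, H), (xg - fc[1L])^2 / (2.4 * ied)^2) +
                              outer((yg - fc[2L])^2 / (2.6 * ied)^2, rep(1, W))))
    s_brow <- sig$brow[t + 1L] * drv_brow
    s_frown <- sig$frown[t + 1L] * drv_frown
    s_smile <- sig$smile[t + 1L] * drv_smile
    # forehead wrinkle lines above the brow apices
    apy <- min(pts[lm_idx(IBUG$brow_apex_R), 2L], pts[lm_idx(IBUG$brow_apex_L), 2L])
    apx <- (pts[lm_idx(IBUG$brow_apex_R), 1L] + pts[lm_idx(IBUG$brow_apex_L), 1L]) / 2
    if (s_brow > 1e-3) {
      for (j in 1:3) {
        y0 <- apy - (0.25 + 0.22 * j) * ied
        img <- gauss_line(img, apx - 0.8 * ied, apx + 0.8 * ied,
                          function(x) y0 + 0.05 * ied *
                            sin(2 * pi * (x - apx) / (1.3 * ied) + ph[j]),
                          0.035 * ied, contrast * s_brow)
      }
    }
    # glabellar (nose-root) vertical lines
    if (s_frown > 1e-3) {
      gy <- (pts[lm_idx(IBUG$brow_med_R), 2L] + pts[lm_idx(IBUG$brow_med_L), 2L]) / 2
      gx <- (pts[lm_idx(IBUG$brow_med_R), 1L] + pts[lm_idx(IBUG$brow_med_L), 1L]) / 2
      for (dx in c(-0.1, 0.1))
        img <- gauss_vline(img, gy - 0.2 * ied, gy + 0.35 * ied,
                           gx + dx * ied, 0.03 * ied, contrast * s_frown)
    }
    # lateral canthal lines (crow's feet) radiating from the outer corners
    if (s_smile > 1e-3) {
      for (side in c("R", "L")) {
        oc <- pts[lm_idx(if (side == "R") IBUG$eye_outer_R else IBUG$eye_outer_L), ]
        dir <- if (side == "R") -1 else 1
        for (j in 1:3) {
          sl <- (j - 2) * 0.45
          x0 <- oc[1L] + dir * 0.15 * ied; x1 <- oc[1L] + dir * 0.62 * ied
          img <- gauss_line(img, min(x0, x1), max(x0, x1),
                            function(x) oc[2L] + sl * dir * (x - oc[1L]),
                            0.03 * ied, 0.8 * contrast * s_smile)
        }
      }
    }
    # cheek texture displaced vertically by the cheek-raise (smile) signal;
    # displacement up to ~0.45 IED so inter-frame luminance changes are well
    # above the entropy histogram's quantization step
    dy <- 0.45 * ied * s_smile
    for (side in c("R", "L")) {
      wing <- pts[lm_idx(if (side == "R") IBUG$nose_wing_R else IBUG$nose_wing_L), ]
      lid <- if (side == "R") c(40L, 41L) else c(46L, 47L)
      cy <- mean(pts[lm_idx(lid), 2L]) + 0.7 * ied
      cx <- wing[1L] + (if (side == "R") -0.35 else 0.35) * ied
      rows <- which(yg >= cy - 0.6 * ied & yg <= cy + 0.6 * ied)
      cols <- which(xg >= cx - 0.45 * ied & xg <= cx + 0.45 * ied)
      if (length(rows) && length(cols)) {
        tex <- outer(sin(2 * pi * (yg[rows] + dy) / (0.23 * ied) + ph[4]),
                     sin(2 * pi * xg[cols] / (0.31 * ied) + ph[5])) +
               0.6 * outer(sin(2 * pi * (yg[rows] + 1.7 * dy) / (0.41 * ied) + ph[6]),
                           cos(2 * pi * xg[cols] / (0.17 * ied) + ph[4]))
        win_r <- exp(-(yg[rows] - cy)^2 / (2 * (0.35 * ied)^2))
        win_c <- exp(-(xg[cols] - cx)^2 / (2 * (0.28 * ied)^2))
        img[rows, cols] <- img[rows, cols] +
          0.14 * tex * outer(win_r, win_c)
      }
    }
    pmin(pmax(img, 0), 1)
  }
  frame_source(get, n_frames(seq), W, H)
}

#' Materialize a frame source into an in-memory array source
#'
#' Rendering lazily re-renders a frame on every access; marker extraction
#' touches each frame several times (one pass per region), so materializing
#' once is faster when memory allows.
#'
#' @param src a [frame_source()].
#' @return a [frame_source()] backed by an `H x W x T` array.
#' @export
materialize_frames <- function(src) {
  arr <- array(0, c(src$height, src$width, src$n_frames))
  for (t in seq_len(src$n_frames)) arr[, , t] <- src$get(t - 1L)
  frame_source_array(arr)
}

#' Simulate a full cohort
#'
#' Controls receive severity 0; patients draw severity from the configured
#' distribution. Covariates derive linearly from severity (clinical scores
#' increase, binding ratios decrease) with additive noise, mirroring the
#' demographic/clinical structure of a de-novo PD cohort. Deterministic per
#' seed, with documented per-subject substream seeds.
#'
#' @param config a [synth_config()].
#' @param compute_markers logical: also extract the marker table (renders
#'   frames for the surface markers when `config$render` is `TRUE`).
#' @param progress logical: print per-subject progress.
#' @return list with `cohort` (metadata `data.frame`), `truth`
#'   (ground-truth `data.frame`), `sequences` (named list of
#'   `landmark_sequence`), `markers` (marker table `data.frame` or `NULL`),
#'   and `config`.
#' @export
simulate_cohort <- function(config, compute_markers = TRUE, progress = FALSE) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_controls + config$n_patients
  grp <- c(rep("HC", config$n_controls), rep("PD", config$n_patients))
  sev <- c(rep(0, config$n_controls), config$severity_dist(config$n_patients))
  sev <- pmin(pmax(sev, 0), 1)
  age <- round(pmin(pmax(rnorm(n, 61, 11), 34), 86))
  sex <- ifelse(runif(n) < 0.6, "M", "F")
  ids <- sprintf("S%03d", seq_len(n))
  pd <- grp == "PD"
  cov_noise <- function(s) rnorm(n, 0, s)
  cohort <- data.frame(
    subject_id = ids, group = grp, age = age, sex = sex,
    mds_updrs_iii = ifelse(pd, round(pmax(3, 12 + 36 * sev + cov_noise(6))), NA),
    brady_rigidity = ifelse(pd, round(pmax(1, 6 + 28 * sev + cov_noise(5))), NA),
    pigd = ifelse(pd, round(pmax(0, 0.4 + 3 * sev + cov_noise(1))), NA),
    moca = ifelse(pd, round(pmin(30, pmax(17, rnorm(n, 25, 3.5)))), NA),
    bdi_ii = ifelse(pd, round(pmin(19, pmax(0, rnorm(n, 8, 4.5)))), NA),
    caudate_sbr = ifelse(pd, round(pmax(1, 3.6 - 1.2 * sev + cov_noise(0.35)), 2), NA),
    putamen_sbr = ifelse(pd, round(pmax(0.8, 2.1 - 1.1 * sev + cov_noise(0.2)), 2), NA),
    perceptual = ifelse(pd,
                        pmin(3, pmax(0, round(3 * sev + cov_noise(0.5)))),
                        pmin(3, pmax(0, round(cov_noise(0.45))))),
    stringsAsFactors = FALSE
  )
  cohort$group <- factor(cohort$group, levels = c("HC", "PD"))
  sequences <- vector("list", n); names(sequences) <- ids
  truths <- vector("list", n)
  vectors <- vector("list", n); names(vectors) <- ids
  for (i in seq_len(n)) {
    sd_i <- subject_seed(config$seed, i)
    rec <- animate_landmarks(config, sev[i], seed = sd_i, subject_id = ids[i])
    sequences[[i]] <- rec$seq
    truths[[i]] <- rec$truth
    if (compute_markers) {
      frames <- NULL
      if (isTRUE(config$render)) {
        frames <- render_frames(rec$seq, rec$truth, config, seed = sd_i)
        # keep rendered frames in memory unless that would be excessive
        if (as.numeric(frames$width) * frames$height * frames$n_frames <= 2e8)
          frames <- materialize_frames(frames)
      }
      vectors[[i]] <- compute_marker_vector(rec$seq, frames)
      if (progress) message(sprintf("  %s (%s, severity %.2f) done",
                                    ids[i], grp[i], sev[i]))
    }
  }
  truth <- data.frame(
    subject_id = ids, severity = sev,
    do.call(rbind, lapply(truths, function(tr)
      as.data.frame(as.list(setNames(tr$effective_amplitudes,
                                     paste0("amp_", names(tr$effective_amplitudes))))))),
    stringsAsFactors = FALSE
  )
  list(cohort = cohort, truth = truth, sequences = sequences,
       markers = if (compute_markers) marker_table(vectors) else NULL,
       ground_truth_detail = truths, config = config)
}
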