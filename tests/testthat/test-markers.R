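# Euclidean and surface marker behaviour: closed-form values, invariances,
# and dispatch/missingness contracts.

test_that("every marker is zero for a perfectly static recording", {
  cfg <- tiny_config()
  rec <- animate_landmarks(cfg, 1, seed = 2)  # severity 1, but weights < 1
  cfg1 <- tiny_config(reduction = c(brow = 1, frown = 1, blink = 1,
                                    smile = 1, speech = 1))
  rec <- animate_landmarks(cfg1, 1, seed = 2)
  src <- materialize_frames(render_frames(rec$seq, rec$truth, cfg1, seed = 2))
  mv <- compute_marker_vector(rec$seq, src)
  expect_true(all(mv$sided == 0))
  expect_true(all(mv$averaged == 0))
})

test_that("sample-SD core agrees with a brute-force two-pass oracle", {
  two_pass_sd <- function(x) {  # independent oracle
    m <- sum(x) / length(x)
    sqrt(sum((x - m)^2) / (length(x) - 1))
  }
  set.seed(42)
  for (n in c(2L, 5L, 100L, 1001L)) {
    x <- rnorm(n) * 10^sample(-3:3, 1L)
    expect_equal(facekin:::sample_sd(x), two_pass_sd(x), tolerance = 1e-12)
  }
})

test_that("normalized distances: closed-form SD and scale/translate invariance", {
  # IED = 1 (landmarks 39, 42); distance series {1, 2, 3} between 8 and 30
  T <- 3L
  co <- array(0, c(T, 68L, 2L))
  co[, 40L, ] <- rep(c(5, 5), each = T)     # landmark 39
  co[, 43L, ] <- rep(c(6, 5), each = T)     # landmark 42 -> IED 1
  co[, 31L, ] <- rep(c(5, 8), each = T)     # nose tip (landmark 30)
  co[, 9L, 1L] <- 5; co[, 9L, 2L] <- 8 + c(1, 2, 3)  # chin at distance 1,2,3
  seq <- landmark_sequence(co, width = 100L, height = 100L)
  expect_equal(normalized_distance_marker(seq, 8L, 30L), 1.0)
  # uniform scaling and translation cancel
  for (k in c(0.25, 3, 17)) {
    co2 <- co * k + 11.5
    seq2 <- landmark_sequence(co2, width = 10000L, height = 10000L)
    expect_equal(normalized_distance_marker(seq2, 8L, 30L), 1.0,
                 tolerance = 1e-12)
  }
  expect_equal(normalized_distance_marker(static_face_seq(), 8L, 30L), 0)
})

test_that("degenerate inner-eye-corner distance is an error", {
  co <- static_face_coords(3L)
  co[2L, 43L, ] <- co[2L, 40L, ]   # landmarks 39 and 42 coincide
  seq <- landmark_sequence(co, width = 200L, height = 200L)
  expect_error(normalized_distance_marker(seq, 8L, 30L), "degenerate")
})

test_that("eyebrow tilt: hand-computed SD, zero when parallel, rotation invariant", {
  make_tilt_seq <- function(angles_deg) {
    T <- length(angles_deg)
    co <- array(0, c(T, 68L, 2L))
    co[, 40L, ] <- rep(c(40, 50), each = T)   # inner corners horizontal
    co[, 43L, ] <- rep(c(60, 50), each = T)
    xs <- seq(-10, 10, length.out = 5L)
    for (t in seq_len(T)) {
      th <- angles_deg[t] * pi / 180
      co[t, 18:22, 1L] <- 30 + xs * cos(th)   # right brow 17..21, y up = -
      co[t, 18:22, 2L] <- 30 - xs * sin(th)
      co[t, 23:27, 1L] <- 70 + xs * cos(th)
      co[t, 23:27, 2L] <- 30 - xs * sin(th)
    }
    landmark_sequence(co, width = 200L, height = 200L)
  }
  expect_equal(eyebrow_tilt_marker(make_tilt_seq(rep(0, 6L)), "R"), 0)
  s <- make_tilt_seq(rep(c(5, 9), 5L))
  expect_equal(eyebrow_tilt_marker(s, "R"), sd(rep(c(5, 9), 5L)),
               tolerance = 1e-9)
  expect_equal(sd(rep(c(5, 9), 5L)), 2.1082, tolerance = 1e-4)
  # rigid per-frame rotation of the whole face changes nothing
  set.seed(6)
  base <- static_face_coords(8L)
  co <- base
  for (t in 1:8) {
    th <- runif(1, -0.4, 0.4)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
    co[t, , ] <- sweep(base[t, , ], 2L, c(100, 76)) %*% t(R) +
      rep(c(100, 76), each = 68L)
  }
  seqr <- landmark_sequence(co, width = 400L, height = 400L)
  expect_equal(eyebrow_tilt_marker(seqr, "L"), 0, tolerance = 1e-9)
  expect_equal(eyebrow_shape_marker(seqr, "L"), 0, tolerance = 1e-9)
  expect_equal(normalized_distance_marker(seqr, 8L, 30L), 0, tolerance = 1e-12)
})

test_that("eyebrow shape: straight, right-isosceles, and two-value SD cases", {
  make_shape_seq <- function(heights) {  # apex height above endpoint midline
    T <- length(heights)
    co <- array(0, c(T, 68L, 2L))
    co[, 40L, ] <- rep(c(40, 50), each = T)
    co[, 43L, ] <- rep(c(60, 50), each = T)
    co[, 18L, ] <- rep(c(20, 30), each = T)  # right brow endpoints 17, 21
    co[, 22L, ] <- rep(c(40, 30), each = T)
    co[, 20L, 1L] <- 30                      # apex (landmark 19) centred
    co[, 20L, 2L] <- 30 - heights
    co[, 19L, ] <- rep(c(25, 30), each = T)
    co[, 21L, ] <- rep(c(35, 30), each = T)
    landmark_sequence(co, width = 200L, height = 200L)
  }
  expect_equal(eyebrow_shape_marker(make_shape_seq(c(0, 0, 0)), "R"), 0)
  # apex height = half the endpoint separation -> 90 degrees each frame
  s90 <- make_shape_seq(c(10, 10))
  expect_equal(facekin:::sample_sd(c(90, 90)), 0)
  expect_equal(eyebrow_shape_marker(s90, "R"), 0)
  # angles {180, 90} across two frames: SD = 45 * sqrt(2) = 63.64
  s <- make_shape_seq(c(0, 10))
  expect_equal(eyebrow_shape_marker(s, "R"), sd(c(180, 90)), tolerance = 1e-9)
  expect_equal(sd(c(180, 90)), 63.6396, tolerance = 1e-4)
})

test_that("palpebral aperture: shoelace area and blink-amplitude linearity", {
  # degenerate 6-point unit square -> area 1 before normalization
  sq <- rbind(c(0, 0), c(0.5, 0), c(1, 0), c(1, 1), c(0.5, 1), c(0, 1))
  expect_equal(abs(facekin:::shoelace_area(sq)), 1.0)
  # blink train of amplitude a doubles the aperture SD vs amplitude a/2
  mk <- function(depth) {
    cfg <- tiny_config(duration = 8,
                       amplitudes = c(brow = 0, frown = 0, blink = depth,
                                      aperture = 0, smile = 0, jaw = 0,
                                      upper_lip = 0, lower_lip = 0, corner = 0))
    rec <- animate_landmarks(cfg, 0, seed = 31)
    palpebral_aperture_marker(rec$seq, "L")
  }
  expect_equal(mk(0.8) / mk(0.4), 2.0, tolerance = 1e-9)
  expect_equal(palpebral_aperture_marker(static_face_seq(), "L"), 0)
})

test_that("surface markers respond to texture dynamics and vanish when static", {
  cfg <- tiny_config(duration = 8, width = 200L, height = 150L, seed = 3)
  rec <- animate_landmarks(cfg, 0, seed = 3)
  src_on <- materialize_frames(render_frames(rec$seq, rec$truth, cfg, seed = 3))
  segs <- gated_segments(rec$seq)
  fl_on <- entropy_line_marker(src_on, segs, "forehead")
  # same landmarks, wrinkle modulation off
  cfg_off <- cfg; cfg_off$wrinkle_contrast <- 0
  src_off <- materialize_frames(render_frames(rec$seq, rec$truth, cfg_off,
                                              seed = 3))
  fl_off <- entropy_line_marker(src_off, segs, "forehead")
  expect_gt(fl_on, fl_off)
  # constant frames -> all surface markers zero
  const <- frame_source(function(t) matrix(0.5, 150L, 200L),
                        n_frames(rec$seq), 200L, 150L)
  expect_equal(entropy_line_marker(const, segs, "forehead"), 0)
  expect_equal(cheek_surface_marker(const, segs, "R"), 0)
})

test_that("cheek marker: alternating frames give a constant pair series", {
  seq <- static_face_seq(T = 6L, width = 200L, height = 200L, ied = 30)
  set.seed(12)
  A <- matrix(runif(200 * 200), 200L)
  B <- matrix(runif(200 * 200), 200L)
  alt <- frame_source(function(t) if (t %% 2 == 0) A else B, 6L, 200L, 200L)
  expect_equal(cheek_surface_marker(alt, gated_segments(seq), "L"), 0,
               tolerance = 1e-12)
})

test_that("cheek-raise amplitude increases the cheek surface marker", {
  mk <- function(sm) {
    cfg <- tiny_config(duration = 8, width = 200L, height = 150L,
                       amplitudes = c(brow = 0, frown = 0, blink = 0,
                                      aperture = 0, smile = sm, jaw = 0,
                                      upper_lip = 0, lower_lip = 0,
                                      corner = 0), seed = 13)
    rec <- animate_landmarks(cfg, 0, seed = 13)
    src <- materialize_frames(render_frames(rec$seq, rec$truth, cfg, seed = 13))
    cheek_surface_marker(src, gated_segments(rec$seq), "R")
  }
  expect_gt(mk(0.25), mk(0.12))
})

test_that("marker dispatch: frames optional, missing propagates as NA", {
  cfg <- tiny_config(duration = 5)
  rec <- animate_landmarks(cfg, 0.2, seed = 8)
  mv <- compute_marker_vector(rec$seq)   # no frames
  surface <- c("forehead_lines", "nose_root_lines", "lateral_canthal_lines",
               "cheek_surface")
  expect_true(all(is.na(mv$averaged[surface])))
  expect_equal(sum(!is.na(mv$averaged)), 8L)
  src <- materialize_frames(render_frames(rec$seq, rec$truth, cfg, seed = 8))
  mv2 <- compute_marker_vector(rec$seq, src)
  expect_equal(sum(!is.na(mv2$sided)), 19L)
  expect_equal(mv2$n_frames_used, n_frames(rec$seq))
  # bilateral averages are (L+R)/2
  expect_equal(mv2$averaged[["eyebrow_tilt"]],
               mean(mv2$sided[c("eyebrow_tilt_L", "eyebrow_tilt_R")]))
})

test_that("markers are unchanged when identical content is split into segments", {
  cfg <- tiny_config(duration = 6)
  rec <- animate_landmarks(cfg, 0, seed = 17)
  whole <- rec$seq
  T <- n_frames(whole)
  half <- T %/% 2L
  seg1 <- landmark_sequence(whole$coords[1:half, , , drop = FALSE],
                            width = whole$width, height = whole$height)
  seg2 <- landmark_sequence(whole$coords[(half + 1L):T, , , drop = FALSE],
                            width = whole$width, height = whole$height)
  m_whole <- normalized_distance_marker(whole, 8L, 30L)
  m_split <- normalized_distance_marker(list(seg1, seg2), 8L, 30L)
  expect_equal(m_split, m_whole, tolerance = 1e-12)
})
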