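test_that("landmark files round-trip losslessly, including validity", {
  set.seed(11)
  co <- array(runif(7 * 68 * 2, 0, 199), c(7L, 68L, 2L))
  valid <- matrix(TRUE, 7L, 68L)
  valid[2L, 31L] <- FALSE        # landmark 30 (0-based) missing in frame 1
  valid[5L, c(1L, 68L)] <- FALSE # first and last landmark missing
  seq <- landmark_sequence(co, fps = 25, subject_id = "rt", valid = valid,
                           width = 200L, height = 200L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmark_series(seq, f)
  back <- read_landmark_series(f)
  expect_identical(back$valid, seq$valid)
  # bit-exact coordinates wherever valid
  expect_identical(back$coords[, , 1L][back$valid], seq$coords[, , 1L][seq$valid])
  expect_identical(back$coords[, , 2L][back$valid], seq$coords[, , 2L][seq$valid])
  expect_equal(back$fps, 25)
  expect_equal(back$subject_id, "rt")
  expect_equal(back$width, 200L)
})

test_that("missing fields mark the landmark invalid, others stay valid", {
  co <- static_face_coords(3L)
  seq <- landmark_sequence(co, width = 200L, height = 200L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmark_series(seq, f)
  lines <- readLines(f)
  hdr <- grepl("^#|^frame", lines)
  row2 <- strsplit(lines[!hdr][2L], ",", fixed = TRUE)[[1L]]
  row2[2L + 2L * 30L] <- ""; row2[3L + 2L * 30L] <- ""  # blank landmark 30
  lines[!hdr][2L] <- paste(row2, collapse = ",")
  writeLines(lines, f)
  back <- read_landmark_series(f)
  expect_false(back$valid[2L, 31L])
  expect_equal(sum(!back$valid), 1L)
})

test_that("malformed rows and bad fps are rejected", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0,1,2,3", "1,4,5,6"), f)
  expect_error(read_landmark_series(f), "malformed")
  seq <- static_face_seq()
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_landmark_series(seq, f2)
  expect_error(read_landmark_series(f2, fps = 0), "fps")
})

test_that("gap gating follows the one-second rule independent of fps", {
  T <- 500L
  co <- static_face_coords(T)
  for (fps in c(25, 50)) {
    gap_frames <- round(0.8 * fps)
    v <- matrix(TRUE, T, 68L); v[101:(100 + gap_frames), 6L] <- FALSE
    s <- landmark_sequence(co, fps = fps, valid = v, width = 200, height = 200)
    g <- gate_gaps(s)
    expect_length(g, 1L)
    expect_equal(g[[1L]]$start, 0L)
    expect_equal(g[[1L]]$end, T)
    expect_equal(g[[1L]]$interpolated, 100:(99 + gap_frames))
    # a gap of the same frame count is excluded once it exceeds one second
    long_frames <- round(1.2 * fps)
    v2 <- matrix(TRUE, T, 68L); v2[101:(100 + long_frames), 6L] <- FALSE
    s2 <- landmark_sequence(co, fps = fps, valid = v2, width = 200, height = 200)
    g2 <- gate_gaps(s2)
    expect_length(g2, 2L)
    expect_equal(g2[[1L]], list(start = 0L, end = 100L, interpolated = integer()))
    expect_equal(g2[[2L]],
                 list(start = 100L + long_frames, end = T,
                      interpolated = integer()))
  }
})

test_that("gating degenerate cases: fully valid, fully invalid, edge gaps", {
  s <- static_face_seq(T = 50L)
  g <- gate_gaps(s)
  expect_equal(g, list(list(start = 0L, end = 50L, interpolated = integer())))
  v <- matrix(FALSE, 50L, 68L)
  s2 <- landmark_sequence(static_face_coords(50L), valid = v,
                          width = 200, height = 200)
  expect_equal(gate_gaps(s2), list())
  # a short gap at the recording start has no left neighbour: excluded
  v3 <- matrix(TRUE, 50L, 68L); v3[1:5, 1L] <- FALSE
  s3 <- landmark_sequence(static_face_coords(50L), valid = v3,
                          width = 200, height = 200)
  g3 <- gate_gaps(s3)
  expect_equal(g3[[1L]]$start, 5L)
})

test_that("segment interpolation is linear and matches a per-landmark oracle", {
  T <- 9L
  co <- static_face_coords(T)
  co[, 31L, 1L] <- seq(0, 80, by = 10)  # landmark 30 moves linearly
  co[, 31L, 2L] <- seq(40, 120, by = 10)
  v <- matrix(TRUE, T, 68L)
  v[2L, 31L] <- FALSE; v[c(5L, 7L), 12L] <- FALSE  # two separate gaps
  set.seed(3)
  co[, 12L, 1L] <- cumsum(runif(T, 0, 5)) + 10
  seq <- landmark_sequence(co, valid = v, width = 200, height = 200)
  segs <- gate_gaps(seq)
  expect_length(segs, 1L)
  out <- interpolate_segment(seq, segs[[1L]])
  # oracle: 1-D linear interpolation per landmark and coordinate
  for (j in c(31L, 12L)) for (d in 1:2) {
    ok <- v[, j]
    oracle <- approx(which(ok), co[ok, j, d], xout = seq_len(T))$y
    expect_equal(out$coords[, j, d], oracle, tolerance = 1e-12)
  }
  # a midpoint gap is the exact mean of its neighbours
  expect_equal(out$coords[2L, 31L, ],
               (co[1L, 31L, ] + co[3L, 31L, ]) / 2, tolerance = 1e-12)
  # no invalid frames: identity
  s0 <- static_face_seq(T = 4L)
  out0 <- interpolate_segment(s0, gate_gaps(s0)[[1L]])
  expect_identical(out0$coords, s0$coords)
})

test_that("gated segments partition the recording without overlap", {
  set.seed(21)
  T <- 400L
  v <- matrix(TRUE, T, 68L)
  for (st in c(30L, 90L, 200L, 390L)) {
    len <- sample(c(5L, 40L), 1L)
    v[st:min(T, st + len - 1L), sample(68L, 3L)] <- FALSE
  }
  s <- landmark_sequence(static_face_coords(T), valid = v,
                         width = 200, height = 200)
  g <- gate_gaps(s)
  spans <- do.call(rbind, lapply(g, function(x) c(x$start, x$end)))
  expect_true(all(diff(spans[, 1L]) > 0))          # ordered
  if (nrow(spans) > 1L)
    expect_true(all(spans[-nrow(spans), 2L] <= spans[-1L, 1L]))  # disjoint
  bad <- rowSums(!v) > 0L
  retained <- unlist(lapply(g, function(x) setdiff(x$start:(x$end - 1L),
                                                   x$interpolated)))
  expect_true(all(!bad[retained + 1L]))            # retained frames are valid
})

test_that("cohort tables read back with group factor and validation", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,group,age,sex,perceptual",
               "a,PD,60,M,2", "b,HC,58,F,0"), f)
  tab <- read_cohort_table(f)
  expect_s3_class(tab$group, "factor")
  expect_equal(levels(tab$group), c("HC", "PD"))
  writeLines(c("subject_id,group,perceptual", "a,PD,7"), f)
  expect_error(read_cohort_table(f), "perceptual")
})
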