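# In-code fixtures: tiny landmark sequences and synthetic configs used across
# the test files. All randomness is seeded at the call site.

# a face with valid static geometry: template scaled to pixels
static_face_coords <- function(T = 5L, width = 200L, height = 200L,
                               ied = 30) {
  base <- facekin:::face_template() * ied
  ctr <- c(width / 2, height * 0.38)
  co <- array(0, c(T, 68L, 2L))
  co[, , 1L] <- matrix(base[, 1L] + ctr[1L], T, 68L, byrow = TRUE)
  co[, , 2L] <- matrix(base[, 2L] + ctr[2L], T, 68L, byrow = TRUE)
  co
}

static_face_seq <- function(T = 5L, width = 200L, height = 200L, ied = 30,
                            fps = 25) {
  landmark_sequence(static_face_coords(T, width, height, ied), fps = fps,
                    width = width, height = height)
}

# small fast generator configuration (no gaps/jitter unless asked)
tiny_config <- function(..., duration = 6, width = 160L, height = 120L,
                        jitter_sd = 0, head_amp = 0, gap_rate = 0,
                        seed = 1L) {
  synth_config(n_controls = 2L, n_patients = 2L, duration = duration,
               width = width, height = height, jitter_sd = jitter_sd,
               head_amp = head_amp, gap_rate = gap_rate, seed = seed, ...)
}

# landmark-only cohort markers for n subjects at given severities
quick_marker_table <- function(severities, config, seed_base = 1L) {
  vectors <- list()
  for (i in seq_along(severities)) {
    id <- sprintf("Q%03d", i)
    rec <- animate_landmarks(config, severities[i],
                             seed = facekin:::subject_seed(seed_base, i),
                             subject_id = id)
    vectors[[id]] <- compute_marker_vector(rec$seq)
  }
  marker_table(vectors)
}
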