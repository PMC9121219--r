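# Test-data builders: random pen streams assembled directly (not through the
# package simulator) for oracle cross-checks, and scaled-down session/cohort
# configurations that keep simulation-heavy tests fast.

# A random pen stream with alternating on-surface strokes and pen-up gaps,
# random-walk positions, jittered timestamps and random pressure/inclination
# traces. Built row-by-row from primitives only.
make_random_stream <- function(seed, n_strokes = 4L, samples_per_stroke = 60L,
                               gap_samples = 10L, step_sd = 0.6,
                               dt = 1 / 180, dt_jitter = 0.1) {
  set.seed(seed)
  rows <- list()
  t <- 0
  x <- runif(1L, 50, 200)
  y <- runif(1L, 50, 130)
  for (s in seq_len(n_strokes)) {
    n <- samples_per_stroke + sample.int(20L, 1L)
    for (i in seq_len(n)) {
      t <- t + dt * (1 + runif(1L, -dt_jitter, dt_jitter))
      x <- x + rnorm(1L, 0, step_sd)
      y <- y + rnorm(1L, 0, step_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        t_s = t, x_mm = x, y_mm = y, pressure = runif(1L, 0.1, 0.9),
        incl_h_deg = 180 + rnorm(1L, 0, 5), incl_v_deg = 60 + rnorm(1L, 0, 4),
        hover_mm = 0)
    }
    if (s < n_strokes) {
      g <- gap_samples + sample.int(5L, 1L)
      for (i in seq_len(g)) {
        t <- t + dt * (1 + runif(1L, -dt_jitter, dt_jitter))
        x <- x + rnorm(1L, 0, step_sd)
        y <- y + rnorm(1L, 0, step_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          t_s = t, x_mm = x, y_mm = y, pressure = 0,
          incl_h_deg = 180 + rnorm(1L, 0, 5),
          incl_v_deg = 60 + rnorm(1L, 0, 4),
          hover_mm = runif(1L, 0.5, 6))
      }
    }
  }
  pen_stream(do.call(rbind, rows))
}

# A single-stroke random walk with small steps, designed to trigger dwell
# detection occasionally.
make_random_walk_stroke <- function(seed, n = 300L, step = 0.05) {
  set.seed(seed)
  df <- data.frame(
    t_s = cumsum(rep(1 / 180, n)),
    x_mm = 100 + cumsum(rnorm(n, 0, step)),
    y_mm = 100 + cumsum(rnorm(n, 0, step)),
    pressure = runif(n, 0.2, 0.8),
    incl_h_deg = 180, incl_v_deg = 60, hover_mm = 0)
  pen_stream(df)
}

# Scaled-down session baselines for simulation-heavy tests: same 25-target
# task and device, but faster nominal drawing so sessions are ~30 s instead
# of ~2 min.
fast_session <- function() session_defaults(speed_base_mm_s = 120)

# Very short sessions (~13 s) for null-calibration loops where the kinematic
# scale is irrelevant by construction.
tiny_session <- function() {
  session_defaults(speed_base_mm_s = 240, pause_ratio_base = 0.2)
}

# Small cohort configs reusing the US-like / Japan-like demographics.
small_us <- function(n) cohort_config_us(n)
small_japan <- function(n) cohort_config_japan(n)

# Generate a feature/metadata record table quickly.
quick_records <- function(n_train, n_test, effect = effect_config(),
                          seed = 1L, session = fast_session()) {
  tr <- generate_cohort(small_us(n_train), effect, seed = seed,
                        session = session, keep_streams = FALSE,
                        extract = TRUE)
  te <- generate_cohort(small_japan(n_test), effect, seed = seed + 1L,
                        session = session, keep_streams = FALSE,
                        extract = TRUE)
  participant_records(tr, te)
}
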