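make_plain_stream <- function(t, x, y, pressure,
                              incl_h = rep(180, length(t)),
                              incl_v = rep(60, length(t))) {
  pen_stream(data.frame(t_s = t, x_mm = x, y_mm = y, pressure = pressure,
                        incl_h_deg = incl_h, incl_v_deg = incl_v,
                        hover_mm = ifelse(pressure > 0, 0, 1)))
}

test_that("stroke segmentation follows the maximal-run definition", {
  n <- 6
  s <- make_plain_stream(t = (0:5) / 180, x = 1:6, y = rep(0, n),
                         pressure = c(0, 1, 1, 0, 1, 0))
  st <- segment_strokes(s)
  expect_equal(st$start, c(2L, 5L))
  expect_equal(st$end, c(3L, 5L))

  all_on <- make_plain_stream((0:5) / 180, 1:6, rep(0, n), rep(0.5, n))
  st2 <- segment_strokes(all_on)
  expect_equal(nrow(st2), 1L)
  expect_equal(c(st2$start, st2$end), c(1L, 6L))

  all_off <- make_plain_stream((0:5) / 180, 1:6, rep(0, n), rep(0, n))
  expect_equal(nrow(segment_strokes(all_off)), 0L)
  expect_error(extract_features(all_off), "no on-surface")
})

test_that("instantaneous speeds match their definition", {
  stationary <- make_plain_stream((0:9) / 180, rep(5, 10), rep(5, 10),
                                  rep(0.5, 10))
  expect_true(all(instantaneous_speeds(stationary) == 0))

  tri <- make_plain_stream(c(0, 0.5), c(0, 3), c(0, 4), c(0.5, 0.5))
  expect_equal(instantaneous_speeds(tri), 10)

  # pairs spanning a pen-up gap are excluded
  gap <- make_plain_stream((0:4) / 180, c(0, 1, 50, 51, 52), rep(0, 5),
                           c(1, 1, 0, 1, 1))
  expect_equal(length(instantaneous_speeds(gap)), 2L)

  s <- make_random_stream(42, n_strokes = 3, samples_per_stroke = 150)
  expect_lt(max(abs(instantaneous_speeds(s) -
                      oracle_speeds(as.data.frame(s),
                                    oracle_segment_strokes(as.data.frame(s))))),
            1e-12)
})

test_that("speed mean/CV follow the sample-SD convention", {
  expect_equal(speed_features(c(5, 5, 5))[["speed_cv"]], 0)
  sf <- speed_features(c(1, 2, 3))
  expect_equal(sf[["speed_mean"]], 2)
  expect_equal(sf[["speed_cv"]], 0.5) # sample SD 1 over mean 2

  base <- speed_features(c(2, 3, 7, 4))
  scaled <- speed_features(3.7 * c(2, 3, 7, 4))
  expect_equal(scaled[["speed_cv"]], base[["speed_cv"]])
  expect_equal(scaled[["speed_mean"]], 3.7 * base[["speed_mean"]])

  expect_error(speed_features(5), "at least 2")
  expect_error(speed_features(c(-1, 1)), "undefined")
})

test_that("pressure MAD is the raw median absolute deviation", {
  n <- 5
  s <- make_plain_stream((0:4) / 180, 1:5, rep(0, n),
                         pressure = c(0.1, 0.2, 0.3, 0.4, 1))
  # median 0.3, abs devs {0.2, 0.1, 0, 0.1, 0.7} -> MAD 0.1
  expect_equal(pressure_mad(s), 0.1)

  const <- make_plain_stream((0:4) / 180, 1:5, rep(0, n), rep(0.5, n))
  expect_equal(pressure_mad(const), 0)
})

test_that("inclination variabilities are plain sample SDs in degrees", {
  s <- make_plain_stream(c(0, 1 / 180), c(0, 1), c(0, 0), c(0.5, 0.5),
                         incl_h = c(10, 20), incl_v = c(60, 60))
  sds <- inclination_sds(s)
  expect_equal(sds[["incl_h_sd"]], sqrt(50))
  expect_equal(sds[["incl_v_sd"]], 0)
  expect_error(inclination_sds(make_plain_stream(0, 1, 1, 0.5)), "at least 2")
})

test_that("pause ratio subtracts dwell time from the drawing denominator", {
  # stroke 1: 2.0 s at 20 mm/s (1 mm steps at 20 Hz), holding still from
  # t = 0.5 to 1.0; 1.0 s pen-up gap; stroke 2: 1.5 s of movement.
  dt <- 0.05
  t1 <- seq(0, 2, by = dt)
  x1 <- cumsum(c(0, ifelse(t1[-1] > 0.5 & t1[-1] <= 1.0, 0, 1)))
  s1 <- data.frame(t_s = t1, x_mm = x1, y_mm = 0, pressure = 0.5,
                   incl_h_deg = 180, incl_v_deg = 60, hover_mm = 0)
  tg <- seq(2 + dt, 3 - dt, by = dt)
  g <- data.frame(t_s = tg, x_mm = max(x1), y_mm = 0, pressure = 0,
                  incl_h_deg = 180, incl_v_deg = 60, hover_mm = 2)
  t2 <- seq(3, 4.5, by = dt)
  s2 <- data.frame(t_s = t2, x_mm = max(x1) + cumsum(rep(1, length(t2))),
                   y_mm = 0, pressure = 0.5, incl_h_deg = 180,
                   incl_v_deg = 60, hover_mm = 0)
  stream <- pen_stream(rbind(s1, g, s2))

  pauses <- detect_pauses(stream)
  expect_equal(sum(pauses$kind == "within_stroke"), 1L)
  expect_equal(sum(pauses$kind == "between_strokes"), 1L)
  expect_equal(pauses$duration_s[pauses$kind == "within_stroke"], 0.5)
  expect_equal(pauses$duration_s[pauses$kind == "between_strokes"], 1.0)
  # (0.5 + 1.0) / (3.5 - 0.5)
  expect_equal(pause_ratio(stream), 0.5)
})

test_that("features are invariant to time shifts and planar isometries", {
  stream <- make_random_stream(7)
  fv <- unclass(extract_features(stream))

  shifted <- as.data.frame(stream)
  shifted$t_s <- shifted$t_s + 123.456
  fv_shift <- unclass(extract_features(pen_stream(shifted)))
  expect_equal(fv_shift, fv, tolerance = 1e-9)

  th <- 0.7
  rot <- as.data.frame(stream)
  x <- rot$x_mm; y <- rot$y_mm
  rot$x_mm <- cos(th) * x - sin(th) * y + 40
  rot$y_mm <- sin(th) * x + cos(th) * y - 15
  fv_rot <- unclass(extract_features(pen_stream(rot)))
  expect_equal(fv_rot, fv, tolerance = 1e-9)
})

test_that("time compression scales mean speed but not its CV", {
  stream <- make_random_stream(8, n_strokes = 2)
  k <- 2.5
  fast <- as.data.frame(stream)
  fast$t_s <- fast$t_s / k
  fv <- extract_features(stream)
  fv_fast <- extract_features(pen_stream(fast))
  expect_equal(fv_fast[["speed_cv"]], fv[["speed_cv"]], tolerance = 1e-9)
  expect_equal(fv_fast[["speed_mean"]], k * fv[["speed_mean"]],
               tolerance = 1e-9)
})

test_that("inserting a stationary dwell never decreases the pause ratio", {
  for (seed in 1:5) {
    stream <- make_random_stream(seed, n_strokes = 2)
    df <- as.data.frame(stream)
    st <- segment_strokes(stream)
    at <- st$start[1] + 10L
    dwell_len <- 40L
    dt <- 1 / 180
    block <- df[rep(at, dwell_len), ]
    block$t_s <- df$t_s[at] + dt * seq_len(dwell_len)
    after <- df[(at + 1):nrow(df), ]
    after$t_s <- after$t_s + dt * dwell_len
    with_dwell <- pen_stream(rbind(df[1:at, ], block, after))
    expect_gte(extract_features(with_dwell)[["pause_ratio"]],
               extract_features(stream)[["pause_ratio"]])
  }
})
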