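test_that("cohort generation is deterministic and validates its inputs", {
  cfg <- cohort_config_us(4)
  a <- generate_cohort(cfg, seed = 7, session = tiny_session())
  b <- generate_cohort(cfg, seed = 7, session = tiny_session())
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$streams, b$streams)
  c <- generate_cohort(cfg, seed = 8, session = tiny_session())
  expect_false(identical(a$streams[[1]], c$streams[[1]]))

  expect_error(cohort_config("x", 0, 80, 5, 0.5, 12, 2, 24, 3), "positive")
  expect_error(cohort_config("x", 5, 80, -1, 0.5, 12, 2, 24, 3),
               "non-negative")
  expect_error(cohort_config("x", 5, 80, 5, 0.5, 12, 2, 24, 3,
                             moca_range = c(10, 35)), "within")
  expect_error(cohort_config("x", 5, 80, 5, 1.5, 12, 2, 24, 3), "prop_female")
})

test_that("generated streams satisfy the physical device contract", {
  cohort <- generate_cohort(cohort_config_japan(3), seed = 3,
                            session = fast_session())
  dev <- device_profile()
  for (s in cohort$streams) {
    on <- s$pressure > 0
    expect_true(all(s$hover_mm[on] == 0))
    expect_true(all(s$pressure[on] > 0))
    expect_true(all(s$pressure[!on] == 0))
    expect_true(all(s$hover_mm[!on] > 0))
    expect_true(all(s$x_mm >= 0 & s$x_mm <= dev$surface_width_mm))
    expect_true(all(s$y_mm >= 0 & s$y_mm <= dev$surface_height_mm))
    # uniform sampling at the device rate
    expect_lt(max(abs(diff(s$t_s) - 1 / 180)), 1e-9)
  }
  md <- cohort$metadata
  expect_true(all(md$age >= 65))
  expect_true(all(md$moca >= 16 & md$moca <= 30))
  expect_true(all(md$sex %in% 0:1))
})

test_that("session plans realize their dwell, gap and speed budgets", {
  plan <- plan_session(seed = 5, v_mean_mm_s = 60, speed_cv = 0.3,
                       pause_ratio_target = 0.4)
  expect_equal(plan$stroke_count, nrow(plan$targets) - 1L)
  stream <- simulate_session(plan, seed = 9)
  fv <- extract_features(stream)
  expect_lt(abs(fv[["pause_ratio"]] - 0.4), 0.04) # within 10% of planned
  expect_lt(abs(fv[["speed_mean"]] - 60) / 60, 0.15)

  # a single planned dwell is enough to produce a positive pause ratio
  plan2 <- plan_session(seed = 6, pause_ratio_target = 0.05, dwell_share = 1)
  fv2 <- extract_features(simulate_session(plan2, seed = 2))
  expect_gt(fv2[["pause_ratio"]], 0)

  # noiseless limit: no dwells, no pen-ups, zero speed noise
  plan3 <- plan_session(seed = 8, speed_cv = 0, pause_ratio_target = 0)
  fv3 <- extract_features(simulate_session(plan3, seed = 4))
  expect_equal(fv3[["pause_ratio"]], 0)
  expect_lt(fv3[["speed_cv"]], 0.05)
})

test_that("zero association strength yields null feature-MoCA correlations", {
  eff0 <- effect_config(strength_scale = 0)
  ch <- generate_cohort(cohort_config_us(1000), eff0, seed = 21,
                        session = tiny_session(), keep_streams = FALSE,
                        extract = TRUE)
  rec <- participant_records(ch)
  tab0 <- feature_moca_table(rec)
  expect_true(all(abs(tab0$r) < 0.1))

  # dose-response: |r| does not decrease as strength_scale rises 0 -> 1
  nonzero <- c("speed_cv", "pressure_mad", "incl_h_sd", "incl_v_sd",
               "pause_ratio")
  tabs <- lapply(c(0.5, 1), function(s) {
    eff <- effect_config(strength_scale = s)
    ch <- generate_cohort(cohort_config_us(1000), eff, seed = 21,
                          session = tiny_session(), keep_streams = FALSE,
                          extract = TRUE)
    feature_moca_table(participant_records(ch))
  })
  for (f in nonzero) {
    r_by_scale <- c(abs(tab0$r[tab0$feature == f]),
                    abs(tabs[[1]]$r[tabs[[1]]$feature == f]),
                    abs(tabs[[2]]$r[tabs[[2]]$feature == f]))
    expect_true(all(diff(r_by_scale) > -0.05))
  }
})

test_that("null partial correlations are centered at zero over replicates", {
  eff0 <- effect_config(strength_scale = 0)
  n <- 60
  rs <- matrix(NA_real_, 50, 6)
  for (k in seq_len(50)) {
    ch <- generate_cohort(cohort_config_japan(n), eff0, seed = 100 + k,
                          session = tiny_session(), keep_streams = FALSE,
                          extract = TRUE)
    rs[k, ] <- feature_moca_table(participant_records(ch))$r
  }
  expect_true(all(abs(colMeans(rs)) < 2 / sqrt(n)))
})

test_that("pen CSV round-trips and rejects malformed files", {
  stream <- make_random_stream(1)
  path <- tempfile(fileext = ".csv")
  write_pen_csv(stream, path)
  back <- read_pen_csv(path)
  for (col in names(stream)) {
    expect_lt(max(abs(stream[[col]] - back[[col]])), 1e-9)
  }

  bad <- as.data.frame(stream)
  bad$t_s <- rev(bad$t_s)
  bad_path <- tempfile(fileext = ".csv")
  utils::write.csv(bad, bad_path, row.names = FALSE)
  expect_error(read_pen_csv(bad_path), "increasing")

  neg <- as.data.frame(stream)
  neg$pressure[1] <- -0.1
  neg_path <- tempfile(fileext = ".csv")
  utils::write.csv(neg, neg_path, row.names = FALSE)
  expect_error(read_pen_csv(neg_path), "negative pressure")

  writeLines(c("a,b,c", "1,2,3"), bad_path)
  expect_error(read_pen_csv(bad_path), "header")
})

test_that("the hand-written 3-row fixture parses with matching values", {
  path <- system.file("extdata", "pen_3row.csv", package = "drawcog")
  s <- read_pen_csv(path)
  expect_equal(nrow(s), 3L)
  expect_equal(s$x_mm, c(10, 10.1, 10.2))
  expect_equal(s$pressure, c(0.5, 0.52, 0))
  expect_equal(s$hover_mm, c(0, 0, 1.5))
})

test_that("streams can be truncated to emulate incomplete sessions", {
  stream <- make_random_stream(2)
  cut <- truncate_stream(stream, 0.5)
  expect_lt(nrow(cut), nrow(stream))
  expect_true(all(cut$t_s - cut$t_s[1] <= 0.5))
  fv <- extract_features(cut)
  expect_true(all(is.finite(unclass(fv))))
})
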