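#' Cohort demographic configuration
#'
#' Describes one study cohort: sample size and the distributions of age, sex,
#' education and MoCA (Montreal Cognitive Assessment, 0-30) scores from which
#' participants are drawn. Two presets mirror the demographics of published
#' US and Japan community-dwelling older-adult samples: the US-like cohort is
#' older (mean 83.4 vs 73.3 years), more educated (16.3 vs 13.8 years) and has
#' a higher proportion of women (71% vs 51%), while both share a mean MoCA of
#' 24.4 (SD 3.2 vs 2.6) with participant scores spanning 16-30.
#'
#' @param name Cohort label.
#' @param n_participants Number of participants to generate.
#' @param age_mean_years,age_sd_years Age distribution (years), truncated at
#'   65-100.
#' @param prop_female Proportion of women; sex is encoded 0/1 with 1 = female.
#' @param edu_mean_years,edu_sd_years Education distribution (years),
#'   truncated at 6-25.
#' @param moca_mean,moca_sd MoCA score distribution before clipping/rounding.
#' @param moca_range Integer pair; generated MoCA scores are clipped to this
#'   range (within 0-30) and rounded to integers.
#'
#' @return An object of class `cohort_config`.
#' @examples
#' cohort_config_us(n_participants = 10)
#' @export
cohort_config <- function(name,
                          n_participants,
                          age_mean_years, age_sd_years,
                          prop_female,
                          edu_mean_years, edu_sd_years,
                          moca_mean, moca_sd,
                          moca_range = c(16L, 30L)) {
  n_participants <- as.integer(n_participants)
  if (is.na(n_participants) || n_participants < 1L) {
    stop("n_participants must be a positive integer", call. = FALSE)
  }
  if (age_sd_years < 0 || edu_sd_years < 0 || moca_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (prop_female < 0 || prop_female > 1) {
    stop("prop_female must lie in [0, 1]", call. = FALSE)
  }
  moca_range <- as.integer(moca_range)
  if (length(moca_range) != 2L || moca_range[1L] > moca_range[2L] ||
      moca_range[1L] < 0L || moca_range[2L] > 30L) {
    stop("moca_range must be an ordered pair within [0, 30]", call. = FALSE)
  }
  structure(
    list(name = name, n_participants = n_participants,
         age_mean_years = age_mean_years, age_sd_years = age_sd_years,
         prop_female = prop_female,
         edu_mean_years = edu_mean_years, edu_sd_years = edu_sd_years,
         moca_mean = moca_mean, moca_sd = moca_sd, moca_range = moca_range),
    class = "cohort_config")
}

#' @rdname cohort_config
#' @export
cohort_config_us <- function(n_participants = 55L) {
  cohort_config("US-like", n_participants,
                age_mean_years = 83.4, age_sd_years = 6.9,
                prop_female = 0.71,
                edu_mean_years = 16.3, edu_sd_years = 2.3,
                moca_mean = 24.4, moca_sd = 3.2)
}

#' @rdname cohort_config
#' @export
cohort_config_japan <- function(n_participants = 37L) {
  cohort_config("Japan-like", n_participants,
                age_mean_years = 73.3, age_sd_years = 4.5,
                prop_female = 0.51,
                edu_mean_years = 13.8, edu_sd_years = 2.0,
                moca_mean = 24.4, moca_sd = 2.6)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %s: n=%d, age %.1f (%.1f), %.0f%% female, edu %.1f (%.1f), MoCA %.1f (%.1f)\n",
    x$name, x$n_participants, x$age_mean_years, x$age_sd_years,
    100 * x$prop_female, x$edu_mean_years, x$edu_sd_years,
    x$moca_mean, x$moca_sd))
  invisible(x)
}

#' Cognition-to-kinematics effect configuration
#'
#' Controls how strongly each drawing feature's generating parameter is tied
#' to the standardized latent cognition (MoCA) score. `assoc` holds the
#' target partial correlation between each feature and MoCA at
#' `strength_scale = 1`; defaults are calibrated to the correlation pattern
#' reported for drawing features versus MoCA in older adults (speed
#' variability, pause ratio and pressure variability negative; inclination
#' variabilities positive; mean speed null). Internally each generating
#' parameter follows a lognormal link: `log(param) = log(base) + b * z + e`
#' with `z` the standardized MoCA score, `e ~ N(0, noise_sd^2)` participant
#' heterogeneity, and slope `b = noise_sd * r / sqrt(1 - r^2)` chosen so that
#' the population correlation between `log(param)` and `z` equals the
#' configured `r`. `strength_scale` multiplies all configured correlations
#' (0 disables every association).
#'
#' @param assoc Named numeric vector of target correlations for
#'   `speed_mean`, `speed_cv`, `pressure_mad`, `incl_h_sd`, `incl_v_sd` and
#'   `pause_ratio`.
#' @param noise_sd Log-scale SD of participant-level heterogeneity in each
#'   generating parameter.
#' @param strength_scale Global multiplier on all associations.
#' @param age_confound Optional confounding strength: when positive, age
#'   lowers both the MoCA score and the mean drawing speed directly, so that
#'   plain and covariate-adjusted correlations diverge.
#'
#' @return An object of class `effect_config`.
#' @export
effect_config <- function(assoc = c(speed_mean = 0, speed_cv = -0.42,
                                    pressure_mad = -0.34, incl_h_sd = 0.33,
                                    incl_v_sd = 0.17, pause_ratio = -0.49),
                          noise_sd = 0.25,
                          strength_scale = 1,
                          age_confound = 0) {
  nm <- drawing_feature_names()
  if (!all(nm %in% names(assoc))) {
    stop("assoc must name all six features: ", paste(nm, collapse = ", "),
         call. = FALSE)
  }
  assoc <- assoc[nm]
  if (any(abs(assoc * strength_scale) >= 1)) {
    stop("scaled associations must have absolute value < 1", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(assoc = assoc, noise_sd = noise_sd,
                 strength_scale = strength_scale,
                 age_confound = age_confound),
            class = "effect_config")
}

#' Session kinematic baselines
#'
#' Baseline generating parameters shared by all participants before the
#' cognition link and participant heterogeneity are applied. The defaults
#' yield sessions of roughly two minutes at 180 Hz — about 87 s of drawing
#' movement at 30 mm/s over 24 strokes plus a ~38% pause budget — matching
#' the session durations reported for the trail-making drawing task in older
#' adults. `min_spacing_mm` and `margin_mm` control the target layout; see
#' [plan_session()].
#'
#' @param speed_base_mm_s Baseline mean drawing speed (mm/s).
#' @param speed_cv_base Baseline within-stroke speed coefficient of variation.
#' @param pause_ratio_base Baseline pause:drawing duration ratio.
#' @param dwell_share Fraction of pause time spent in within-stroke dwells.
#' @param n_dwells Maximum dwell events per session.
#' @param pressure_disp_base Baseline marginal SD of pressure fluctuations
#'   (normalized pressure units).
#' @param incl_h_disp_base,incl_v_disp_base Baseline marginal SDs of the
#'   horizontal and vertical inclination fluctuations (degrees).
#' @param n_targets,margin_mm,min_spacing_mm Target layout; see
#'   [plan_session()].
#' @return A list of class `session_defaults`.
#' @export
session_defaults <- function(speed_base_mm_s = 30,
                             speed_cv_base = 0.45,
                             pause_ratio_base = 0.38,
                             dwell_share = 0.18,
                             n_dwells = 6L,
                             pressure_disp_base = 0.04,
                             incl_h_disp_base = 4,
                             incl_v_disp_base = 3,
                             n_targets = 25L,
                             margin_mm = 10,
                             min_spacing_mm = 20) {
  structure(list(speed_base_mm_s = speed_base_mm_s,
                 speed_cv_base = speed_cv_base,
                 pause_ratio_base = pause_ratio_base,
                 dwell_share = dwell_share,
                 n_dwells = as.integer(n_dwells),
                 pressure_disp_base = pressure_disp_base,
                 incl_h_disp_base = incl_h_disp_base,
                 incl_v_disp_base = incl_v_disp_base,
                 n_targets = as.integer(n_targets),
                 margin_mm = margin_mm,
                 min_spacing_mm = min_spacing_mm),
            class = "session_defaults")
}

# One-row data frame from a drawing_features vector.
features_row <- function(fv) {
  as.data.frame(as.list(unclass(fv)))
}

# Slope of the log-link such that cor(log(param), z) equals r when the
# participant noise SD is tau. With tau = 0 the link is deterministic and the
# slope falls back to r itself (sign and monotonicity preserved).
effect_slopes <- function(effect) {
  r <- effect$assoc * effect$strength_scale
  tau <- effect$noise_sd
  if (tau == 0) return(r)
  tau * r / sqrt(1 - r^2)
}

#' Generate a synthetic cohort of drawing sessions
#'
#' Draws participant demographics from the cohort configuration (age and
#' education truncated to plausible bounds, MoCA clipped to the configured
#' range and rounded to an integer), links each participant's kinematic
#' generating parameters to the standardized MoCA score through the effect
#' configuration's lognormal links, and simulates one raw pen-event session
#' per participant. Identical `(configs, seed)` reproduce identical output.
#'
#' With `effect_cfg$age_confound > 0`, standardized age additionally lowers
#' both the MoCA score and the mean drawing speed directly, creating a
#' demographic confound that covariate adjustment should remove.
#'
#' @param cohort_cfg A [cohort_config()].
#' @param effect_cfg An [effect_config()].
#' @param device A [device_profile()].
#' @param seed Integer seed.
#' @param session A [session_defaults()] list of kinematic baselines.
#' @param keep_streams Keep the raw `pen_stream` objects (may be large); set
#'   `FALSE` to retain only metadata, generating parameters and (optionally)
#'   extracted features.
#' @param extract Also extract the six drawing features per session into a
#'   `features` data frame.
#'
#' @return An object of class `pen_cohort`: a list with `metadata` (one row
#'   per participant: `participant_id`, `cohort`, `age`, `sex`,
#'   `education_years`, `moca`), `streams` (list of [pen_stream()] or `NULL`),
#'   `params` (per-participant generating parameters), and `features` when
#'   `extract = TRUE`.
#' @export
generate_cohort <- function(cohort_cfg,
                            effect_cfg = effect_config(),
                            device = device_profile(),
                            seed = 1L,
                            session = session_defaults(),
                            keep_streams = TRUE,
                            extract = FALSE) {
  stopifnot(inherits(cohort_cfg, "cohort_config"),
            inherits(effect_cfg, "effect_config"))
  n <- cohort_cfg$n_participants
  with_seed(seed, {
    age <- rnorm_trunc(n, cohort_cfg$age_mean_years, cohort_cfg$age_sd_years,
                       65, 100)
    sex <- stats::rbinom(n, 1L, cohort_cfg$prop_female)
    edu <- rnorm_trunc(n, cohort_cfg$edu_mean_years, cohort_cfg$edu_sd_years,
                       6, 25)

    z_age <- if (cohort_cfg$age_sd_years > 0) {
      (age - cohort_cfg$age_mean_years) / cohort_cfg$age_sd_years
    } else rep(0, n)
    conf <- effect_cfg$age_confound

    moca_mu <- cohort_cfg$moca_mean - conf * z_age * cohort_cfg$moca_sd
    moca <- round(pmin(pmax(stats::rnorm(n, moca_mu, cohort_cfg$moca_sd),
                            cohort_cfg$moca_range[1L]),
                       cohort_cfg$moca_range[2L]))
    z <- if (cohort_cfg$moca_sd > 0) {
      (moca - cohort_cfg$moca_mean) / cohort_cfg$moca_sd
    } else rep(0, n)

    b <- effect_slopes(effect_cfg)
    tau <- effect_cfg$noise_sd
    lp <- function(base, slope, extra = 0) {
      base * exp(slope * z + stats::rnorm(n, 0, tau) + extra)
    }
    v_mean <- lp(session$speed_base_mm_s, b[["speed_mean"]],
                 extra = -0.25 * conf * z_age)
    speed_cv <- lp(session$speed_cv_base, b[["speed_cv"]])
    press_disp <- lp(session$pressure_disp_base, b[["pressure_mad"]])
    incl_h_disp <- lp(session$incl_h_disp_base, b[["incl_h_sd"]])
    incl_v_disp <- lp(session$incl_v_disp_base, b[["incl_v_sd"]])
    pause_ratio <- lp(session$pause_ratio_base, b[["pause_ratio"]])

    press_base <- stats::runif(n, 0.4, 0.6)
    incl_h_base <- stats::runif(n, 160, 200)
    incl_v_base <- stats::runif(n, 52, 68)

    seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2L * n), ncol = 2L)

    metadata <- data.frame(
      participant_id = sprintf("%s_%03d", gsub("\\s+", "_", cohort_cfg$name),
                               seq_len(n)),
      cohort = cohort_cfg$name,
      age = age, sex = sex, education_years = edu, moca = as.integer(moca),
      stringsAsFactors = FALSE)

    params <- data.frame(
      participant_id = metadata$participant_id,
      v_mean_mm_s = v_mean, speed_cv = speed_cv,
      pressure_disp = press_disp,
      incl_h_disp = incl_h_disp, incl_v_disp = incl_v_disp,
      pause_ratio_target = pause_ratio,
      stringsAsFactors = FALSE)

    streams <- if (keep_streams) vector("list", n) else NULL
    feats <- if (extract) vector("list", n) else NULL

    for (i in seq_len(n)) {
      plan <- plan_session(
        device = device, seed = seeds[i, 1L],
        v_mean_mm_s = v_mean[i], speed_cv = speed_cv[i],
        pause_ratio_target = pause_ratio[i],
        dwell_share = session$dwell_share, n_dwells = session$n_dwells,
        pressure_base = press_base[i], pressure_disp = press_disp[i],
        incl_h_base = incl_h_base[i], incl_v_base = incl_v_base[i],
        incl_h_disp = incl_h_disp[i], incl_v_disp = incl_v_disp[i],
        n_targets = session$n_targets, margin_mm = session$margin_mm,
        min_spacing_mm = session$min_spacing_mm)
      stream <- simulate_session(plan, device, seed = seeds[i, 2L])
      if (keep_streams) streams[[i]] <- stream
      if (extract) feats[[i]] <- features_row(extract_features(stream))
    }

    out <- list(metadata = metadata, streams = streams, params = params,
                cohort_cfg = cohort_cfg, effect_cfg = effect_cfg,
                device = device, seed = as.integer(seed))
    if (extract) {
      out$features <- cbind(participant_id = metadata$participant_id,
                            do.call(rbind, feats))
      rownames(out$features) <- NULL
    }
    structure(out, class = "pen_cohort")
  })
}

#' @export
print.pen_cohort <- function(x, ...) {
  cat(sprintf("<pen_cohort> %s: %d participants (streams %s)\n",
              x$cohort_cfg$name, nrow(x$metadata),
              if (is.null(x$streams)) "dropped" else "kept"))
  invisible(x)
}

#' Assemble the per-participant analysis table
#'
#' Joins extracted drawing features with demographics and MoCA scores for one
#' or more generated cohorts, producing the record table consumed by the
#' statistical and machine-learning stages.
#'
#' @param ... `pen_cohort` objects generated with `extract = TRUE` (or with
#'   streams kept, in which case features are extracted here).
#' @return A data frame with one row per participant: identifiers,
#'   demographics, MoCA and the six drawing features.
#' @export
participant_records <- function(...) {
  cohorts <- list(...)
  rows <- lapply(cohorts, function(ch) {
    stopifnot(inherits(ch, "pen_cohort"))
    feats <- ch$features
    if (is.null(feats)) {
      if (is.null(ch$streams)) {
        stop("cohort has neither features nor streams", call. = FALSE)
      }
      fl <- lapply(ch$streams, function(s) features_row(extract_features(s)))
      feats <- cbind(participant_id = ch$metadata$participant_id,
                     do.call(rbind, fl))
    }
    merge(ch$metadata, feats, by = "participant_id", sort = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
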