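#' Plan a trail-making-style drawing session
#'
#' Lays out one session of the connect-the-targets drawing task used
#' throughout this package: 25 targets placed on the drawing surface and 24
#' straight connecting strokes, together with the kinematic parameters that
#' the simulator realizes — per-stroke nominal speed, within-stroke speed
#' dispersion, dwell (within-stroke pause) events, pen-up gaps between
#' strokes, and pressure/inclination baselines and dispersions.
#'
#' Targets are placed uniformly at random inside a margin, rejection-sampled
#' to keep a minimum inter-target spacing so no stroke degenerates to zero
#' length. The pause budget is expressed as a target pause:drawing duration
#' ratio: total pause time equals `pause_ratio_target` times the planned
#' drawing (movement) time, split between within-stroke dwells
#' (`dwell_share`) and pen-up gaps (the remainder).
#'
#' @param device A [device_profile()]; bounds the target layout.
#' @param seed Integer seed for the layout and pause placement.
#' @param v_mean_mm_s Nominal pen-tip speed during drawing movements (mm/s).
#' @param speed_cv Planned coefficient of variation of instantaneous drawing
#'   speed (dimensionless, excluding dwell samples).
#' @param pause_ratio_target Planned ratio of total pause time to drawing
#'   (movement) time.
#' @param dwell_share Fraction of the pause budget spent in within-stroke
#'   dwells rather than pen-up gaps.
#' @param n_dwells Maximum number of dwell events in the session.
#' @param min_dwell_s Shortest planned dwell (s); keeps dwells well above the
#'   100 ms detection threshold.
#' @param pressure_base Baseline normalized pressure while drawing.
#' @param pressure_disp Marginal SD of the pressure fluctuation process.
#' @param incl_h_base,incl_v_base Baseline pen inclinations (degrees).
#' @param incl_h_disp,incl_v_disp Marginal SDs of the inclination fluctuation
#'   processes (degrees).
#' @param n_targets Number of targets (25 for the standard task).
#' @param margin_mm Margin between targets and the surface edge (mm).
#' @param min_spacing_mm Minimum inter-target distance (mm).
#'
#' @return An object of class `session_plan`.
#' @export
plan_session <- function(device = device_profile(),
                         seed = 1L,
                         v_mean_mm_s = 30,
                         speed_cv = 0.45,
                         pause_ratio_target = 0.38,
                         dwell_share = 0.18,
                         n_dwells = 6L,
                         min_dwell_s = 0.3,
                         pressure_base = 0.5,
                         pressure_disp = 0.04,
                         incl_h_base = 180,
                         incl_v_base = 60,
                         incl_h_disp = 4,
                         incl_v_disp = 3,
                         n_targets = 25L,
                         margin_mm = 10,
                         min_spacing_mm = 20) {
  stopifnot(v_mean_mm_s > 0, speed_cv >= 0, pause_ratio_target >= 0,
            dwell_share >= 0, dwell_share <= 1, n_targets >= 2L,
            pressure_base > 0, pressure_base <= 1,
            pressure_disp >= 0, incl_h_disp >= 0, incl_v_disp >= 0)
  with_seed(seed, {
    targets <- sample_targets(n_targets, device, margin_mm, min_spacing_mm)
    n_strokes <- n_targets - 1L
    d <- sqrt(rowSums((targets[-1L, , drop = FALSE] -
                         targets[-n_targets, , drop = FALSE])^2))
    stroke_speeds <- rep(v_mean_mm_s, n_strokes)
    draw_time_s <- sum(d / stroke_speeds)

    pause_total <- pause_ratio_target * draw_time_s
    dwell_total <- pause_total * dwell_share
    gap_total <- pause_total - dwell_total

    dwells <- plan_dwells(dwell_total, n_dwells, min_dwell_s, n_strokes)

    n_gaps <- n_strokes - 1L
    if (gap_total > 0 && n_gaps > 0L) {
      w <- exp(stats::rnorm(n_gaps, 0, 0.3))
      gap_durations <- gap_total * w / sum(w)
    } else {
      gap_durations <- rep(0, max(n_gaps, 0L))
    }
    gap_hover_mm <- stats::runif(max(n_gaps, 0L), 2, 8)

    structure(
      list(targets = targets,
           stroke_count = n_strokes,
           stroke_speeds = stroke_speeds,
           speed_cv = speed_cv,
           dwells = dwells,
           gap_durations = gap_durations,
           gap_hover_mm = gap_hover_mm,
           pressure_base = pressure_base,
           pressure_disp = pressure_disp,
           incl_h_base = incl_h_base,
           incl_v_base = incl_v_base,
           incl_h_disp = incl_h_disp,
           incl_v_disp = incl_v_disp,
           draw_time_s = draw_time_s,
           dwell_total_s = sum(dwells$duration_s),
           gap_total_s = sum(gap_durations)),
      class = "session_plan")
  })
}

sample_targets <- function(n, device, margin, min_spacing, max_tries = 20000L) {
  lo_x <- margin; hi_x <- device$surface_width_mm - margin
  lo_y <- margin; hi_y <- device$surface_height_mm - margin
  if (hi_x <= lo_x || hi_y <= lo_y) {
    stop("margin leaves no drawing area", call. = FALSE)
  }
  pts <- matrix(NA_real_, n, 2L)
  k <- 0L
  for (i in seq_len(max_tries)) {
    cand <- c(stats::runif(1L, lo_x, hi_x), stats::runif(1L, lo_y, hi_y))
    if (k == 0L ||
        min(sqrt((pts[seq_len(k), 1L] - cand[1L])^2 +
                 (pts[seq_len(k), 2L] - cand[2L])^2)) >= min_spacing) {
      k <- k + 1L
      pts[k, ] <- cand
      if (k == n) break
    }
  }
  if (k < n) {
    stop("could not place targets with the requested spacing; ",
         "reduce min_spacing_mm or enlarge the surface", call. = FALSE)
  }
  colnames(pts) <- c("x_mm", "y_mm")
  pts
}

plan_dwells <- function(dwell_total, n_dwells, min_dwell, n_strokes) {
  if (dwell_total <= 0 || n_dwells < 1L) {
    return(data.frame(stroke = integer(), at_frac = numeric(),
                      duration_s = numeric()))
  }
  k <- max(1L, min(as.integer(n_dwells), floor(dwell_total / min_dwell)))
  w <- exp(stats::rnorm(k, 0, 0.4))
  extra <- max(dwell_total - k * min(min_dwell, dwell_total / k), 0)
  base <- min(min_dwell, dwell_total / k)
  durations <- base + extra * w / sum(w)
  data.frame(stroke = sample.int(n_strokes, k, replace = TRUE),
             at_frac = stats::runif(k, 0.15, 0.85),
             duration_s = durations)
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf(paste0(
    "<session_plan> %d targets, %d strokes, %.1f s drawing, ",
    "%d dwells (%.1f s), %.1f s pen-up\n"),
    nrow(x$targets), x$stroke_count, x$draw_time_s,
    nrow(x$dwells), x$dwell_total_s, x$gap_total_s))
  invisible(x)
}

validate_session_plan <- function(plan, device) {
  stopifnot(inherits(plan, "session_plan"))
  tg <- plan$targets
  if (plan$stroke_count != nrow(tg) - 1L) {
    stop("stroke_count must equal target count - 1", call. = FALSE)
  }
  if (any(tg[, 1L] < 0) || any(tg[, 1L] > device$surface_width_mm) ||
      any(tg[, 2L] < 0) || any(tg[, 2L] > device$surface_height_mm)) {
    stop("targets outside the device bounding box", call. = FALSE)
  }
  if (any(plan$dwells$duration_s < 0) || any(plan$gap_durations < 0)) {
    stop("dwell and gap durations must be non-negative", call. = FALSE)
  }
  total <- plan$draw_time_s + sum(plan$dwells$duration_s) +
    sum(plan$gap_durations)
  if (sum(plan$dwells$duration_s) > total || sum(plan$gap_durations) > total) {
    stop("pause durations exceed the planned session length", call. = FALSE)
  }
  invisible(plan)
}

#' Simulate the raw pen-event stream for a planned session
#'
#' Realizes a [plan_session()] as a pen-event time series sampled at the
#' device rate. Strokes traverse consecutive targets along straight paths;
#' per-sample step lengths carry multiplicative lognormal noise whose
#' dispersion realizes the planned speed coefficient of variation. Planned
#' dwell events hold the pen exactly stationary on-surface for their planned
#' duration; pen-up gaps emit samples with zero pressure and a positive
#' hover-distance arc. Pressure and the two inclinations fluctuate around
#' their baselines as smooth AR(1) processes with the planned marginal
#' dispersions; on-surface pressure is clipped away from zero and quantized
#' to the device's discrete pressure levels.
#'
#' @param plan A [plan_session()].
#' @param device A [device_profile()].
#' @param seed Integer seed; identical (plan, device, seed) give bit-identical
#'   streams.
#' @return A [pen_stream()].
#' @export
simulate_session <- function(plan, device = device_profile(), seed = 1L) {
  validate_session_plan(plan, device)
  with_seed(seed, {
    rate <- device$sampling_rate_hz
    nseg <- plan$stroke_count
    tg <- plan$targets
    sig <- sqrt(log(1 + plan$speed_cv^2))

    xs <- vector("list", 2L * nseg)
    ys <- vector("list", 2L * nseg)
    on <- vector("list", 2L * nseg)
    hv <- vector("list", 2L * nseg)

    for (j in seq_len(nseg)) {
      a <- tg[j, ]; b <- tg[j + 1L, ]
      d <- sqrt(sum((b - a)^2))
      v <- plan$stroke_speeds[j]
      n <- max(2L, as.integer(round(d / v * rate)))
      m <- if (sig > 0) exp(stats::rnorm(n, -sig^2 / 2, sig)) else rep(1, n)
      frac <- cumsum(m) / sum(m)
      x <- c(a[1L], a[1L] + frac * (b[1L] - a[1L]))
      y <- c(a[2L], a[2L] + frac * (b[2L] - a[2L]))

      dw <- plan$dwells[plan$dwells$stroke == j, , drop = FALSE]
      if (nrow(dw) > 0L) {
        dw <- dw[order(dw$at_frac, decreasing = TRUE), , drop = FALSE]
        for (q in seq_len(nrow(dw))) {
          n_dw <- as.integer(round(dw$duration_s[q] * rate))
          if (n_dw < 1L) next
          k <- min(length(x), max(1L, 1L + as.integer(round(dw$at_frac[q] * n))))
          x <- append(x, rep(x[k], n_dw), after = k)
          y <- append(y, rep(y[k], n_dw), after = k)
        }
      }
      xs[[2L * j - 1L]] <- x
      ys[[2L * j - 1L]] <- y
      on[[2L * j - 1L]] <- rep(TRUE, length(x))
      hv[[2L * j - 1L]] <- rep(0, length(x))

      if (j < nseg) {
        g <- as.integer(round(plan$gap_durations[j] * rate))
        if (g > 0L) {
          jx <- b[1L] + stats::rnorm(g, 0, 0.3)
          jy <- b[2L] + stats::rnorm(g, 0, 0.3)
          xs[[2L * j]] <- pmin(pmax(jx, 0), device$surface_width_mm)
          ys[[2L * j]] <- pmin(pmax(jy, 0), device$surface_height_mm)
          on[[2L * j]] <- rep(FALSE, g)
          hv[[2L * j]] <- plan$gap_hover_mm[j] * sin(pi * seq_len(g) / (g + 1L))
        }
      }
    }

    x <- unlist(xs, use.names = FALSE)
    y <- unlist(ys, use.names = FALSE)
    on <- unlist(on, use.names = FALSE)
    hover <- unlist(hv, use.names = FALSE)
    n_all <- length(x)
    t_s <- (seq_len(n_all) - 1L) / rate

    press <- plan$pressure_base + ar1_series(n_all, plan$pressure_disp, 0.9)
    press <- pmin(pmax(press, 0.05), 0.995)
    lev <- device$pressure_levels - 1L
    press <- round(press * lev) / lev
    press[!on] <- 0

    incl_h <- plan$incl_h_base + ar1_series(n_all, plan$incl_h_disp, 0.97)
    incl_v <- plan$incl_v_base + ar1_series(n_all, plan$incl_v_disp, 0.97)

    pen_stream(data.frame(t_s = t_s, x_mm = x, y_mm = y, pressure = press,
                          incl_h_deg = incl_h, incl_v_deg = incl_v,
                          hover_mm = hover),
               device = device, validate = FALSE)
  })
}
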