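#' Names of the six drawing features
#'
#' @return Character vector: `speed_mean` (mm/s), `speed_cv`, `pressure_mad`
#'   (normalized pressure units), `incl_h_sd`, `incl_v_sd` (degrees),
#'   `pause_ratio`.
#' @export
drawing_feature_names <- function() {
  c("speed_mean", "speed_cv", "pressure_mad",
    "incl_h_sd", "incl_v_sd", "pause_ratio")
}

#' Segment a pen stream into strokes
#'
#' A stroke is a maximal contiguous run of on-surface samples, where
#' on-surface means `pressure > 0` (the hover distance is ignored for
#' segmentation; pressure is the direct contact signal).
#'
#' @param stream A [pen_stream()].
#' @return A data frame with one row per stroke: `start`, `end` (inclusive
#'   sample indices), `start_t`, `end_t`, `duration_s`.
#' @examples
#' # pressure pattern 0,1,1,0,1,0 -> strokes (2,3) and (5,5)
#' @export
segment_strokes <- function(stream) {
  if (nrow(stream) == 0L) stop("empty stream", call. = FALSE)
  on <- stream$pressure > 0
  r <- rle(on)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$start_t <- stream$t_s[out$start]
  out$end_t <- stream$t_s[out$end]
  out$duration_s <- out$end_t - out$start_t
  out
}

#' Instantaneous drawing speeds
#'
#' One speed per consecutive on-surface sample pair within a stroke:
#' Euclidean displacement divided by the timestamp difference. Pairs spanning
#' stroke boundaries are excluded and no smoothing is applied. Time steps are
#' taken from the timestamps (not assumed equal to the nominal sampling
#' period), so streams with dropped samples are handled correctly.
#'
#' @param stream A [pen_stream()].
#' @param strokes Output of [segment_strokes()].
#' @return Numeric vector of speeds (mm/s).
#' @export
instantaneous_speeds <- function(stream, strokes = segment_strokes(stream)) {
  if (nrow(strokes) == 0L) stop("no strokes in stream", call. = FALSE)
  n <- nrow(stream)
  stroke_id <- rep(NA_integer_, n)
  for (j in seq_len(nrow(strokes))) {
    stroke_id[strokes$start[j]:strokes$end[j]] <- j
  }
  i1 <- seq_len(n - 1L)
  ok <- !is.na(stroke_id[i1]) & !is.na(stroke_id[i1 + 1L]) &
    stroke_id[i1] == stroke_id[i1 + 1L]
  dt <- stream$t_s[i1 + 1L][ok] - stream$t_s[i1][ok]
  if (any(dt <= 0)) stop("non-positive time step within a stroke", call. = FALSE)
  dx <- stream$x_mm[i1 + 1L][ok] - stream$x_mm[i1][ok]
  dy <- stream$y_mm[i1 + 1L][ok] - stream$y_mm[i1][ok]
  sqrt(dx^2 + dy^2) / dt
}

#' Mean drawing speed and its coefficient of variation
#'
#' The speed variability is expressed as the coefficient of variation (sample
#' SD with denominator n-1 divided by the mean) to remove the influence of
#' the absolute speed, which enters as its own feature.
#'
#' @param speeds Output of [instantaneous_speeds()].
#' @return Named vector `c(speed_mean, speed_cv)`.
#' @export
speed_features <- function(speeds) {
  if (length(speeds) < 2L) stop("need at least 2 speed samples", call. = FALSE)
  m <- mean(speeds)
  s <- stats::sd(speeds)
  if (m == 0) {
    if (s > 0) stop("speed CV undefined: zero mean with nonzero SD",
                    call. = FALSE)
    return(c(speed_mean = 0, speed_cv = 0))
  }
  c(speed_mean = m, speed_cv = s / m)
}

#' Pressure variability (median absolute deviation)
#'
#' The raw median absolute deviation of on-surface pressure samples —
#' `median(|p - median(p)|)` with no consistency constant — chosen for its
#' robustness to pressure outliers.
#'
#' @inheritParams instantaneous_speeds
#' @return Scalar MAD in normalized pressure units.
#' @export
pressure_mad <- function(stream, strokes = segment_strokes(stream)) {
  p <- stream$pressure[stream$pressure > 0]
  if (length(p) == 0L) stop("no on-surface samples", call. = FALSE)
  stats::mad(p, constant = 1)
}

#' Inclination variabilities
#'
#' Sample standard deviations (denominator n-1) of the pen's horizontal and
#' vertical inclinations over on-surface samples, treating the angles as
#' plain linear quantities in degrees.
#'
#' @inheritParams instantaneous_speeds
#' @return Named vector `c(incl_h_sd, incl_v_sd)` in degrees.
#' @export
inclination_sds <- function(stream, strokes = segment_strokes(stream)) {
  on <- stream$pressure > 0
  if (sum(on) < 2L) stop("need at least 2 on-surface samples", call. = FALSE)
  c(incl_h_sd = stats::sd(stream$incl_h_deg[on]),
    incl_v_sd = stats::sd(stream$incl_v_deg[on]))
}

#' Detect pauses within and between strokes
#'
#' Within-stroke pauses are detected with a greedy anchor scan: starting from
#' an anchor sample, the window extends while every sample stays within
#' `radius_mm` of the anchor's position; if the window lasts strictly longer
#' than `min_duration_s` a pause is emitted and the scan restarts after the
#' window, otherwise the anchor advances by one sample. Defaults implement
#' the standard rule for digitizer drawing data: the pen tip remaining inside
#' a 0.25-mm radius on the drawing surface for more than 100 ms. Pauses are
#' non-overlapping by construction. Between-stroke pauses are the pen-up
#' intervals separating consecutive strokes (no minimum duration).
#'
#' @inheritParams instantaneous_speeds
#' @param radius_mm Dwell radius around the anchor sample (mm).
#' @param min_duration_s Strict minimum duration of a within-stroke pause (s).
#' @return Data frame with columns `kind` (`"within_stroke"` or
#'   `"between_strokes"`), `start_t`, `end_t`, `duration_s`.
#' @export
detect_pauses <- function(stream, strokes = segment_strokes(stream),
                          radius_mm = 0.25, min_duration_s = 0.1) {
  if (radius_mm <= 0) stop("radius_mm must be positive", call. = FALSE)
  if (min_duration_s <= 0) stop("min_duration_s must be positive", call. = FALSE)
  if (nrow(strokes) == 0L) stop("no strokes in stream", call. = FALSE)

  within <- vector("list", nrow(strokes))
  for (j in seq_len(nrow(strokes))) {
    idx <- strokes$start[j]:strokes$end[j]
    w <- pause_scan_cpp(stream$x_mm[idx], stream$y_mm[idx], stream$t_s[idx],
                        radius_mm, min_duration_s)
    if (nrow(w) > 0L) {
      within[[j]] <- data.frame(kind = "within_stroke",
                                start_t = w[, 1L], end_t = w[, 2L])
    }
  }
  within <- do.call(rbind, within)

  between <- NULL
  if (nrow(strokes) > 1L) {
    between <- data.frame(
      kind = "between_strokes",
      start_t = strokes$end_t[-nrow(strokes)],
      end_t = strokes$start_t[-1L])
  }
  out <- rbind(within, between)
  if (is.null(out)) {
    out <- data.frame(kind = character(), start_t = numeric(),
                      end_t = numeric())
  }
  out <- out[order(out$start_t), , drop = FALSE]
  out$duration_s <- out$end_t - out$start_t
  rownames(out) <- NULL
  out
}

#' Pause:drawing duration ratio
#'
#' Total pause time (within-stroke dwells plus pen-up gaps between strokes)
#' divided by total drawing-motion time. Dwelling is not drawing motion, so
#' within-stroke pause time is subtracted from the total stroke duration in
#' the denominator.
#'
#' @inheritParams instantaneous_speeds
#' @param pauses Output of [detect_pauses()].
#' @return Scalar ratio (dimensionless).
#' @export
pause_ratio <- function(stream, strokes = segment_strokes(stream),
                        pauses = detect_pauses(stream, strokes)) {
  pause_total <- sum(pauses$duration_s)
  within_total <- sum(pauses$duration_s[pauses$kind == "within_stroke"])
  denom <- sum(strokes$duration_s) - within_total
  if (denom <= 0) stop("total drawing duration must be positive", call. = FALSE)
  pause_total / denom
}

#' Extract the six drawing features from a session
#'
#' Composes stroke segmentation, instantaneous speeds, robust pressure
#' dispersion, inclination variabilities and pause detection into the
#' six-element feature vector used throughout the analysis. Partial or
#' truncated streams are processed as-is.
#'
#' @param stream A [pen_stream()].
#' @param radius_mm,min_duration_s Pause-detection parameters; see
#'   [detect_pauses()].
#' @return Named numeric vector of class `drawing_features` with elements
#'   `speed_mean`, `speed_cv`, `pressure_mad`, `incl_h_sd`, `incl_v_sd`,
#'   `pause_ratio`.
#' @export
extract_features <- function(stream, radius_mm = 0.25, min_duration_s = 0.1) {
  strokes <- segment_strokes(stream)
  if (nrow(strokes) == 0L) stop("stream has no on-surface samples", call. = FALSE)
  speeds <- instantaneous_speeds(stream, strokes)
  sp <- speed_features(speeds)
  pauses <- detect_pauses(stream, strokes, radius_mm, min_duration_s)
  out <- c(sp,
           pressure_mad = pressure_mad(stream, strokes),
           inclination_sds(stream, strokes),
           pause_ratio = pause_ratio(stream, strokes, pauses))
  structure(out[drawing_feature_names()], class = "drawing_features")
}

#' @export
print.drawing_features <- function(x, ...) {
  cat("<drawing_features>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Write or read a features table CSV
#'
#' Columns: `participant_id` followed by the six drawing features.
#'
#' @param features Data frame as produced by
#'   [generate_cohort()]`$features` or [participant_records()].
#' @param path File path.
#' @return `read_features_csv()` returns the data frame; `write_features_csv()`
#'   returns `path` invisibly.
#' @export
write_features_csv <- function(features, path) {
  cols <- c("participant_id", drawing_feature_names())
  stopifnot(all(cols %in% names(features)))
  utils::write.csv(features[cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- c("participant_id", drawing_feature_names())
  if (!all(cols %in% names(df))) {
    stop("features CSV missing required columns", call. = FALSE)
  }
  df[cols]
}
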