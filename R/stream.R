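#' Pen-event streams
#'
#' A `pen_stream` is the raw material of all drawing features: one drawing
#' session recorded as an ordered series of pen events. Each row is one sample
#' with columns `t_s` (seconds from session start), `x_mm`, `y_mm` (position on
#' the drawing surface), `pressure` (normalized to `[0, 1]`; 0 while the pen is
#' lifted), `incl_h_deg`, `incl_v_deg` (pen inclinations in degrees) and
#' `hover_mm` (distance of the pen tip from the surface; 0 while on-surface).
#'
#' @param df A data frame with the seven pen-event columns.
#' @param device A [device_profile()].
#' @param validate Check stream invariants (monotone time, pressure bounds,
#'   pressure/hover exclusivity).
#'
#' @return An object of class `pen_stream` (a data frame with a `device`
#'   attribute).
#' @export
pen_stream <- function(df, device = device_profile(), validate = TRUE) {
  cols <- pen_stream_columns()
  if (!all(cols %in% names(df))) {
    stop("pen_stream requires columns: ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[cols]
  if (validate) validate_pen_stream(df)
  structure(df, device = device, class = c("pen_stream", "data.frame"))
}

pen_stream_columns <- function() {
  c("t_s", "x_mm", "y_mm", "pressure", "incl_h_deg", "incl_v_deg", "hover_mm")
}

validate_pen_stream <- function(df) {
  if (nrow(df) == 0L) stop("empty pen stream", call. = FALSE)
  if (any(!is.finite(df$t_s))) stop("non-finite timestamps", call. = FALSE)
  if (nrow(df) > 1L && any(diff(df$t_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (any(df$pressure < 0)) stop("negative pressure", call. = FALSE)
  if (any(df$pressure > 1)) stop("pressure must lie in [0, 1]", call. = FALSE)
  if (any(df$hover_mm < 0)) stop("negative hover distance", call. = FALSE)
  if (any(df$pressure > 0 & df$hover_mm > 0)) {
    stop("on-surface samples (pressure > 0) must have hover 0", call. = FALSE)
  }
  invisible(df)
}

#' @export
print.pen_stream <- function(x, ...) {
  dur <- x$t_s[nrow(x)] - x$t_s[1L]
  cat(sprintf("<pen_stream> %d samples, %.1f s, %.0f%% on-surface\n",
              nrow(x), dur, 100 * mean(x$pressure > 0)))
  invisible(x)
}

#' Truncate a pen stream in time
#'
#' Keeps the samples recorded up to `t_max` seconds from the first sample,
#' emulating an incomplete session whose partial drawing data are still
#' analyzed.
#'
#' @param stream A [pen_stream()].
#' @param t_max Cut-off in seconds relative to the first sample.
#' @return The truncated `pen_stream`.
#' @export
truncate_stream <- function(stream, t_max) {
  stopifnot(inherits(stream, "pen_stream"), t_max > 0)
  keep <- stream$t_s - stream$t_s[1L] <= t_max
  if (!any(keep)) stop("truncation removes all samples", call. = FALSE)
  pen_stream(stream[keep, , drop = FALSE],
             device = attr(stream, "device"), validate = FALSE)
}

#' Read and write pen-event CSV files
#'
#' The on-disk interchange format is a plain CSV with a fixed header
#' `t_s,x_mm,y_mm,pressure,incl_h_deg,incl_v_deg,hover_mm`, mirroring the raw
#' capture columns of a digitizer tablet (time, position, pressure,
#' inclinations, hover distance). `read_pen_csv()` validates the header and the
#' stream invariants (strictly increasing timestamps, non-negative pressure).
#'
#' @param stream A [pen_stream()].
#' @param path File path.
#' @param device Device profile attached to the stream on read.
#' @return `read_pen_csv()` returns a `pen_stream`; `write_pen_csv()` returns
#'   `path` invisibly.
#' @export
write_pen_csv <- function(stream, path) {
  stopifnot(inherits(stream, "pen_stream"))
  if (nrow(stream) == 0L) stop("refusing to write an empty stream", call. = FALSE)
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_pen_csv
#' @export
read_pen_csv <- function(path, device = device_profile()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  header <- gsub('^"|"$', "", trimws(header))
  if (!identical(header, pen_stream_columns())) {
    stop("malformed pen CSV header in ", path, call. = FALSE)
  }
  df <- utils::read.csv(path)
  pen_stream(df, device = device, validate = TRUE)
}
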