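#' Digitizer device profile
#'
#' Describes the capture device used for drawing sessions. Defaults match a
#' professional pen display commonly used in drawing-based cognitive
#' assessment studies: 180 Hz sampling, a 252 x 186 mm active area, 8192
#' pressure levels and 1-degree inclination resolution.
#'
#' @param sampling_rate_hz Samples per second emitted by the tablet.
#' @param surface_width_mm,surface_height_mm Active drawing area (mm); defines
#'   the bounding box for all generated coordinates.
#' @param pressure_levels Number of discrete pressure steps the device reports;
#'   simulated pressure (normalized to `[0, 1]`) is quantized to
#'   `1/(pressure_levels - 1)` steps.
#' @param inclination_resolution_deg Angular resolution of the reported pen
#'   inclinations, in degrees.
#'
#' @return An object of class `device_profile`.
#' @examples
#' device_profile()
#' @export
device_profile <- function(sampling_rate_hz = 180,
                           surface_width_mm = 252,
                           surface_height_mm = 186,
                           pressure_levels = 8192L,
                           inclination_resolution_deg = 1) {
  vals <- c(sampling_rate_hz, surface_width_mm, surface_height_mm,
            pressure_levels, inclination_resolution_deg)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all device_profile fields must be strictly positive", call. = FALSE)
  }
  structure(
    list(sampling_rate_hz = sampling_rate_hz,
         surface_width_mm = surface_width_mm,
         surface_height_mm = surface_height_mm,
         pressure_levels = as.integer(pressure_levels),
         inclination_resolution_deg = inclination_resolution_deg),
    class = "device_profile")
}

#' @export
print.device_profile <- function(x, ...) {
  cat(sprintf(
    "<device_profile> %g Hz, %g x %g mm, %d pressure levels, %g deg inclination\n",
    x$sampling_rate_hz, x$surface_width_mm, x$surface_height_mm,
    x$pressure_levels, x$inclination_resolution_deg))
  invisible(x)
}
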