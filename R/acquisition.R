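#' Acquisition configuration for a flow-chamber field of view
#'
#' Describes how a time-lapse stack of one field of view was (or is to be)
#' acquired: frame rate, acquisition window, physical field dimensions, pixel
#' calibration, and the wall shear stress of the perfusion. The defaults
#' reproduce a typical parallel-plate assay: a 594 x 446 um field imaged for
#' 4 s at 30 frames/s under 0.6 dyn/cm2 laminar shear, six fields per chamber.
#'
#' The flow axis is the 446 um image axis (image rows); a rolling cell whose
#' streak must start and end inside the field can therefore travel at most
#' `field_height_um / duration` (about 112 um/s at the defaults), which is the
#' geometric velocity cap reported by [velocity_cap_um_s()].
#'
#' @param frame_rate Frames per second (default 30).
#' @param duration Acquisition window in seconds (default 4).
#' @param field_width_um Field extent along the non-flow axis, in um
#'   (default 594; image columns).
#' @param field_height_um Field extent along the flow axis, in um
#'   (default 446; image rows).
#' @param pixel_size_um Physical size of one pixel, um/pixel (default 1).
#' @param shear_stress_dyn_cm2 Wall shear stress in dyn/cm2 (default 0.6).
#' @param n_fields_per_chamber Number of fields imaged per chamber (default 6).
#' @param max_gray Full-scale intensity of the camera (default 255, 8-bit).
#'
#' @return An object of class `acquisition_config`.
#' @seealso [n_frames()], [field_area_mm2()], [shear_stress_pa()],
#'   [velocity_cap_um_s()], [raster_dims()]
#' @examples
#' cfg <- acquisition_config()
#' n_frames(cfg)          # 120
#' velocity_cap_um_s(cfg) # 111.5
#' @export
acquisition_config <- function(frame_rate = 30,
                               duration = 4,
                               field_width_um = 594,
                               field_height_um = 446,
                               pixel_size_um = 1,
                               shear_stress_dyn_cm2 = 0.6,
                               n_fields_per_chamber = 6,
                               max_gray = 255) {
  if (!is.numeric(frame_rate) || frame_rate <= 0) {
    stop_parameter("`frame_rate` must be a positive number")
  }
  if (!is.numeric(duration) || duration <= 0) {
    stop_parameter("`duration` must be a positive number")
  }
  nf <- frame_rate * duration
  if (abs(nf - round(nf)) > 1e-9 || round(nf) < 1) {
    stop_parameter(sprintf(
      "frame_rate * duration must be a positive integer frame count, got %g",
      nf
    ))
  }
  if (field_width_um <= 0 || field_height_um <= 0) {
    stop_parameter("field dimensions must be positive")
  }
  if (pixel_size_um <= 0) {
    stop_parameter("`pixel_size_um` must be positive")
  }
  dims <- c(
    rows = round(field_height_um / pixel_size_um),
    cols = round(field_width_um / pixel_size_um)
  )
  if (any(dims < 16)) {
    stop_parameter("raster dimensions must be at least 16 px along each axis")
  }
  if (shear_stress_dyn_cm2 < 0) {
    stop_parameter("`shear_stress_dyn_cm2` must be non-negative")
  }
  structure(
    list(
      frame_rate = frame_rate,
      duration = duration,
      field_width_um = field_width_um,
      field_height_um = field_height_um,
      pixel_size_um = pixel_size_um,
      shear_stress_dyn_cm2 = shear_stress_dyn_cm2,
      n_fields_per_chamber = n_fields_per_chamber,
      max_gray = max_gray
    ),
    class = "acquisition_config"
  )
}

#' Number of frames in the acquisition window
#'
#' @param config An [acquisition_config()].
#' @return Integer frame count (`frame_rate * duration`; 120 at the defaults).
#' @export
n_frames <- function(config) {
  stopifnot(inherits(config, "acquisition_config"))
  as.integer(round(config$frame_rate * config$duration))
}

#' Field-of-view area in mm^2
#'
#' @param config An [acquisition_config()].
#' @return Field area in mm^2 (0.594 x 0.446 = 0.264924 at the defaults).
#' @export
field_area_mm2 <- function(config) {
  stopifnot(inherits(config, "acquisition_config"))
  (config$field_width_um / 1000) * (config$field_height_um / 1000)
}

#' Wall shear stress in pascal
#'
#' Converts the configured shear stress from dyn/cm2 to Pa
#' (1 dyn/cm2 = 0.1 Pa), so the default 0.6 dyn/cm2 echoes as 0.06 Pa.
#'
#' @param config An [acquisition_config()].
#' @return Shear stress in Pa.
#' @export
shear_stress_pa <- function(config) {
  stopifnot(inherits(config, "acquisition_config"))
  config$shear_stress_dyn_cm2 * 0.1
}

#' Maximum measurable rolling velocity
#'
#' A streak is only measurable when both its start and end lie inside the
#' field, so the fastest measurable cell crosses the full flow-axis extent in
#' one acquisition window: `field_height_um / duration`, about 112 um/s at the
#' defaults (446 um / 4 s = 111.5 um/s).
#'
#' @param config An [acquisition_config()].
#' @return Velocity cap in um/s.
#' @export
velocity_cap_um_s <- function(config) {
  stopifnot(inherits(config, "acquisition_config"))
  config$field_height_um / config$duration
}

#' Raster dimensions of one frame
#'
#' @param config An [acquisition_config()].
#' @return Integer vector `c(rows, cols)`; rows run along the flow axis.
#' @export
raster_dims <- function(config) {
  stopifnot(inherits(config, "acquisition_config"))
  c(
    rows = as.integer(round(config$field_height_um / config$pixel_size_um)),
    cols = as.integer(round(config$field_width_um / config$pixel_size_um))
  )
}

#' @export
print.acquisition_config <- function(x, ...) {
  dims <- raster_dims(x)
  cat("Flow-chamber acquisition configuration\n")
  cat(sprintf(
    "  field: %g x %g um (%d x %d px at %g um/px), flow along the %g um axis\n",
    x$field_width_um, x$field_height_um, dims["cols"], dims["rows"],
    x$pixel_size_um, x$field_height_um
  ))
  cat(sprintf(
    "  acquisition: %g s at %g frames/s (%d frames)\n",
    x$duration, x$frame_rate, n_frames(x)
  ))
  cat(sprintf(
    "  shear stress: %g dyn/cm2 = %g Pa\n",
    x$shear_stress_dyn_cm2, shear_stress_pa(x)
  ))
  cat(sprintf(
    "  velocity cap: %.1f um/s; field area %.6f mm2; %d fields/chamber\n",
    velocity_cap_um_s(x), field_area_mm2(x), x$n_fields_per_chamber
  ))
  invisible(x)
}

# Condition helpers: typed errors so callers (and the CLI) can map failure
# modes to exit codes.
stop_parameter <- function(msg) {
  stop(errorCondition(msg, class = c("chamberflow_parameter_error", "chamberflow_error")))
}
stop_config <- function(msg) {
  stop(errorCondition(msg, class = c("chamberflow_config_error", "chamberflow_error")))
}
stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("chamberflow_format_error", "chamberflow_error")))
}
stop_analysis <- function(msg) {
  stop(errorCondition(msg, class = c("chamberflow_analysis_error", "chamberflow_error")))
}
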