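#' Derived projection images
#'
#' The projection-based workflow reduces a time-lapse stack to three images:
#' a single-frame *snapshot* showing every substrate-interacting (in-focus)
#' cell, a temporal *minimization* image in which a pixel keeps the lowest
#' intensity it ever took (so only cells stationary for the whole window
#' survive as bright discs), and a temporal *maximization* image in which
#' moving bright cells paint elongated streaks whose length encodes the
#' distance travelled.
#'
#' @param raster Numeric matrix.
#' @param kind `"snapshot"`, `"min"` or `"max"`.
#' @param source_frame_count Number of frames that contributed.
#' @param duration_s Time covered by the projection, seconds.
#' @return An object of class `projection_image`.
#' @keywords internal
projection_image <- function(raster, kind, source_frame_count, duration_s) {
  kind <- match.arg(kind, c("snapshot", "min", "max"))
  structure(
    list(
      raster = raster,
      kind = kind,
      source_frame_count = source_frame_count,
      duration_s = duration_s
    ),
    class = "projection_image"
  )
}

#' @export
print.projection_image <- function(x, ...) {
  cat(sprintf(
    "projection_image[%s]: %d x %d px from %d frame(s) over %.2f s\n",
    x$kind, nrow(x$raster), ncol(x$raster), x$source_frame_count, x$duration_s
  ))
  invisible(x)
}

#' Single-frame snapshot
#'
#' Returns one frame of the stack unmodified. The snapshot shows both firmly
#' adherent and rolling cells as bright circles; free-stream cells are out of
#' focus and effectively invisible. Frame 0 (index 0) is the default.
#'
#' @param stack A [frame_stack()].
#' @param frame_index 0-based frame index (default 0).
#' @return A `projection_image` of kind `"snapshot"`.
#' @export
snapshot <- function(stack, frame_index = 0) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- length(stack$frames)
  if (!is.numeric(frame_index) || frame_index != round(frame_index) ||
      frame_index < 0 || frame_index >= n) {
    stop_parameter(sprintf(
      "`frame_index` must be an integer in [0, %d), got %s", n, format(frame_index)
    ))
  }
  projection_image(stack$frames[[frame_index + 1]], "snapshot",
    source_frame_count = 1L, duration_s = 0
  )
}

#' Temporal minimum-intensity projection
#'
#' Per-pixel minimum over all frames. A bright cell survives only where its
#' footprint covers a pixel in every frame, so with a 4 s stack the result
#' contains exactly the cells that remained stationary for at least 4 s --
#' the operational definition of firm adhesion. A rolling cell's previous
#' positions are replaced by the dark background it exposes as it moves.
#'
#' @param stack A [frame_stack()].
#' @return A `projection_image` of kind `"min"`.
#' @export
temporal_min <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!length(stack$frames)) stop_parameter("stack has no frames")
  projection_image(Reduce(pmin, stack$frames), "min",
    source_frame_count = length(stack$frames),
    duration_s = stack$config$duration
  )
}

#' Temporal maximum-intensity projection
#'
#' Per-pixel maximum over all frames: a rolling cell appears as a long
#' continuous blur covering every position it visited, which is the input to
#' streak velocimetry ([segment_streaks()]).
#'
#' @param stack A [frame_stack()].
#' @return A `projection_image` of kind `"max"`.
#' @export
temporal_max <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!length(stack$frames)) stop_parameter("stack has no frames")
  projection_image(Reduce(pmax, stack$frames), "max",
    source_frame_count = length(stack$frames),
    duration_s = stack$config$duration
  )
}

#' Write a projection image as single-page TIFF
#'
#' The projection kind is appended to the file name
#' (`<stem>_<kind>.tif`) so the three derived images of a field can live side
#' by side.
#'
#' @param image A `projection_image`.
#' @param stem Path stem (directory + basename without extension).
#' @param max_gray Full-scale intensity used for encoding (default 255).
#' @param bits Bits per sample, 8 or 16.
#' @return The written path, invisibly.
#' @export
write_projection_tiff <- function(image, stem, max_gray = 255, bits = 8) {
  stopifnot(inherits(image, "projection_image"))
  path <- sprintf("%s_%s.tif", stem, image$kind)
  tiff::writeTIFF(pmin(pmax(image$raster / max_gray, 0), 1), path,
    bits.per.sample = bits
  )
  invisible(path)
}
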