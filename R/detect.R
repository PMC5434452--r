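#' Detector configuration
#'
#' Tunable parameters of the cell and streak detectors. Defaults are chosen
#' for ~10 um phase-bright monocytes imaged at 1 um/px on an 8-bit scale.
#'
#' Thresholding uses Otsu's method on the image histogram with a floor at
#' `background + threshold_floor_nsigma * noise`, where background and noise
#' are estimated robustly (median and MAD of the image). The floor keeps the
#' detector from chasing noise or low-contrast out-of-focus cells when no
#' bright in-focus cell is present; `min_mean_contrast` additionally rejects
#' components whose mean intensity sits too close to the background, which is
#' what makes defocused free-stream cells invisible to the detector.
#'
#' @param min_area_um2,max_area_um2 Area gate for single cells, um^2
#'   (defaults 25 and 400: discs of roughly 6-22 um diameter).
#' @param min_circularity Minimum circularity `4*pi*area/perimeter^2`
#'   (clamped to 1) for snapshot/minimization detections; default 0.6.
#' @param threshold_floor_nsigma Floor of the global threshold, in robust
#'   noise SDs above the background estimate; default 3.
#' @param min_mean_contrast Minimum mean intensity of a detection above the
#'   background estimate, grayscale units; default 30.
#' @param min_elongation Minimum major/minor extent ratio for a maximization
#'   blur to count as a rolling streak; default 2.
#' @param cell_diameter_um Mean cell diameter used by the corrected
#'   velocity mode, um; default 10.
#' @param velocity_mode `"corrected"` (subtract the streak's own measured
#'   width from its length before dividing by time, so a stationary cell
#'   implies velocity 0), `"diameter"` (subtract `cell_diameter_um`), or
#'   `"raw"` (blur length divided by time, the strict historical convention).
#' @param orientation_gate_deg Optional gate on streak orientation relative
#'   to the flow axis, degrees; `NULL` (default) disables it.
#' @param snapshot_frame 0-based frame used as the snapshot; default 0.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(min_area_um2 = 25,
                            max_area_um2 = 400,
                            min_circularity = 0.6,
                            threshold_floor_nsigma = 3,
                            min_mean_contrast = 30,
                            min_elongation = 2,
                            cell_diameter_um = 10,
                            velocity_mode = c("corrected", "diameter", "raw"),
                            orientation_gate_deg = NULL,
                            snapshot_frame = 0) {
  velocity_mode <- match.arg(velocity_mode)
  if (min_area_um2 <= 0 || max_area_um2 <= min_area_um2) {
    stop_parameter("need 0 < min_area_um2 < max_area_um2")
  }
  structure(
    list(
      min_area_um2 = min_area_um2,
      max_area_um2 = max_area_um2,
      min_circularity = min_circularity,
      threshold_floor_nsigma = threshold_floor_nsigma,
      min_mean_contrast = min_mean_contrast,
      min_elongation = min_elongation,
      cell_diameter_um = cell_diameter_um,
      velocity_mode = velocity_mode,
      orientation_gate_deg = orientation_gate_deg,
      snapshot_frame = snapshot_frame
    ),
    class = "detector_config"
  )
}

# Global threshold: Otsu with a robust noise floor. Returns Inf for a flat
# image (nothing to detect).
choose_threshold <- function(raster, detector, max_gray = 255) {
  if (diff(range(raster)) < 1e-9) return(Inf)
  bg <- stats::median(raster)
  noise <- stats::mad(raster)
  ot <- EBImage::otsu(EBImage::Image(raster / max_gray),
    range = c(0, 1), levels = 256
  ) * max_gray
  max(ot, bg + detector$threshold_floor_nsigma * noise)
}

# Label a binary mask, splitting fused clumps by one round of watershed on
# the distance transform. The split triggers when a component exceeds twice
# the nominal single-cell footprint (pi * (d/2)^2), i.e. when it can only be
# two or more touching cells; watershed leaves well-formed single discs
# untouched (one catchment basin).
label_mask <- function(mask, nominal_cell_area_px) {
  labels <- EBImage::bwlabel(mask)
  areas <- tabulate(labels[labels > 0])
  if (length(areas) && any(areas > 2 * nominal_cell_area_px)) {
    labels <- EBImage::watershed(EBImage::distmap(mask))
  }
  labels
}

#' Detect in-focus cells in a snapshot or minimization image
#'
#' Global threshold (Otsu with a noise floor), connected-component labelling,
#' then filtering by area bounds, circularity and mean contrast. Out-of-focus
#' free-stream cells fall below the contrast gates and are not detected.
#' Components larger than twice the nominal single-cell footprint
#' (`pi * (cell_diameter_um / 2)^2`) can only be fused cells and are split by
#' one round of watershed on the distance transform before filtering.
#'
#' Detections whose centroid lies inside the field count, including discs
#' touching the image border.
#'
#' @param image A `projection_image` of kind `"snapshot"` or `"min"`.
#' @param config An [acquisition_config()] (for pixel calibration).
#' @param detector A [detector_config()].
#' @return A data frame with one row per detection: `x_um`, `y_um` (centroid;
#'   x = columns, origin top-left), `area_um2`, `equivalent_diameter_um`,
#'   `circularity`, `mean_intensity`.
#' @export
segment_cells <- function(image,
                          config = acquisition_config(),
                          detector = detector_config()) {
  stopifnot(inherits(image, "projection_image"))
  if (image$kind == "max") {
    stop_parameter("segment_cells expects a snapshot or min image; streaks in a max image are not cells (use segment_streaks)")
  }
  raster <- image$raster
  px <- config$pixel_size_um
  empty <- data.frame(
    x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
    equivalent_diameter_um = numeric(), circularity = numeric(),
    mean_intensity = numeric()
  )
  thr <- choose_threshold(raster, detector, config$max_gray)
  if (!is.finite(thr)) return(empty)
  mask <- raster > thr
  if (!any(mask)) return(empty)
  storage.mode(mask) <- "integer"
  nominal_area_px <- pi * (detector$cell_diameter_um / 2)^2 / px^2
  labels <- label_mask(mask, nominal_area_px)
  labels <- as.matrix(EBImage::imageData(labels))
  nobj <- max(labels)
  if (nobj == 0) return(empty)

  shp <- EBImage::computeFeatures.shape(labels)
  mom <- EBImage::computeFeatures.moment(labels)
  if (is.null(dim(shp))) shp <- matrix(shp, nrow = 1, dimnames = list(NULL, names(shp)))
  if (is.null(dim(mom))) mom <- matrix(mom, nrow = 1, dimnames = list(NULL, names(mom)))

  idx <- which(labels > 0)
  mean_int <- vapply(
    split(raster[idx], labels[idx]), mean, numeric(1)
  )[as.character(seq_len(nrow(shp)))]

  bg <- stats::median(raster)
  area_um2 <- shp[, "s.area"] * px^2
  perim_um <- pmax(shp[, "s.perimeter"], 1) * px
  circ <- pmin(1, 4 * pi * area_um2 / perim_um^2)

  keep <- area_um2 >= detector$min_area_um2 &
    area_um2 <= detector$max_area_um2 &
    circ >= detector$min_circularity &
    (mean_int - bg) >= detector$min_mean_contrast
  keep[is.na(keep)] <- FALSE

  data.frame(
    x_um = (mom[keep, "m.cy"] - 0.5) * px,
    y_um = (mom[keep, "m.cx"] - 0.5) * px,
    area_um2 = area_um2[keep],
    equivalent_diameter_um = 2 * sqrt(area_um2[keep] / pi),
    circularity = circ[keep],
    mean_intensity = mean_int[keep],
    row.names = NULL
  )
}

#' Classify a field into adherent and rolling counts
#'
#' Applies the projection-subtraction rule to one stack: the snapshot count
#' is the total number of substrate-interacting cells, the count in the
#' temporal minimization image is the number of firmly adherent cells
#' (stationary for the whole >= 4 s window), and their difference is the
#' number of rolling cells. A negative difference is clamped to zero and
#' flagged.
#'
#' @param stack A [frame_stack()] covering at least 4 seconds.
#' @param detector A [detector_config()].
#' @return An object of class `field_quantification` with counts, the field
#'   area in mm^2, densities per mm^2, the detection tables, and a `clamped`
#'   quality flag.
#' @export
classify_field <- function(stack, detector = detector_config()) {
  stopifnot(inherits(stack, "frame_stack"))
  config <- stack$config
  if (config$duration < 4) {
    stop_parameter(sprintf(
      "firm adhesion requires at least a 4 s window; stack covers %.2f s",
      config$duration
    ))
  }
  snap <- snapshot(stack, detector$snapshot_frame)
  mins <- temporal_min(stack)
  det_snap <- segment_cells(snap, config, detector)
  det_min <- segment_cells(mins, config, detector)
  total <- nrow(det_snap)
  adherent <- nrow(det_min)
  rolling <- total - adherent
  clamped <- rolling < 0
  if (clamped) {
    warning("adherent count exceeds snapshot total; rolling count clamped to 0")
    rolling <- 0
  }
  area <- field_area_mm2(config)
  structure(
    list(
      total_count = total,
      adherent_count = adherent,
      rolling_count = rolling,
      field_area_mm2 = area,
      adherent_density_mm2 = adherent / area,
      rolling_density_mm2 = rolling / area,
      snapshot_detections = det_snap,
      adherent_detections = det_min,
      clamped = clamped
    ),
    class = "field_quantification"
  )
}

#' @export
print.field_quantification <- function(x, ...) {
  cat(sprintf(
    "field_quantification: total %d, adherent %d, rolling %d (%.4f mm2)\n",
    x$total_count, x$adherent_count, x$rolling_count, x$field_area_mm2
  ))
  cat(sprintf(
    "  densities: %.1f adherent/mm2, %.1f rolling/mm2%s\n",
    x$adherent_density_mm2, x$rolling_density_mm2,
    if (isTRUE(x$clamped)) " [clamped]" else ""
  ))
  invisible(x)
}

#' Convert a cell count to a density per mm^2
#'
#' Counts are reported per mm^2 of substrate; the default field covers
#' 0.594 x 0.446 mm = 0.264924 mm^2. Densities from several fields of one
#' chamber are aggregated as the mean of per-field densities.
#'
#' @param count Non-negative cell count (vectorized).
#' @param config An [acquisition_config()].
#' @return Density in cells per mm^2.
#' @examples
#' density_per_mm2(4) # 15.098...
#' @export
density_per_mm2 <- function(count, config = acquisition_config()) {
  if (any(count < 0)) stop_parameter("`count` must be non-negative")
  area <- field_area_mm2(config)
  if (area <= 0) stop_parameter("field dimensions must be positive")
  count / area
}
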