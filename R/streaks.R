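#' Detect rolling-cell streaks in a maximization image
#'
#' A cell rolling at constant velocity paints an elongated blur into the
#' temporal maximum projection. Streak candidates are obtained by global
#' thresholding and connected-component labelling; a component is kept as a
#' streak when its elongation (major/minor extent) is at least
#' `min_elongation`, which excludes the discs left by stationary cells.
#'
#' Extents are Feret-style: the major length is the longest chord of the
#' component (computed on the convex hull of its pixel centres, plus one
#' pixel for pixel extent) and the minor width is the maximal extent
#' perpendicular to it. `touches_border` is set when the component meets any
#' image edge -- such a streak has no visible start or end point and its
#' length underestimates the path. Components whose width profile along the
#' major axis has more than one wide region (typically two crossing blurs)
#' are flagged `ambiguous`.
#'
#' @param max_image A `projection_image` of kind `"max"`.
#' @param config An [acquisition_config()].
#' @param detector A [detector_config()].
#' @return A data frame with one row per streak: `major_length_um`,
#'   `minor_width_um`, `orientation_deg` (from the flow axis),
#'   `touches_border`, `ambiguous`, `x_um`, `y_um`, `mean_intensity`.
#' @export
segment_streaks <- function(max_image,
                            config = acquisition_config(),
                            detector = detector_config()) {
  stopifnot(inherits(max_image, "projection_image"))
  if (max_image$kind != "max") {
    stop_parameter("segment_streaks expects a maximization image")
  }
  raster <- max_image$raster
  px <- config$pixel_size_um
  empty <- data.frame(
    major_length_um = numeric(), minor_width_um = numeric(),
    orientation_deg = numeric(), touches_border = logical(),
    ambiguous = logical(), x_um = numeric(), y_um = numeric(),
    mean_intensity = numeric()
  )
  thr <- choose_threshold(raster, detector, config$max_gray)
  if (!is.finite(thr)) return(empty)
  mask <- raster > thr
  if (!any(mask)) return(empty)
  storage.mode(mask) <- "integer"
  labels <- as.matrix(EBImage::imageData(EBImage::bwlabel(mask)))
  nobj <- max(labels)
  if (nobj == 0) return(empty)
  nr <- nrow(raster)
  nc <- ncol(raster)
  bg <- stats::median(raster)

  rows <- lapply(seq_len(nobj), function(l) {
    pix <- which(labels == l, arr.ind = TRUE)
    geom <- streak_geometry(pix, px)
    touches <- any(pix[, 1] == 1L) || any(pix[, 1] == nr) ||
      any(pix[, 2] == 1L) || any(pix[, 2] == nc)
    data.frame(
      major_length_um = geom$major_um,
      minor_width_um = geom$minor_um,
      orientation_deg = geom$orientation_deg,
      touches_border = touches,
      ambiguous = geom$ambiguous,
      x_um = (mean(pix[, 2]) - 0.5) * px,
      y_um = (mean(pix[, 1]) - 0.5) * px,
      mean_intensity = mean(raster[pix])
    )
  })
  out <- do.call(rbind, rows)

  elong <- out$major_length_um / pmax(out$minor_width_um, px)
  keep <- elong >= detector$min_elongation &
    (out$mean_intensity - bg) >= detector$min_mean_contrast
  if (!is.null(detector$orientation_gate_deg)) {
    keep <- keep & abs(out$orientation_deg) <= detector$orientation_gate_deg
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Feret-style extents, orientation, and a width-profile multimodality flag
# for one labelled component. `pix` is a (row, col) index matrix.
streak_geometry <- function(pix, px) {
  y <- pix[, 1] * px
  x <- pix[, 2] * px
  n <- length(x)
  if (n <= 2) {
    return(list(
      major_um = px * n, minor_um = px, orientation_deg = 0, ambiguous = FALSE
    ))
  }
  # principal axis from second moments
  mx <- mean(x); my <- mean(y)
  cx <- x - mx; cy <- y - my
  mu20 <- mean(cy^2); mu02 <- mean(cx^2); mu11 <- mean(cx * cy)
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02)  # angle from flow (row) axis
  ux <- sin(theta); uy <- cos(theta)           # major direction
  hull <- grDevices::chull(x, y)
  hx <- x[hull] - mx; hy <- y[hull] - my
  along <- hx * ux + hy * uy
  across <- -hx * uy + hy * ux
  major <- diff(range(along)) + px
  minor <- diff(range(across)) + px
  if (minor > major) {
    tmp <- major; major <- minor; minor <- tmp
    theta <- theta + pi / 2
  }
  deg <- (theta * 180 / pi) %% 180
  if (deg > 90) deg <- deg - 180

  # width profile along the major axis: more than one wide region means two
  # blurs crossing or merging
  al_all <- (x - mx) * ux + (y - my) * uy
  ac_all <- -(x - mx) * uy + (y - my) * ux
  ambiguous <- FALSE
  span <- diff(range(al_all))
  if (span > 6 * px) {
    nbins <- max(5L, min(60L, floor(span / (2 * px))))
    bins <- cut(al_all, breaks = nbins)
    w <- tapply(ac_all, bins, function(v) diff(range(v)) + px)
    w <- w[!is.na(w)]
    if (length(w) > 4) {
      med <- stats::median(w)
      wide <- w > 1.5 * med
      # interior wide runs (the tapering ends are naturally narrow)
      runs <- rle(as.vector(wide))
      ambiguous <- any(runs$values & runs$lengths >= 2)
    }
  }
  list(major_um = major, minor_um = minor, orientation_deg = deg,
       ambiguous = ambiguous)
}

#' Keep only streaks with visible start and end points
#'
#' A streak that touches the image border entered or left the field during
#' acquisition, so its length is a lower bound on the path travelled; only
#' cells whose full path is visible are analysed. The filter is idempotent
#' and order-preserving.
#'
#' @param streaks Data frame from [segment_streaks()].
#' @return The subset with `touches_border == FALSE`, order preserved.
#' @export
filter_complete_streaks <- function(streaks) {
  stopifnot(is.data.frame(streaks))
  out <- streaks[!streaks$touches_border, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert streak lengths to rolling velocities
#'
#' The average velocity of a rolling cell is its blur length divided by the
#' acquisition time. A disc of diameter d translating a distance L leaves a
#' blur of extent L + d, so the default `"corrected"` mode subtracts the
#' streak's own measured width (an estimate of the thresholded cell
#' diameter) from the major length before dividing, which makes a stationary
#' cell's implied velocity 0. Mode `"diameter"` subtracts the configured
#' mean cell diameter instead, and `"raw"` divides the uncorrected blur
#' length by time (the strict historical convention). Velocities are floored
#' at 0; a velocity above the geometric cap ([velocity_cap_um_s()]) is
#' flagged `over_cap` as a segmentation artefact and should be excluded from
#' summaries (as [measure_field_velocities()] does).
#'
#' @param streaks Data frame from [segment_streaks()] (border-complete rows).
#' @param duration_s Acquisition time in seconds.
#' @param detector A [detector_config()] supplying the mode and diameter.
#' @param cap_um_s Geometric velocity cap in um/s (default from `config`).
#' @param config An [acquisition_config()] used when `cap_um_s` is missing.
#' @return A data frame of velocity measurements: `velocity_um_s`,
#'   `duration_s`, streak geometry, and `over_cap`/`ambiguous` flags.
#' @export
streak_velocity <- function(streaks,
                            duration_s,
                            detector = detector_config(),
                            cap_um_s = NULL,
                            config = acquisition_config()) {
  stopifnot(is.data.frame(streaks))
  if (!is.numeric(duration_s) || duration_s <= 0) {
    stop_parameter("`duration_s` must be positive")
  }
  if (is.null(cap_um_s)) cap_um_s <- velocity_cap_um_s(config)
  if (nrow(streaks) == 0) {
    out <- streaks
    out$velocity_um_s <- numeric(0)
    out$duration_s <- numeric(0)
    out$over_cap <- logical(0)
    return(out)
  }
  corr <- switch(detector$velocity_mode,
    corrected = streaks$minor_width_um,
    diameter = rep(detector$cell_diameter_um, nrow(streaks)),
    raw = rep(0, nrow(streaks))
  )
  v <- pmax(streaks$major_length_um - corr, 0) / duration_s
  out <- streaks
  out$velocity_um_s <- v
  out$duration_s <- duration_s
  out$over_cap <- v > cap_um_s
  rownames(out) <- NULL
  out
}

#' Measure rolling velocities for one stack
#'
#' Runs the full velocimetry chain: temporal maximum projection, streak
#' segmentation, completeness filtering (visible start and end points),
#' length-to-velocity conversion, and exclusion of flagged measurements
#' (`over_cap` artefacts and `ambiguous` merged blurs).
#'
#' @param stack A [frame_stack()].
#' @param detector A [detector_config()].
#' @return A list with `measurements` (all complete streaks with velocities
#'   and flags) and `velocities_um_s` (the retained velocity vector).
#' @export
measure_field_velocities <- function(stack, detector = detector_config()) {
  stopifnot(inherits(stack, "frame_stack"))
  config <- stack$config
  mx <- temporal_max(stack)
  st <- segment_streaks(mx, config, detector)
  st <- filter_complete_streaks(st)
  meas <- streak_velocity(st, config$duration, detector, config = config)
  valid <- !meas$over_cap & !meas$ambiguous
  list(
    measurements = meas,
    velocities_um_s = meas$velocity_um_s[valid]
  )
}

#' Summarize velocities as mean, SEM and n
#'
#' Group results are reported as mean +/- SEM with SEM = SD/sqrt(n). A single
#' measurement yields SEM 0; an empty input yields a distinguished empty
#' summary (n = 0, mean and SEM `NA`) rather than an error.
#'
#' @param velocities Numeric vector of velocities (um/s), or any numeric
#'   sample.
#' @return A list of class `velocity_summary`: `mean`, `sem`, `n`.
#' @examples
#' summarize_velocities(c(10, 20, 30)) # mean 20, SEM 5.7735
#' @export
summarize_velocities <- function(velocities) {
  velocities <- velocities[is.finite(velocities)]
  n <- length(velocities)
  if (n == 0) {
    out <- list(mean = NA_real_, sem = NA_real_, n = 0L)
  } else if (n == 1) {
    out <- list(mean = velocities, sem = 0, n = 1L)
  } else {
    out <- list(
      mean = mean(velocities),
      sem = stats::sd(velocities) / sqrt(n),
      n = as.integer(n)
    )
  }
  structure(out, class = "velocity_summary")
}

#' @export
print.velocity_summary <- function(x, ...) {
  if (x$n == 0) {
    cat("velocity_summary: empty (n = 0)\n")
  } else {
    cat(sprintf("velocity_summary: %.2f +/- %.2f um/s (n = %d)\n", x$mean, x$sem, x$n))
  }
  invisible(x)
}
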