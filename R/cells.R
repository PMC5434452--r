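#' Specification of one simulated cell
#'
#' A cell in a synthetic flow-chamber scene. Positions are in um from the
#' top-left corner of the field; `x` runs along the image columns (non-flow
#' axis) and `y` along the rows (flow axis), so rolling and free-stream cells
#' translate toward increasing `y`.
#'
#' Three classes are distinguished:
#' \describe{
#'   \item{adherent}{in focus, stationary for the whole window (velocity 0);
#'     optionally a sub-pixel thermal jitter can be added at render time.}
#'   \item{rolling}{in focus, translating along the flow axis at a constant
#'     velocity between 0 and the geometric cap.}
#'   \item{freestream}{carried in the free stream above the substrate, out of
#'     the focal plane: rendered strongly blurred and at low contrast so a
#'     contrast-thresholding detector does not see it.}
#' }
#'
#' @param class_label One of `"adherent"`, `"rolling"`, `"freestream"`.
#' @param x_um,y_um Position of the cell centre at frame 0, in um.
#' @param radius_um Cell radius in um (default 5; a ~10 um monocyte).
#' @param peak_intensity Peak intensity above background, grayscale units.
#'   Defaults: 120 for in-focus cells, 15 for free-stream cells (8-bit scale).
#' @param velocity_um_s Translation speed along the flow axis in um/s; must be
#'   0 for adherent cells and positive for rolling and free-stream cells.
#'   Free-stream cells default to 300 um/s (faster than the measurable cap).
#' @param focus_blur_sigma_um Gaussian defocus sigma in um; 0 for in-focus
#'   cells, default 8 for free-stream cells.
#'
#' @return An object of class `cell_spec` (a named list).
#' @examples
#' cell_spec("adherent", 100, 200)
#' cell_spec("rolling", 300, 50, velocity_um_s = 27)
#' @export
cell_spec <- function(class_label,
                      x_um,
                      y_um,
                      radius_um = 5,
                      peak_intensity = NULL,
                      velocity_um_s = NULL,
                      focus_blur_sigma_um = NULL) {
  class_label <- match.arg(class_label, c("adherent", "rolling", "freestream"))
  if (is.null(peak_intensity)) {
    peak_intensity <- if (class_label == "freestream") 15 else 120
  }
  if (is.null(velocity_um_s)) {
    velocity_um_s <- switch(class_label,
      adherent = 0, rolling = 27, freestream = 300
    )
  }
  if (is.null(focus_blur_sigma_um)) {
    focus_blur_sigma_um <- if (class_label == "freestream") 8 else 0
  }
  if (radius_um <= 0) stop_parameter("`radius_um` must be positive")
  if (peak_intensity < 0) stop_parameter("`peak_intensity` must be non-negative")
  if (class_label == "adherent" && velocity_um_s != 0) {
    stop_parameter("adherent cells must have velocity 0")
  }
  if (class_label == "rolling" && velocity_um_s <= 0) {
    stop_parameter("rolling cells must have positive velocity")
  }
  if (class_label == "freestream" && focus_blur_sigma_um <= 0) {
    stop_parameter("freestream cells must have positive focus blur")
  }
  structure(
    list(
      class_label = class_label,
      x_um = x_um,
      y_um = y_um,
      radius_um = radius_um,
      peak_intensity = peak_intensity,
      velocity_um_s = velocity_um_s,
      focus_blur_sigma_um = focus_blur_sigma_um
    ),
    class = "cell_spec"
  )
}

#' @export
print.cell_spec <- function(x, ...) {
  cat(sprintf(
    "cell_spec: %s at (%.1f, %.1f) um, r=%.1f um, v=%.1f um/s, peak=%g\n",
    x$class_label, x$x_um, x$y_um, x$radius_um, x$velocity_um_s,
    x$peak_intensity
  ))
  invisible(x)
}

#' Tabulate a scene as a data frame
#'
#' @param scene A list of [cell_spec()] objects.
#' @return A data frame with one row per cell.
#' @export
scene_as_data_frame <- function(scene) {
  stopifnot(is.list(scene))
  if (length(scene) == 0) {
    return(data.frame(
      class = character(), x_um = numeric(), y_um = numeric(),
      radius_um = numeric(), velocity_um_s = numeric(),
      peak_intensity = numeric(), focus_blur_sigma_um = numeric()
    ))
  }
  do.call(rbind, lapply(scene, function(c) {
    data.frame(
      class = c$class_label, x_um = c$x_um, y_um = c$y_um,
      radius_um = c$radius_um, velocity_um_s = c$velocity_um_s,
      peak_intensity = c$peak_intensity,
      focus_blur_sigma_um = c$focus_blur_sigma_um
    )
  }))
}

#' Build a random well-separated scene
#'
#' Places adherent, rolling and free-stream cells uniformly at random inside
#' the field, subject to separation constraints that keep every object
#' individually resolvable: cell centres are kept at least `min_separation_um`
#' apart, rolling cells get exclusive "lanes" (no other in-focus cell inside
#' the strip their streak sweeps), and each rolling cell's path is kept fully
#' inside the field so its streak has visible start and end points.
#'
#' @param n_adherent,n_rolling,n_freestream Cell counts per class.
#' @param config An [acquisition_config()].
#' @param rolling_velocities Velocities for rolling cells, um/s; recycled or
#'   drawn uniformly in `velocity_range` when `NULL`.
#' @param velocity_range Range for random rolling velocities (default
#'   `c(10, 60)` um/s).
#' @param radius_um Cell radius in um.
#' @param min_separation_um Minimum distance between cell centres (default
#'   25 um).
#' @param seed Integer seed; placement is deterministic given the seed.
#' @param max_tries Rejection-sampling budget per cell.
#' @return A list of [cell_spec()] objects.
#' @export
build_scene <- function(n_adherent,
                        n_rolling,
                        n_freestream = 0,
                        config = acquisition_config(),
                        rolling_velocities = NULL,
                        velocity_range = c(10, 60),
                        radius_um = 5,
                        min_separation_um = 25,
                        seed = NULL,
                        max_tries = 2000) {
  if (!is.null(seed)) set.seed(seed)
  W <- config$field_width_um
  H <- config$field_height_um
  Tdur <- config$duration
  r <- radius_um
  margin <- r + 2

  if (is.null(rolling_velocities)) {
    rolling_velocities <- stats::runif(max(n_rolling, 0), velocity_range[1], velocity_range[2])
  } else {
    rolling_velocities <- rep_len(rolling_velocities, n_rolling)
  }
  cap <- velocity_cap_um_s(config)
  rolling_velocities <- pmin(rolling_velocities, cap - 2 * margin / Tdur)

  placed_x <- numeric(0)
  placed_y <- numeric(0)
  # lane strips swept by rolling cells: (x, y_start, y_end)
  lanes <- matrix(numeric(0), ncol = 3)

  ok_point <- function(x, y) {
    if (length(placed_x) &&
        any((placed_x - x)^2 + (placed_y - y)^2 < min_separation_um^2)) {
      return(FALSE)
    }
    if (nrow(lanes)) {
      in_lane <- abs(lanes[, 1] - x) < (2 * r + 5) &
        y > lanes[, 2] - min_separation_um & y < lanes[, 3] + min_separation_um
      if (any(in_lane)) return(FALSE)
    }
    TRUE
  }

  scene <- list()

  for (i in seq_len(n_rolling)) {
    v <- rolling_velocities[i]
    path <- v * Tdur
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, margin, W - margin)
      y <- stats::runif(1, margin, H - path - margin)
      strip_ok <- ok_point(x, y) && ok_point(x, y + path) &&
        ok_point(x, y + path / 2)
      lane_clash <- length(placed_x) &&
        any(abs(placed_x - x) < (2 * r + 5) &
              placed_y > y - min_separation_um &
              placed_y < y + path + min_separation_um)
      if (strip_ok && !lane_clash) break
      if (try == max_tries) stop_parameter("could not place rolling cell; scene too crowded")
    }
    scene[[length(scene) + 1]] <-
      cell_spec("rolling", x, y, radius_um = r, velocity_um_s = v)
    placed_x <- c(placed_x, x)
    placed_y <- c(placed_y, y)
    lanes <- rbind(lanes, c(x, y - r, y + path + r))
  }

  for (i in seq_len(n_adherent)) {
    for (try in seq_len(max_tries)) {
      x <- stats::runif(1, margin, W - margin)
      y <- stats::runif(1, margin, H - margin)
      if (ok_point(x, y)) break
      if (try == max_tries) stop_parameter("could not place adherent cell; scene too crowded")
    }
    scene[[length(scene) + 1]] <- cell_spec("adherent", x, y, radius_um = r)
    placed_x <- c(placed_x, x)
    placed_y <- c(placed_y, y)
  }

  for (i in seq_len(n_freestream)) {
    x <- stats::runif(1, margin, W - margin)
    y <- stats::runif(1, 0, H / 2)
    scene[[length(scene) + 1]] <- cell_spec("freestream", x, y, radius_um = r)
  }

  scene
}
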