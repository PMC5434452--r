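#' Time-lapse stack of one field of view
#'
#' Internal constructor for the `frame_stack` container: an ordered list of
#' equal-sized grayscale matrices (rows = flow axis) plus the acquisition
#' configuration that calibrates them.
#'
#' @param frames List of numeric matrices, all the same dimension.
#' @param config An [acquisition_config()].
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, config) {
  if (!length(frames)) stop_parameter("a frame stack needs at least one frame")
  d <- dim(frames[[1]])
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1))
  if (!all(same)) stop_parameter("all frames must share one shape")
  structure(list(frames = frames, config = config), class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "frame_stack: %d frames of %d x %d px (%.1f s at %g frames/s)\n",
    length(x$frames), d[1], d[2], x$config$duration, x$config$frame_rate
  ))
  invisible(x)
}

# Frame sample times span the acquisition window inclusively, so the centroid
# displacement of a roller over the stack equals velocity * duration exactly
# and its streak extent is path length + cell diameter.
frame_times <- function(config) {
  n <- n_frames(config)
  if (n == 1) return(0)
  seq(0, config$duration, length.out = n)
}

# One cell's intensity footprint as a window patch (rows, cols, add), or NULL
# when the footprint misses the raster. The caller applies the patch so the
# frame is modified in place (no copy-on-write of the full raster).
cell_patch <- function(cell, y_t, x_t, dims, px, edge_width_um) {
  nr <- dims[1]
  nc <- dims[2]
  r <- cell$radius_um
  if (cell$focus_blur_sigma_um > 0) {
    half <- r + 3 * cell$focus_blur_sigma_um
  } else {
    half <- r + 6 * edge_width_um
  }
  r0 <- max(1L, floor((y_t - half) / px) + 1L)
  r1 <- min(nr, ceiling((y_t + half) / px))
  c0 <- max(1L, floor((x_t - half) / px) + 1L)
  c1 <- min(nc, ceiling((x_t + half) / px))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1
  cols <- c0:c1
  yy <- (rows - 0.5) * px - y_t
  xx <- (cols - 0.5) * px - x_t
  d <- sqrt(outer(yy^2, xx^2, `+`))
  if (cell$focus_blur_sigma_um > 0) {
    prof <- exp(-d^2 / (2 * cell$focus_blur_sigma_um^2))
  } else {
    prof <- 1 / (1 + exp((d - r) / edge_width_um))
  }
  list(rows = rows, cols = cols, add = cell$peak_intensity * prof)
}

#' Generate a synthetic time-lapse stack with ground truth
#'
#' Renders a scene of [cell_spec()]s into a multi-frame grayscale stack that
#' emulates phase-contrast acquisition of a flow chamber: in-focus cells are
#' bright discs with a soft (sigmoidal, sub-pixel) edge on a uniform dark
#' background, rolling and free-stream cells translate along the flow axis at
#' constant velocity, free-stream cells are rendered heavily blurred and at
#' low contrast, and optional additive Gaussian noise is applied per pixel and
#' frame, with intensities clipped to `[0, max_gray]` and quantized to integer
#' gray levels (camera digitization).
#'
#' Ground-truth counts follow the snapshot convention: only in-focus cells
#' whose centre lies inside the field at frame 0 are counted, so cells that
#' enter the field later do not contribute to `n_adherent`/`n_rolling`.
#'
#' @param scene List of [cell_spec()] objects.
#' @param config An [acquisition_config()].
#' @param noise_sigma Standard deviation of additive Gaussian noise,
#'   grayscale units (default 0 = noiseless).
#' @param seed Integer seed; the stack is bit-identical for identical
#'   `(scene, config, noise_sigma, seed)`.
#' @param background Uniform background level, grayscale units (default 30).
#' @param jitter_px Amplitude (in pixels, < 0.5) of optional per-frame
#'   sub-pixel jitter applied to adherent cells; default 0.
#' @param edge_width_um Softness of the in-focus disc edge, um (default 0.5).
#'
#' @return A list with components `stack` (a [frame_stack()]) and `truth`, a
#'   `ground_truth` object with fields `cells` (data frame), `n_adherent`,
#'   `n_rolling`, `rolling_velocities`, `seed` and `overlap_warning`.
#' @examples
#' cfg <- acquisition_config()
#' scene <- build_scene(3, 2, config = cfg, seed = 1)
#' out <- generate_field_stack(scene, cfg, noise_sigma = 0, seed = 1)
#' out$truth$n_adherent
#' @export
generate_field_stack <- function(scene,
                                 config = acquisition_config(),
                                 noise_sigma = 0,
                                 seed = 1,
                                 background = 30,
                                 jitter_px = 0,
                                 edge_width_um = 0.5) {
  stopifnot(inherits(config, "acquisition_config"))
  if (noise_sigma < 0) stop_parameter("`noise_sigma` must be non-negative")
  if (jitter_px < 0 || jitter_px >= 0.5) {
    stop_parameter("`jitter_px` must be in [0, 0.5)")
  }
  W <- config$field_width_um
  H <- config$field_height_um
  for (cell in scene) {
    if (!inherits(cell, "cell_spec")) stop_parameter("scene must contain cell_spec objects")
    if (cell$x_um < 0 || cell$x_um > W || cell$y_um > H ||
        cell$y_um + cell$velocity_um_s * config$duration < 0) {
      stop_parameter("every scene cell must lie within or enter the field")
    }
  }

  set.seed(seed)
  dims <- raster_dims(config)
  px <- config$pixel_size_um
  times <- frame_times(config)
  nfr <- length(times)

  adherent_idx <- which(vapply(scene, function(c) c$class_label == "adherent", logical(1)))
  jit <- NULL
  if (jitter_px > 0 && length(adherent_idx)) {
    jit <- array(
      stats::runif(2 * nfr * length(adherent_idx), -jitter_px, jitter_px) * px,
      dim = c(nfr, length(adherent_idx), 2)
    )
  }

  # static layer: background plus non-jittered adherent cells, rendered once
  static <- matrix(background, dims["rows"], dims["cols"])
  static_idx <- if (is.null(jit)) adherent_idx else integer(0)
  for (i in static_idx) {
    p <- cell_patch(scene[[i]], scene[[i]]$y_um, scene[[i]]$x_um, dims, px, edge_width_um)
    if (!is.null(p)) static[p$rows, p$cols] <- static[p$rows, p$cols] + p$add
  }
  moving_idx <- setdiff(seq_along(scene), static_idx)

  frames <- vector("list", nfr)
  for (k in seq_len(nfr)) {
    f <- static + 0  # fresh copy, safe to modify in place
    for (i in moving_idx) {
      cell <- scene[[i]]
      y_t <- cell$y_um + cell$velocity_um_s * times[k]
      x_t <- cell$x_um
      if (!is.null(jit) && cell$class_label == "adherent") {
        j <- match(i, adherent_idx)
        y_t <- y_t + jit[k, j, 1]
        x_t <- x_t + jit[k, j, 2]
      }
      if (y_t < -3 * H || y_t > 2 * H) next
      p <- cell_patch(cell, y_t, x_t, dims, px, edge_width_um)
      if (!is.null(p)) f[p$rows, p$cols] <- f[p$rows, p$cols] + p$add
    }
    if (noise_sigma > 0) {
      f <- f + stats::rnorm(length(f), 0, noise_sigma)
      f <- pmin(pmax(f, 0), config$max_gray)
    } else {
      # noiseless intensities are non-negative by construction; clip the top
      # only when overlapping footprints actually exceed full scale
      if (max(f) > config$max_gray) f <- pmin(f, config$max_gray)
    }
    frames[[k]] <- round(f)
  }

  df <- scene_as_data_frame(scene)
  in_field <- df$x_um >= 0 & df$x_um <= W & df$y_um >= 0 & df$y_um <= H
  in_focus <- df$class != "freestream"
  counted <- in_field & in_focus
  n_adh <- sum(counted & df$class == "adherent")
  n_rol <- sum(counted & df$class == "rolling")
  rv <- df$velocity_um_s[counted & df$class == "rolling"]

  overlap <- FALSE
  foc <- df[in_focus & in_field, , drop = FALSE]
  if (nrow(foc) > 1) {
    dd <- as.matrix(stats::dist(foc[, c("x_um", "y_um")]))
    diag(dd) <- Inf
    lim <- outer(foc$radius_um, foc$radius_um, `+`)  # one diameter for equal radii
    overlap <- any(dd < lim)
  }

  truth <- structure(
    list(
      cells = df,
      n_adherent = n_adh,
      n_rolling = n_rol,
      rolling_velocities = rv,
      seed = seed,
      overlap_warning = overlap
    ),
    class = "ground_truth"
  )
  list(stack = frame_stack(frames, config), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "ground_truth: %d adherent + %d rolling in-focus cells (seed %s)%s\n",
    x$n_adherent, x$n_rolling, format(x$seed),
    if (isTRUE(x$overlap_warning)) " [overlap warning]" else ""
  ))
  invisible(x)
}

#' Write a frame stack as a multi-page TIFF
#'
#' @param stack A [frame_stack()].
#' @param path Output file path.
#' @param bits Bits per sample: 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, bits = 8) {
  stopifnot(inherits(stack, "frame_stack"))
  if (!bits %in% c(8, 16)) stop_parameter("`bits` must be 8 or 16")
  mg <- stack$config$max_gray
  pages <- lapply(stack$frames, function(f) pmin(pmax(f / mg, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Read a multi-page TIFF as a frame stack
#'
#' Intensities are rescaled to the configured `max_gray` scale. When `config`
#' is supplied the frame count and raster dimensions are validated against it.
#'
#' @param path Path to a grayscale multi-page TIFF.
#' @param config An [acquisition_config()] used for calibration/validation.
#' @return A [frame_stack()].
#' @export
read_stack_tiff <- function(path, config = acquisition_config()) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
    error = function(e) stop_format(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)))
  )
  if (!is.list(pages)) pages <- list(pages)
  frames <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # drop extra channels
    round(p * config$max_gray)
  })
  expected <- n_frames(config)
  if (length(frames) != expected) {
    stop_format(sprintf(
      "expected %d frames (%g s at %g frames/s), file has %d",
      expected, config$duration, config$frame_rate, length(frames)
    ))
  }
  dims <- raster_dims(config)
  d <- dim(frames[[1]])
  if (d[1] != dims["rows"] || d[2] != dims["cols"]) {
    stop_format(sprintf(
      "expected %d x %d px frames, file has %d x %d",
      dims["rows"], dims["cols"], d[1], d[2]
    ))
  }
  frame_stack(frames, config)
}

#' Write ground truth as CSV plus a JSON sidecar
#'
#' One CSV row per cell (class, position, radius, velocity, intensity) and a
#' JSON sidecar holding the acquisition configuration, seed and summary
#' counts, so a stack on disk is fully reproducible.
#'
#' @param truth A `ground_truth` object from [generate_field_stack()].
#' @param config The [acquisition_config()] used.
#' @param csv_path Output CSV path; the sidecar is written next to it as
#'   `<csv_path>.json`.
#' @return `csv_path`, invisibly.
#' @export
write_ground_truth <- function(truth, config, csv_path) {
  utils::write.csv(truth$cells, csv_path, row.names = FALSE)
  side <- list(
    config = unclass(config),
    seed = truth$seed,
    n_adherent = truth$n_adherent,
    n_rolling = truth$n_rolling,
    overlap_warning = truth$overlap_warning
  )
  jsonlite::write_json(side, paste0(csv_path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
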