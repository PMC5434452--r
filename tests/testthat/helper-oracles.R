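# Independent oracles and small fixture builders used across the suite.

# Naive per-pixel, per-frame projection: the reference the vectorized
# implementation is checked against, kept deliberately loop-based.
brute_force_projection <- function(frames, fun) {
  d <- dim(frames[[1]])
  out <- matrix(NA_real_, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      series <- vapply(frames, function(f) f[i, j], numeric(1))
      out[i, j] <- fun(series)
    }
  }
  out
}

# A tiny stack of random integer frames with a matching configuration.
random_small_stack <- function(n_frames = 5, rows = 16, cols = 20, max_gray = 255) {
  cfg <- acquisition_config(
    frame_rate = n_frames, duration = 1,
    field_width_um = cols, field_height_um = rows,
    pixel_size_um = 1, max_gray = max_gray
  )
  frames <- lapply(seq_len(n_frames), function(k) {
    matrix(sample.int(max_gray + 1, rows * cols, replace = TRUE) - 1, rows, cols)
  })
  frame_stack(frames, cfg)
}

# Build a stack directly from a list of matrices with a duration-compatible
# config (frame_rate chosen so frame count validates).
stack_from_frames <- function(frames, duration = 4) {
  n <- length(frames)
  d <- dim(frames[[1]])
  cfg <- acquisition_config(
    frame_rate = n / duration, duration = duration,
    field_width_um = d[2], field_height_um = d[1], pixel_size_um = 1
  )
  frame_stack(frames, cfg)
}

# Intensity-weighted centroid of the above-background pixels, in um.
bright_centroid_um <- function(raster, background = 30, px = 1) {
  w <- pmax(raster - background, 0)
  idx <- which(w > 0, arr.ind = TRUE)
  w <- w[idx]
  c(
    x = sum((idx[, 2] - 0.5) * px * w) / sum(w),
    y = sum((idx[, 1] - 0.5) * px * w) / sum(w)
  )
}

default_cfg <- acquisition_config()
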