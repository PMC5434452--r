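test_that("a stationary disc leaves no streak in the max image", {
  cfg <- acquisition_config(
    frame_rate = 10, duration = 4, field_width_um = 100, field_height_um = 100
  )
  out <- generate_field_stack(list(cell_spec("adherent", 50, 50)), cfg, seed = 1)
  st <- segment_streaks(temporal_max(out$stack), cfg)
  expect_identical(nrow(st), 0L)
  # and the full velocimetry chain degrades to an empty measurement table
  v <- measure_field_velocities(out$stack)
  expect_identical(nrow(v$measurements), 0L)
  expect_length(v$velocities_um_s, 0)
})

test_that("streak extent is path length plus cell diameter", {
  cfg <- acquisition_config()
  cell <- cell_spec("rolling", 200, 150, velocity_um_s = 27) # path 108 um
  out <- generate_field_stack(list(cell), cfg, noise_sigma = 0, seed = 2)
  st <- segment_streaks(temporal_max(out$stack), cfg)
  expect_identical(nrow(st), 1L)
  expect_lt(abs(st$major_length_um - (108 + 10)), 2)
  expect_false(st$touches_border)
  expect_false(st$ambiguous)
  expect_lt(abs(st$orientation_deg), 3)
})

test_that("streaks crossing the field edge are flagged and filtered out", {
  cfg <- acquisition_config(
    frame_rate = 10, duration = 4, field_width_um = 200, field_height_um = 200
  )
  scene <- list(
    cell_spec("rolling", 60, 150, velocity_um_s = 30),  # exits the field
    cell_spec("rolling", 140, 30, velocity_um_s = 20)   # fully interior
  )
  out <- generate_field_stack(scene, cfg, noise_sigma = 0, seed = 3)
  st <- segment_streaks(temporal_max(out$stack), cfg)
  expect_identical(nrow(st), 2L)
  expect_identical(sum(st$touches_border), 1L)
  kept <- filter_complete_streaks(st)
  expect_identical(nrow(kept), 1L)
  expect_false(kept$touches_border)
})

test_that("completeness filtering is a pure, idempotent predicate filter", {
  streaks <- data.frame(
    major_length_um = c(50, 80, 120, 40),
    minor_width_um = 10,
    orientation_deg = 0,
    touches_border = c(FALSE, TRUE, FALSE, TRUE),
    ambiguous = FALSE
  )
  kept <- filter_complete_streaks(streaks)
  expect_identical(kept$major_length_um, c(50, 120))       # order preserved
  expect_identical(filter_complete_streaks(kept), kept)    # idempotent
  none <- streaks[streaks$touches_border, ]
  expect_identical(nrow(filter_complete_streaks(none)), 0L)
  expect_identical(nrow(filter_complete_streaks(streaks[!streaks$touches_border, ])), 2L)
})

test_that("velocity is corrected length over time, floored and capped", {
  det_d <- detector_config(velocity_mode = "diameter")
  streak <- data.frame(
    major_length_um = 130, minor_width_um = 10, orientation_deg = 0,
    touches_border = FALSE, ambiguous = FALSE
  )
  m <- streak_velocity(streak, 4, det_d)
  expect_equal(m$velocity_um_s, (130 - 10) / 4) # corrected length 120 -> 30
  expect_false(m$over_cap)

  raw <- streak_velocity(streak, 4, detector_config(velocity_mode = "raw"))
  expect_equal(raw$velocity_um_s, 130 / 4)

  corr <- streak_velocity(streak, 4, detector_config(velocity_mode = "corrected"))
  expect_equal(corr$velocity_um_s, (130 - 10) / 4)

  # a stationary disc implies velocity 0 in corrected mode
  disc <- data.frame(
    major_length_um = 11, minor_width_um = 11, orientation_deg = 0,
    touches_border = FALSE, ambiguous = FALSE
  )
  expect_equal(streak_velocity(disc, 4, detector_config())$velocity_um_s, 0)

  # beyond the geometric cap: flagged as a segmentation artefact
  huge <- data.frame(
    major_length_um = 500, minor_width_um = 10, orientation_deg = 0,
    touches_border = FALSE, ambiguous = FALSE
  )
  expect_true(streak_velocity(huge, 4, det_d)$over_cap)
  expect_error(streak_velocity(streak, 0, det_d), class = "chamberflow_parameter_error")
})

test_that("a full-span interior streak approaches the ~112 um/s cap", {
  cfg <- acquisition_config()
  # maximal interior path: from the top edge to the bottom edge of the field
  streak <- data.frame(
    major_length_um = cfg$field_height_um, minor_width_um = 10,
    orientation_deg = 0, touches_border = FALSE, ambiguous = FALSE
  )
  m <- streak_velocity(streak, cfg$duration, detector_config(velocity_mode = "raw"))
  expect_equal(m$velocity_um_s, 111.5)
  expect_false(m$over_cap)
  expect_lt(abs(velocity_cap_um_s(cfg) - 112), 1)
})

test_that("velocities from rendered rollers recover ground truth", {
  cfg <- acquisition_config()
  vels <- c(12, 28, 45, 66, 85)
  scene <- build_scene(0, 5, config = cfg, rolling_velocities = vels, seed = 77)
  out <- generate_field_stack(scene, cfg, noise_sigma = 0, seed = 77)
  v <- measure_field_velocities(out$stack)
  expect_length(v$velocities_um_s, 5)
  truth <- sort(scene_as_data_frame(scene)$velocity_um_s[
    scene_as_data_frame(scene)$class == "rolling"
  ])
  err <- abs(sort(v$velocities_um_s) - truth)
  expect_true(all(err <= 2 * cfg$pixel_size_um / cfg$duration))
})

test_that("velocity summaries report mean, SEM and n", {
  s <- summarize_velocities(c(10, 20, 30))
  expect_equal(s$mean, 20)
  expect_equal(s$sem, 10 / sqrt(3)) # 5.7735
  expect_identical(s$n, 3L)
  one <- summarize_velocities(42)
  expect_equal(one$mean, 42)
  expect_equal(one$sem, 0)
  none <- summarize_velocities(numeric(0))
  expect_identical(none$n, 0L)
  expect_true(is.na(none$mean))
  expect_s3_class(none, "velocity_summary")
})

test_that("segment_streaks refuses non-max images", {
  cfg <- acquisition_config(
    frame_rate = 5, duration = 4, field_width_um = 64, field_height_um = 64
  )
  st <- generate_field_stack(list(cell_spec("adherent", 30, 30)), cfg, seed = 1)$stack
  expect_error(segment_streaks(snapshot(st, 0), cfg),
    class = "chamberflow_parameter_error")
  expect_error(segment_streaks(temporal_min(st), cfg),
    class = "chamberflow_parameter_error")
})

test_that("crossing blurs are flagged ambiguous and excluded from summaries", {
  cfg <- acquisition_config(
    frame_rate = 30, duration = 4, field_width_um = 200, field_height_um = 300
  )
  # two rollers in overlapping lanes with different speeds: their blurs merge
  # into one component with a locally widened profile where they overlap
  scene <- list(
    cell_spec("rolling", 100, 30, velocity_um_s = 20),
    cell_spec("rolling", 107, 90, velocity_um_s = 40)
  )
  out <- generate_field_stack(scene, cfg, noise_sigma = 0, seed = 5)
  v <- measure_field_velocities(out$stack)
  merged <- v$measurements
  # whatever the segmentation produced, no un-flagged measurement may claim a
  # velocity that no cell had
  ok <- v$velocities_um_s
  expect_true(all(ok < velocity_cap_um_s(cfg)))
  if (nrow(merged) == 1) {
    expect_true(merged$ambiguous || merged$over_cap ||
      abs(merged$velocity_um_s - 40) < 3)
  }
})
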