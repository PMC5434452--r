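test_that("empty noiseless scene renders the flat background", {
  cfg <- acquisition_config(
    frame_rate = 5, duration = 4, field_width_um = 64, field_height_um = 64
  )
  out <- generate_field_stack(list(), cfg, noise_sigma = 0, seed = 3)
  expect_length(out$stack$frames, 20)
  for (f in out$stack$frames) {
    expect_true(all(f == 30))
  }
  expect_identical(out$truth$n_adherent, 0L)
  expect_identical(out$truth$n_rolling, 0L)
})

test_that("a rolling cell translates at its nominal velocity", {
  cfg <- acquisition_config()
  cell <- cell_spec("rolling", x_um = 300, y_um = 100, velocity_um_s = 27)
  out <- generate_field_stack(list(cell), cfg, noise_sigma = 0, seed = 1)
  first <- bright_centroid_um(out$stack$frames[[1]])
  last <- bright_centroid_um(out$stack$frames[[120]])
  # path length = velocity x duration = 108 um along the flow (y) axis
  expect_equal(unname(last["y"] - first["y"]), 27 * 4, tolerance = 1 / (27 * 4))
  expect_lt(abs(last["x"] - first["x"]), 1)
  expect_equal(out$truth$rolling_velocities, 27)
})

test_that("stacks are bit-identical for identical scene/config/noise/seed", {
  cfg <- acquisition_config(
    frame_rate = 10, duration = 4, field_width_um = 128, field_height_um = 128
  )
  scene <- build_scene(2, 1, 1, config = cfg, velocity_range = c(10, 20), seed = 5)
  a <- generate_field_stack(scene, cfg, noise_sigma = 4, seed = 11)
  b <- generate_field_stack(scene, cfg, noise_sigma = 4, seed = 11)
  expect_identical(a$stack$frames, b$stack$frames)
  c <- generate_field_stack(scene, cfg, noise_sigma = 4, seed = 12)
  expect_false(identical(a$stack$frames, c$stack$frames))
})

test_that("generator rejects invalid parameters and flags crowded scenes", {
  cfg <- acquisition_config(
    frame_rate = 5, duration = 4, field_width_um = 64, field_height_um = 64
  )
  scene <- list(cell_spec("adherent", 30, 30))
  expect_error(
    generate_field_stack(scene, cfg, noise_sigma = -1),
    class = "chamberflow_parameter_error"
  )
  expect_error(
    generate_field_stack(scene, cfg, jitter_px = 0.7),
    class = "chamberflow_parameter_error"
  )
  expect_error(
    generate_field_stack(list(cell_spec("adherent", 500, 30)), cfg),
    class = "chamberflow_parameter_error"
  )
  # two adherent cells closer than one diameter: warning flag, not an error
  near <- list(cell_spec("adherent", 30, 30), cell_spec("adherent", 36, 30))
  out <- generate_field_stack(near, cfg, noise_sigma = 0, seed = 1)
  expect_true(out$truth$overlap_warning)
  far <- list(cell_spec("adherent", 15, 15), cell_spec("adherent", 45, 45))
  expect_false(generate_field_stack(far, cfg, seed = 1)$truth$overlap_warning)
})

test_that("cell_spec enforces class invariants", {
  expect_error(cell_spec("adherent", 1, 1, velocity_um_s = 5),
    class = "chamberflow_parameter_error")
  expect_error(cell_spec("rolling", 1, 1, velocity_um_s = 0),
    class = "chamberflow_parameter_error")
  expect_error(cell_spec("freestream", 1, 1, focus_blur_sigma_um = 0),
    class = "chamberflow_parameter_error")
  expect_error(cell_spec("rolling", 1, 1, radius_um = -2),
    class = "chamberflow_parameter_error")
})

test_that("ground-truth counts equal an independent enumeration of the specs", {
  cohort <- cohort_preset("old", "LPS", n_donors = 2, seed = 9)
  for (fld in cohort$fields) {
    df <- scene_as_data_frame(fld$scene)
    expect_identical(fld$true_n_adherent, sum(df$class == "adherent"))
    expect_identical(fld$true_n_rolling, sum(df$class == "rolling"))
    out <- generate_field_stack(fld$scene, default_cfg, seed = fld$field_seed)
    expect_equal(out$truth$n_adherent, sum(df$class == "adherent"))
    expect_equal(out$truth$n_rolling, sum(df$class == "rolling"))
    expect_length(out$truth$rolling_velocities, out$truth$n_rolling)
  }
})

test_that("cohort presets are reproducible and reject unknown labels", {
  a <- cohort_preset("young", "control", n_donors = 3, seed = 4)
  b <- cohort_preset("young", "control", n_donors = 3, seed = 4)
  expect_identical(a$donors, b$donors)
  expect_identical(
    scene_as_data_frame(a$fields[[5]]$scene),
    scene_as_data_frame(b$fields[[5]]$scene)
  )
  expect_error(cohort_preset("young", "nonsense"),
    class = "chamberflow_parameter_error")
  # uncoated control: hardly any adhesion
  un <- cohort_preset("young", "uncoated", n_donors = 20, seed = 2)
  expect_lt(mean(un$donors$expected_adherent_density_mm2), 2)
})

test_that("stack TIFF round trip preserves frames; wrong counts are refused", {
  cfg <- acquisition_config(
    frame_rate = 5, duration = 4, field_width_um = 64, field_height_um = 48
  )
  scene <- build_scene(2, 1, config = cfg, velocity_range = c(5, 8), seed = 6)
  out <- generate_field_stack(scene, cfg, noise_sigma = 4, seed = 6)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(out$stack, path)
  back <- read_stack_tiff(path, cfg)
  expect_identical(back$frames, out$stack$frames)
  # truncated stack: frame count no longer matches the configuration
  short <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(
    lapply(out$stack$frames[1:19], function(f) f / 255), short,
    bits.per.sample = 8
  )
  expect_error(read_stack_tiff(short, cfg), class = "chamberflow_format_error")
  expect_error(read_stack_tiff("nope.tif", cfg), class = "chamberflow_format_error")
})

test_that("ground truth exports as CSV with a JSON sidecar", {
  cfg <- acquisition_config(
    frame_rate = 5, duration = 4, field_width_um = 64, field_height_um = 64
  )
  scene <- list(cell_spec("adherent", 20, 20), cell_spec("rolling", 40, 10, velocity_um_s = 8))
  out <- generate_field_stack(scene, cfg, seed = 2)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_ground_truth(out$truth, cfg, csv)
  df <- read.csv(csv)
  expect_identical(nrow(df), 2L)
  expect_setequal(df$class, c("adherent", "rolling"))
  side <- jsonlite::read_json(paste0(csv, ".json"))
  expect_equal(side$n_adherent, 1)
  expect_equal(side$seed, 2)
})
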