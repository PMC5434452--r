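#' Run configuration for an end-to-end simulated experiment
#'
#' Bundles everything a reproducible run needs: the acquisition settings,
#' detector settings, which cohort presets to simulate with how many donors,
#' the master seed, noise level, and the output directory. A run is fully
#' determined by its `run_config`; the configuration (and its hash) is
#' written alongside every output.
#'
#' @param acquisition An [acquisition_config()].
#' @param detector A [detector_config()].
#' @param groups Data frame with columns `age_group`, `treatment`, and
#'   optionally `n_donors` (defaults to the emulated cohort sizes). Default:
#'   the four control/LPS cohorts.
#' @param seed Master seed; per-group and per-field seeds are derived from
#'   it by a fixed splitting rule.
#' @param noise_sigma Additive Gaussian noise SD for rendered stacks
#'   (default 4 grayscale units).
#' @param out_dir Output directory.
#' @param write_stacks Also write every rendered stack as multi-page TIFF
#'   (default `FALSE`; stacks are large).
#' @return An object of class `run_config`.
#' @export
run_config <- function(acquisition = acquisition_config(),
                       detector = detector_config(),
                       groups = NULL,
                       seed = 1,
                       noise_sigma = 4,
                       out_dir = tempfile("chamberflow_run_"),
                       write_stacks = FALSE) {
  if (is.null(groups)) {
    groups <- expand.grid(
      age_group = c("young", "old"),
      treatment = c("control", "LPS"),
      stringsAsFactors = FALSE
    )
  }
  if (!all(c("age_group", "treatment") %in% names(groups))) {
    stop_config("`groups` needs columns age_group and treatment")
  }
  tab <- cohort_preset_table()
  known <- paste(tab$age_group, tab$treatment)
  bad <- !(paste(groups$age_group, groups$treatment) %in% known)
  if (any(bad)) {
    stop_config(sprintf(
      "unknown preset(s): %s",
      paste(groups$age_group[bad], groups$treatment[bad], collapse = ", ")
    ))
  }
  if (noise_sigma < 0) stop_config("`noise_sigma` must be non-negative")
  structure(
    list(
      acquisition = acquisition,
      detector = detector,
      groups = groups,
      seed = as.integer(seed),
      noise_sigma = noise_sigma,
      out_dir = out_dir,
      write_stacks = isTRUE(write_stacks)
    ),
    class = "run_config"
  )
}

config_as_list <- function(config) {
  list(
    acquisition = unclass(config$acquisition),
    detector = unclass(config$detector),
    groups = config$groups,
    seed = config$seed,
    noise_sigma = config$noise_sigma,
    write_stacks = config$write_stacks
  )
}

#' Serialize / restore a run configuration
#'
#' @param config A [run_config()].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config_as_list(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("no such config file: %s", path))
  x <- yaml::read_yaml(path)
  run_config(
    acquisition = do.call(acquisition_config, x$acquisition),
    detector = do.call(detector_config, x$detector),
    groups = as.data.frame(do.call(cbind, x$groups)),
    seed = x$seed,
    noise_sigma = x$noise_sigma,
    write_stacks = isTRUE(x$write_stacks)
  )
}

#' Quantify one field stack end to end
#'
#' Applies the projection-subtraction classification and the velocimetry
#' chain to one in-memory stack.
#'
#' @param stack A [frame_stack()].
#' @param detector A [detector_config()].
#' @return A list with `quantification` (a `field_quantification`) and
#'   `velocimetry` (see [measure_field_velocities()]).
#' @export
quantify_stack <- function(stack, detector = detector_config()) {
  list(
    quantification = classify_field(stack, detector),
    velocimetry = measure_field_velocities(stack, detector)
  )
}

#' Quantify a stack stored as multi-page TIFF
#'
#' Reads a user-supplied (real or synthetic) time-lapse TIFF, validates the
#' frame count and raster shape against the acquisition configuration, and
#' runs the full per-field quantification.
#'
#' @param path Path to a grayscale multi-page TIFF with at least 4 s of
#'   frames at the configured rate.
#' @param config An [acquisition_config()] describing the acquisition.
#' @param detector A [detector_config()].
#' @return As [quantify_stack()].
#' @export
quantify_stack_file <- function(path,
                                config = acquisition_config(),
                                detector = detector_config()) {
  stack <- read_stack_tiff(path, config)
  quantify_stack(stack, detector)
}

render_and_quantify_field <- function(field, config, detector, noise_sigma) {
  gen <- generate_field_stack(
    field$scene, config,
    noise_sigma = noise_sigma, seed = field$field_seed
  )
  q <- quantify_stack(gen$stack, detector)
  list(gen = gen, q = q)
}

#' Run a full simulated flow-chamber experiment
#'
#' The end-to-end pipeline: for every configured cohort preset, draw donors
#' and per-field scenes, render each field's time-lapse stack, quantify it
#' (snapshot / minimization counts, subtraction, densities, streak
#' velocimetry), aggregate fields to donor records, and run the group
#' statistics (young-vs-old and control-vs-LPS comparisons with the
#' normality gate, the two-way age x LPS ANOVA, and per-donor LPS response
#' ratios where both treatments were simulated).
#'
#' Outputs written to `config$out_dir`:
#' \itemize{
#'   \item `fields.csv` -- one row per field: counts, densities, number of
#'     velocity measurements, ground-truth counts;
#'   \item `velocities.csv` -- one row per retained velocity measurement;
#'   \item `donors.csv` -- one row per donor x treatment with aggregated
#'     densities and mean velocity;
#'   \item `stats_report.txt` -- human-readable group summaries and tests;
#'   \item `run_log.json` -- config (with MD5 hash), seeds, versions.
#' }
#'
#' @param config A [run_config()].
#' @return A list with `fields`, `velocities`, `donors` (data frames),
#'   `stats` (list of test objects), and `paths` of the written files.
#' @export
run_experiment <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop_config(sprintf("cannot create output dir: %s", out_dir))
  acq <- config$acquisition
  det <- config$detector

  field_rows <- list()
  vel_rows <- list()
  donor_rows <- list()

  for (g in seq_len(nrow(config$groups))) {
    age <- config$groups$age_group[g]
    trt <- config$groups$treatment[g]
    n_donors <- if ("n_donors" %in% names(config$groups)) config$groups$n_donors[g] else NULL
    group_seed <- field_seed(config$seed, 1000 + g)
    cohort <- cohort_preset(age, trt, n_donors = n_donors, config = acq, seed = group_seed)
    message(sprintf(
      "group %s/%s: %d donors x %d fields", age, trt,
      nrow(cohort$donors), acq$n_fields_per_chamber
    ))

    per_donor <- split(cohort$fields, vapply(cohort$fields, `[[`, "", "donor_id"))
    for (donor_id in cohort$donors$donor_id) {
      dfields <- per_donor[[donor_id]]
      dens_adh <- numeric(0)
      dens_rol <- numeric(0)
      vels <- numeric(0)
      for (fld in dfields) {
        res <- render_and_quantify_field(fld, acq, det, config$noise_sigma)
        qq <- res$q$quantification
        vv <- res$q$velocimetry
        if (config$write_stacks) {
          write_stack_tiff(res$gen$stack, file.path(
            out_dir, sprintf("%s_f%d.tif", donor_id, fld$field_index)
          ))
        }
        field_rows[[length(field_rows) + 1]] <- data.frame(
          donor_id = donor_id, age_group = age, treatment = trt,
          field_index = fld$field_index,
          total_count = qq$total_count,
          adherent_count = qq$adherent_count,
          rolling_count = qq$rolling_count,
          adherent_density_mm2 = qq$adherent_density_mm2,
          rolling_density_mm2 = qq$rolling_density_mm2,
          n_velocities = length(vv$velocities_um_s),
          clamped = qq$clamped,
          true_n_adherent = res$gen$truth$n_adherent,
          true_n_rolling = res$gen$truth$n_rolling
        )
        if (nrow(vv$measurements)) {
          m <- vv$measurements
          vel_rows[[length(vel_rows) + 1]] <- data.frame(
            donor_id = donor_id, age_group = age, treatment = trt,
            field_index = fld$field_index,
            velocity_um_s = m$velocity_um_s,
            major_length_um = m$major_length_um,
            minor_width_um = m$minor_width_um,
            orientation_deg = m$orientation_deg,
            over_cap = m$over_cap,
            ambiguous = m$ambiguous
          )
        }
        dens_adh <- c(dens_adh, qq$adherent_density_mm2)
        dens_rol <- c(dens_rol, qq$rolling_density_mm2)
        vels <- c(vels, vv$velocities_um_s)
      }
      donor_rows[[length(donor_rows) + 1]] <- data.frame(
        donor_id = donor_id,
        age_group = age,
        gender = cohort$donors$gender[cohort$donors$donor_id == donor_id],
        treatment = trt,
        adherent_density_mm2 = mean(dens_adh),
        rolling_density_mm2 = mean(dens_rol),
        mean_velocity_um_s = if (length(vels)) mean(vels) else NA_real_,
        n_fields = length(dfields),
        n_velocities = length(vels)
      )
    }
  }

  fields <- do.call(rbind, field_rows)
  velocities <- if (length(vel_rows)) do.call(rbind, vel_rows) else NULL
  donors <- do.call(rbind, donor_rows)

  stats <- donor_statistics(donors)

  paths <- list(
    fields = file.path(out_dir, "fields.csv"),
    velocities = file.path(out_dir, "velocities.csv"),
    donors = file.path(out_dir, "donors.csv"),
    report = file.path(out_dir, "stats_report.txt"),
    log = file.path(out_dir, "run_log.json"),
    config = file.path(out_dir, "run_config.yaml")
  )
  utils::write.csv(fields, paths$fields, row.names = FALSE)
  if (!is.null(velocities)) {
    utils::write.csv(velocities, paths$velocities, row.names = FALSE)
  } else {
    utils::write.csv(
      data.frame(donor_id = character(), velocity_um_s = numeric()),
      paths$velocities, row.names = FALSE
    )
  }
  utils::write.csv(donors, paths$donors, row.names = FALSE)
  write_run_config(config, paths$config)
  writeLines(format_stats_report(donors, stats), paths$report)
  jsonlite::write_json(
    list(
      config = config_as_list(config),
      config_md5 = unname(tools::md5sum(paths$config)),
      seed = config$seed,
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("chamberflow")),
      timestamp = format(Sys.time(), tz = "UTC")
    ),
    paths$log, auto_unbox = TRUE, digits = NA
  )
  list(fields = fields, velocities = velocities, donors = donors,
       stats = stats, paths = paths)
}

#' Donor-level statistics for a run
#'
#' @param donors Donor records data frame (as produced by
#'   [run_experiment()] or read from `donors.csv`).
#' @return A list of `group_comparison` / `anova_result` objects (present
#'   when the needed groups exist) plus LPS response ratios per age group.
#' @export
donor_statistics <- function(donors) {
  stats <- list()
  get <- function(age, trt, col) {
    donors[[col]][donors$age_group == age & donors$treatment == trt]
  }
  have <- function(age, trt) sum(donors$age_group == age & donors$treatment == trt) >= 3

  pairs <- list(
    adhesion_young_vs_old_control = list("control", "adherent_density_mm2"),
    rolling_young_vs_old_control = list("control", "rolling_density_mm2"),
    velocity_young_vs_old_control = list("control", "mean_velocity_um_s"),
    adhesion_young_vs_old_LPS = list("LPS", "adherent_density_mm2")
  )
  for (nm in names(pairs)) {
    trt <- pairs[[nm]][[1]]
    col <- pairs[[nm]][[2]]
    if (have("young", trt) && have("old", trt)) {
      stats[[nm]] <- compare_two_groups(
        get("young", trt, col), get("old", trt, col),
        label_a = paste0("young/", trt), label_b = paste0("old/", trt)
      )
    }
  }
  for (age in c("young", "old")) {
    if (have(age, "control") && have(age, "LPS")) {
      stats[[paste0("adhesion_", age, "_control_vs_LPS")]] <- compare_two_groups(
        get(age, "control", "adherent_density_mm2"),
        get(age, "LPS", "adherent_density_mm2"),
        label_a = paste0(age, "/control"), label_b = paste0(age, "/LPS")
      )
    }
  }
  four <- all(
    vapply(c("young", "old"), function(a) have(a, "control") && have(a, "LPS"), logical(1))
  )
  if (four) {
    stats$anova_age_lps <- two_way_anova_age_lps(donors)
    ratios <- list()
    for (age in c("young", "old")) {
      ctrl <- get(age, "control", "adherent_density_mm2")
      stim <- get(age, "LPS", "adherent_density_mm2")
      n <- min(length(ctrl), length(stim))
      ok <- ctrl[seq_len(n)] > 0
      rr <- lps_response_ratio(stim[seq_len(n)][ok], ctrl[seq_len(n)][ok])
      ratios[[age]] <- rr$ratio
    }
    rv <- c(ratios$young, ratios$old)
    ga <- rep(c("young", "old"), c(length(ratios$young), length(ratios$old)))
    if (all(table(ga) >= 2)) {
      stats$lps_response_variance <- response_variance_by_group(rv, ga)
    }
    stats$lps_response_ratios <- data.frame(age_group = ga, ratio = rv)
  }
  stats
}

format_stats_report <- function(donors, stats) {
  lines <- c("Flow-chamber quantification: donor-level statistics", "")
  agg <- stats::aggregate(
    cbind(adherent_density_mm2, rolling_density_mm2, mean_velocity_um_s) ~
      age_group + treatment,
    data = donors, FUN = function(x) c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
  )
  lines <- c(lines, "Group summaries (mean +/- SEM):")
  for (i in seq_len(nrow(agg))) {
    a <- agg[i, ]
    lines <- c(lines, sprintf(
      "  %s/%s: adherent %.1f +/- %.1f /mm2; rolling %.1f +/- %.1f /mm2; velocity %.1f +/- %.1f um/s",
      a$age_group, a$treatment,
      a$adherent_density_mm2[1], a$adherent_density_mm2[2],
      a$rolling_density_mm2[1], a$rolling_density_mm2[2],
      a$mean_velocity_um_s[1], a$mean_velocity_um_s[2]
    ))
  }
  lines <- c(lines, "")
  for (nm in names(stats)) {
    obj <- stats[[nm]]
    if (inherits(obj, "group_comparison")) {
      lines <- c(lines, sprintf(
        "%s [%s]: p = %.4g (%s)", nm, obj$test_name, obj$p_value,
        obj$significance_symbol
      ))
    } else if (inherits(obj, "anova_result")) {
      lines <- c(lines, sprintf(
        "%s: age p = %.4g (%s); LPS p = %.4g (%s); interaction p = %.4g (%s)",
        nm,
        obj$factor_p_values["age"], obj$symbols["age"],
        obj$factor_p_values["lps"], obj$symbols["lps"],
        obj$factor_p_values["interaction"], obj$symbols["interaction"]
      ))
    } else if (nm == "lps_response_variance") {
      lines <- c(lines, sprintf(
        "LPS response variance: young %.3f, old %.3f (young more heterogeneous: %s)",
        obj$variance["young"], obj$variance["old"], obj$young_more_heterogeneous
      ))
    }
  }
  lines
}
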