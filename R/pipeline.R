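#' Run the full droplet phage-detection pipeline
#'
#' Chains every analysis stage over one configuration: obtain events
#' (either read from a CSV or simulated), size-filter and threshold them,
#' estimate the mean phage load per droplet from the negative fraction at a
#' reference timepoint, and optionally compute a plaque-titer time course
#' and plate recovery statistics. All stage outputs are written as CSVs
#' into `output_dir` together with one machine-readable `summary.json`
#' that echoes every parameter used; identical config + seed gives
#' identical outputs.
#'
#' The configuration is a named list (or a YAML file path, see
#' [read_pipeline_config()]) with blocks:
#' * `events`: path to an event CSV, **or** `simulation`: a block of
#'   [sim_config()] keys (exactly one of the two must be present; a seed is
#'   required when simulating);
#' * `gate`: [gate_policy()] keys (optional; defaults apply);
#' * `geometry`: `diameter_um` and/or `volume_pL` (optional; default
#'   volume 18.8 pL);
#' * `reference_timepoint_h`: timepoint whose negative fraction feeds the
#'   occupancy estimate (default 5);
#' * `plaques`: path to a plaque-count CSV for [titer_timecourse()]
#'   (optional);
#' * `plates`: path to a well-outcome CSV for [read_plate_table()]
#'   (optional).
#'
#' @param config Named list or YAML path.
#' @param output_dir Directory for the report bundle (created if needed).
#' @return Invisibly, a list with `gate_summary`, `occupancy`, `titer`,
#'   `recovery`, `summary` (the parsed contents of `summary.json`).
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  stopifnot(is.list(config))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  has_events <- !is.null(config$events)
  has_sim <- !is.null(config$simulation)
  if (has_events == has_sim) {
    stop("Supply exactly one event source: `events` (a CSV path) or ",
         "`simulation` (a config block).", call. = FALSE)
  }

  # --- stage 1: events --------------------------------------------------
  sim_cfg <- NULL
  if (has_sim) {
    sim_cfg <- do.call(sim_config, config$simulation)
    sim <- simulate_experiment(sim_cfg)
    events <- sim$events
    write_event_table(events, file.path(output_dir, "events.csv"))
    readr::write_csv(sim$truth, file.path(output_dir, "latent_truth.csv"))
  } else {
    events <- read_event_table(config$events)
  }

  # --- stage 2: gating --------------------------------------------------
  policy <- do.call(gate_policy, config$gate %||% list())
  control <- dplyr::filter(events, .data$condition == "no_phage")
  if (policy$threshold_mode == "from_negative_control" &&
      nrow(control) == 0) {
    stop("Stage 'gate' failed: threshold mode 'from_negative_control' but ",
         "the event table has no `no_phage` rows.", call. = FALSE)
  }
  ref_t <- config$reference_timepoint_h %||% 5
  control_ref <- dplyr::filter(control, .data$timepoint_h == ref_t)
  gate_summary <- classify_and_summarize(
    events, policy,
    control_events = if (nrow(control_ref)) control_ref else control
  )
  readr::write_csv(gate_summary, file.path(output_dir, "gate_summary.csv"))

  # --- stage 3: occupancy -----------------------------------------------
  geometry <- if (!is.null(config$geometry)) {
    do.call(droplet_geometry, config$geometry)
  } else {
    droplet_geometry(volume_pL = 18.8)
  }
  phage_ref <- dplyr::filter(gate_summary, .data$condition == "phage",
                             .data$timepoint_h == ref_t)
  occupancy <- NULL
  if (nrow(phage_ref) == 1 && phage_ref$fluorescent_fraction < 1) {
    occupancy <- lambda_from_negative_fraction(
      1 - phage_ref$fluorescent_fraction, phage_ref$n_after_size_filter)
    occupancy$implied_conc_pfu_per_ml <-
      occupancy$lambda_hat / (geometry$volume_pL * 1e-9)
    readr::write_csv(occupancy, file.path(output_dir, "occupancy.csv"))
  }

  # --- stage 4 (optional): titer ----------------------------------------
  titer <- NULL
  if (!is.null(config$plaques)) {
    plaques <- readr::read_csv(config$plaques, show_col_types = FALSE)
    titer <- titer_timecourse(
      plaques,
      aliquot_volume_uL = config$aliquot_volume_uL %||% 8,
      recovery_dilution = config$recovery_dilution %||% 1
    )
    readr::write_csv(titer, file.path(output_dir, "titer.csv"))
  }

  # --- stage 5 (optional): recovery -------------------------------------
  recovery <- NULL
  if (!is.null(config$plates)) {
    plates <- read_plate_table(config$plates)
    recovery <- dplyr::bind_rows(lapply(plates, function(p) {
      tibble::tibble(gate_label = p$gate_label, n_positive = p$n_positive,
                     n_total = p$n_total, n_excluded = p$n_excluded,
                     recovery_rate = p$recovery_rate,
                     ci_low = p$ci_low, ci_high = p$ci_high)
    }))
    readr::write_csv(recovery, file.path(output_dir, "recovery.csv"))
  }

  # --- report ----------------------------------------------------------
  summary <- list(
    parameters = list(
      event_source = if (has_sim) "simulation" else config$events,
      simulation = if (has_sim) unclass(sim_cfg) else NULL,
      gate = unclass(policy),
      geometry = unclass(geometry),
      reference_timepoint_h = ref_t
    ),
    gate_summary = gate_summary,
    occupancy = occupancy,
    titer = titer,
    recovery = recovery
  )
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(gate_summary = gate_summary, occupancy = occupancy,
                 titer = titer, recovery = recovery, summary = summary))
}
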