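#' Simulation configuration for synthetic droplet experiments
#'
#' Bundles every latent parameter of the synthetic event generator: Poisson
#' co-encapsulation of phage particles and host cells, a deterministic
#' burst-cycle propagation ladder, a multiplicative-noise fluorescence /
#' forward-scatter signal model, and a phenomenological "starvation
#' artifact" channel that gives a small fraction of phage-free, cell-rich
#' droplets a medium fluorescence at late timepoints (mimicking dye leakage
#' into starved host cells).
#'
#' Defaults mirror a typical droplet co-cultivation run: ~30 um droplets
#' (5% CV), host cells loaded at 1e9 cells/mL into an 18.8 pL effective
#' volume (hence `lambda_cells = 19`), seven timepoints from 0 to 24 h with
#' 40,000 measured droplets each. The microbiological free parameters —
#' burst size, latent period, fluorescence gain per stained genome — are
#' not pinned down by droplet-level data; the defaults (burst 100, latent
#' 1 h, 0.01 a.u./genome over a baseline of 10 a.u.) are representative of
#' a T-even coliphage and produce the qualitative signal structure such
#' assays show: a low-fluorescence majority, a propagation-driven
#' high-fluorescence subpopulation growing over incubation time, and a rare
#' medium-intensity artifact group appearing late even without phage.
#'
#' @param lambda_phage Mean phage particles per droplet (>= 0).
#' @param lambda_cells Mean host cells per droplet (>= 0; default 19).
#' @param diameter_mean_um Mean droplet diameter in um (default 30).
#' @param diameter_cv Coefficient of variation of the diameter (default 0.05).
#' @param timepoints_h Incubation times in hours (default 0,1,3,5,7,9,24).
#' @param n_droplets Events rendered per timepoint (default 40000).
#' @param latent_period_h Time before the first progeny release, hours
#'   (default 1).
#' @param burst_size Progeny genomes per infected cell per cycle (> 1;
#'   default 100).
#' @param genome_cap Maximum stained genome copies per droplet, the
#'   host-resource ceiling (default 1e5).
#' @param fl_baseline Mean background fluorescence, a.u. (default 10).
#' @param fl_per_genome Fluorescence gain per genome copy, a.u.
#'   (default 0.01).
#' @param fl_noise_cv CV of the multiplicative lognormal measurement noise
#'   applied to both channels (default 0.25).
#' @param artifact_prob Probability that an eligible phage-free droplet
#'   (more cells than average, past `artifact_onset_h`) reads at the
#'   artifact intensity (default 0.01).
#' @param artifact_onset_h Earliest time the artifact can appear, hours
#'   (default 7).
#' @param artifact_intensity Mean artifact fluorescence, a.u.; must lie
#'   strictly between the baseline and the full-propagation level
#'   (default 200).
#' @param fsc_gain Forward-scatter units per um^2 of droplet cross-section
#'   (default 1).
#' @param seed RNG seed (required; every stochastic claim about the
#'   simulator must be replayable).
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(lambda_phage = 0.2, n_droplets = 1000, seed = 1)
#' @export
sim_config <- function(lambda_phage,
                       lambda_cells = 19,
                       diameter_mean_um = 30,
                       diameter_cv = 0.05,
                       timepoints_h = c(0, 1, 3, 5, 7, 9, 24),
                       n_droplets = 40000,
                       latent_period_h = 1,
                       burst_size = 100,
                       genome_cap = 1e5,
                       fl_baseline = 10,
                       fl_per_genome = 0.01,
                       fl_noise_cv = 0.25,
                       artifact_prob = 0.01,
                       artifact_onset_h = 7,
                       artifact_intensity = 200,
                       fsc_gain = 1,
                       seed) {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: simulated experiments must be replayable.",
         call. = FALSE)
  }
  cfg <- list(
    lambda_phage = lambda_phage, lambda_cells = lambda_cells,
    diameter_mean_um = diameter_mean_um, diameter_cv = diameter_cv,
    timepoints_h = timepoints_h, n_droplets = n_droplets,
    latent_period_h = latent_period_h, burst_size = burst_size,
    genome_cap = genome_cap, fl_baseline = fl_baseline,
    fl_per_genome = fl_per_genome, fl_noise_cv = fl_noise_cv,
    artifact_prob = artifact_prob, artifact_onset_h = artifact_onset_h,
    artifact_intensity = artifact_intensity, fsc_gain = fsc_gain,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(num1(cfg$lambda_phage) && cfg$lambda_phage >= 0,
      "`lambda_phage` must be a single non-negative number.")
  chk(num1(cfg$lambda_cells) && cfg$lambda_cells >= 0,
      "`lambda_cells` must be a single non-negative number.")
  chk(num1(cfg$diameter_mean_um) && cfg$diameter_mean_um > 0,
      "`diameter_mean_um` must be positive.")
  chk(num1(cfg$diameter_cv) && cfg$diameter_cv >= 0,
      "`diameter_cv` must be non-negative.")
  chk(is.numeric(cfg$timepoints_h) && length(cfg$timepoints_h) >= 1 &&
        all(cfg$timepoints_h >= 0) && !anyDuplicated(cfg$timepoints_h),
      "`timepoints_h` must be distinct non-negative times.")
  chk(num1(cfg$n_droplets) && cfg$n_droplets >= 1,
      "`n_droplets` must be at least 1.")
  chk(num1(cfg$latent_period_h) && cfg$latent_period_h > 0,
      "`latent_period_h` must be positive.")
  chk(num1(cfg$burst_size) && cfg$burst_size > 1,
      "`burst_size` must exceed 1.")
  chk(num1(cfg$genome_cap) && cfg$genome_cap >= 1,
      "`genome_cap` must be at least 1.")
  chk(num1(cfg$fl_baseline) && cfg$fl_baseline >= 0,
      "`fl_baseline` must be non-negative.")
  chk(num1(cfg$fl_per_genome) && cfg$fl_per_genome >= 0,
      "`fl_per_genome` must be non-negative.")
  chk(num1(cfg$fl_noise_cv) && cfg$fl_noise_cv >= 0,
      "`fl_noise_cv` must be non-negative.")
  chk(num1(cfg$artifact_prob) && cfg$artifact_prob >= 0 &&
        cfg$artifact_prob <= 1,
      "`artifact_prob` must lie in [0, 1].")
  chk(num1(cfg$artifact_onset_h) && cfg$artifact_onset_h >= 0,
      "`artifact_onset_h` must be non-negative.")
  fl_max <- cfg$fl_baseline + cfg$fl_per_genome * cfg$genome_cap
  chk(num1(cfg$artifact_intensity) &&
        cfg$artifact_intensity > cfg$fl_baseline &&
        cfg$artifact_intensity < fl_max,
      paste0("`artifact_intensity` must lie strictly between the baseline (",
             cfg$fl_baseline, ") and the full-propagation level (",
             fl_max, ")."))
  chk(num1(cfg$fsc_gain) && cfg$fsc_gain > 0, "`fsc_gain` must be positive.")
  chk(num1(cfg$seed), "`seed` must be a single integer.")
  invisible(cfg)
}

#' Draw the latent droplet population
#'
#' Co-encapsulation of phage particles and host cells is modelled as two
#' independent Poisson processes: each droplet receives
#' `n_phage ~ Poisson(lambda_phage)` particles and
#' `n_cells ~ Poisson(lambda_cells)` cells. Diameters are lognormal with
#' the configured mean and CV (strictly positive, monodisperse as CV -> 0).
#'
#' @param config A [sim_config()].
#' @return A tibble of latent droplet states: `droplet_id`, `n_phage`,
#'   `n_cells`, `diameter_um`.
#' @examples
#' states <- simulate_encapsulation(sim_config(0.08, n_droplets = 500, seed = 7))
#' mean(states$n_phage == 0)  # ~ exp(-0.08)
#' @export
simulate_encapsulation <- function(config) {
  validate_sim_config(config)
  n <- config$n_droplets
  withr::with_seed(config$seed, {
    tibble::tibble(
      droplet_id = seq_len(n),
      n_phage = stats::rpois(n, config$lambda_phage),
      n_cells = stats::rpois(n, config$lambda_cells),
      diameter_um = rlnorm_mean_cv(n, config$diameter_mean_um,
                                   config$diameter_cv)
    )
  })
}

#' Stained genome copies in a droplet after incubation
#'
#' Deterministic burst-cycle ladder: a droplet that holds at least one phage
#' and at least one host cell completes \eqn{\lfloor t / T_L \rfloor}
#' infection cycles by time `t` (latent period \eqn{T_L}), each multiplying
#' the genome count by the burst size, saturating at the host-resource cap:
#' \deqn{g(t) = \min(\mathrm{cap},\; n_{phage} \cdot B^{\lfloor t/T_L \rfloor}).}
#' Droplets without phage or without cells keep `n_phage` copies at all
#' times. The function is pure (no RNG), vectorised over droplets, and
#' monotone non-decreasing in `t_h`.
#'
#' @param n_phage,n_cells Initial particle and cell counts (vectors).
#' @param config A [sim_config()] supplying latent period, burst size, cap.
#' @param t_h Incubation time in hours (single value, >= 0).
#' @return Integer-valued numeric vector of genome-equivalent copies.
#' @examples
#' cfg <- sim_config(0.2, n_droplets = 1, seed = 1)
#' simulate_propagation(1, 1, cfg, t_h = 5)
#' @export
simulate_propagation <- function(n_phage, n_cells, config, t_h) {
  validate_sim_config(config)
  stopifnot(is.numeric(t_h), length(t_h) == 1, t_h >= 0)
  stopifnot(length(n_phage) == length(n_cells))
  cycles <- floor(t_h / config$latent_period_h)
  grown <- pmin(config$genome_cap, n_phage * config$burst_size^cycles)
  ifelse(n_phage == 0 | n_cells == 0 | t_h < config$latent_period_h,
         n_phage, grown)
}

#' Render latent droplets into a measured event table
#'
#' Turns latent droplet states into one cytometry-like event row per
#' droplet at timepoint `t_h`:
#' * fluorescence = (baseline + gain x genome copies) x lognormal noise,
#'   with the artifact channel replacing the mean for eligible phage-free
#'   droplets (those with more cells than the configured average, past the
#'   artifact onset, selected with probability `artifact_prob`);
#' * forward scatter = `fsc_gain` x cross-sectional area x lognormal noise.
#'
#' Rendering is deterministic for a fixed config: the RNG stream is keyed
#' on the config seed and the index of `t_h` within `config$timepoints_h`
#' (so each timepoint gets an independent, reproducible noise draw).
#'
#' @param states Latent states from [simulate_encapsulation()].
#' @param config The same [sim_config()] the states were generated with.
#' @param t_h One of `config$timepoints_h`.
#' @param sample_id Label written into the `sample_id` column.
#' @param condition `"phage"` or `"no_phage"` label for the output.
#' @return An event tibble: `droplet_id`, `sample_id`, `condition`,
#'   `timepoint_h`, `fsc`, `fluorescence`.
#' @export
render_events <- function(states, config, t_h, sample_id = "sim",
                          condition = c("phage", "no_phage")) {
  validate_sim_config(config)
  condition <- match.arg(condition)
  t_idx <- match(t_h, config$timepoints_h)
  if (is.na(t_idx)) {
    stop("`t_h` (", t_h, ") is not one of the configured timepoints.",
         call. = FALSE)
  }
  n <- nrow(states)
  genomes <- simulate_propagation(states$n_phage, states$n_cells, config, t_h)
  withr::with_seed(config$seed + 1000L * t_idx, {
    fl_mean <- config$fl_baseline + config$fl_per_genome * genomes
    eligible <- states$n_phage == 0 &
      states$n_cells > config$lambda_cells &
      t_h >= config$artifact_onset_h
    is_artifact <- eligible & stats::runif(n) < config$artifact_prob
    fl_mean[is_artifact] <- config$artifact_intensity
    fluorescence <- fl_mean * rlnorm_mean_cv(n, 1, config$fl_noise_cv)
    area <- pi * (states$diameter_um / 2)^2
    fsc <- config$fsc_gain * area * rlnorm_mean_cv(n, 1, config$fl_noise_cv)
  })
  tibble::tibble(
    droplet_id = states$droplet_id,
    sample_id = sample_id,
    condition = condition,
    timepoint_h = t_h,
    fsc = fsc,
    fluorescence = fluorescence
  )
}

#' Simulate a full droplet co-cultivation experiment
#'
#' Draws one latent population per condition (with-phage at the configured
#' `lambda_phage`, plus an optional no-phage control at `lambda_phage = 0`)
#' and renders it at every configured timepoint, emulating repeated
#' cytometric reads of the same incubating emulsion.
#'
#' @param config A [sim_config()] for the with-phage sample.
#' @param control Logical; also simulate a matched no-phage control
#'   (default `TRUE`). The control reuses every parameter but sets
#'   `lambda_phage = 0` and offsets the seed so the two emulsions are
#'   independent.
#' @param sample_id Base label; conditions are suffixed `_phage` /
#'   `_no_phage`.
#' @return A list with `events` (all conditions and timepoints, row-bound)
#'   and `truth` (latent per-droplet states per condition, with genome
#'   copies at every timepoint in long format: `droplet_id`, `condition`,
#'   `n_phage`, `n_cells`, `diameter_um`, `timepoint_h`, `genomes`).
#' @examples
#' sim <- simulate_experiment(
#'   sim_config(0.2, n_droplets = 500, timepoints_h = c(0, 5), seed = 42))
#' table(sim$events$condition, sim$events$timepoint_h)
#' @export
simulate_experiment <- function(config, control = TRUE, sample_id = "sim") {
  validate_sim_config(config)
  configs <- list(phage = config)
  if (control) {
    ctl <- config
    ctl$lambda_phage <- 0
    ctl$seed <- config$seed + 499979L  # prime offset: independent emulsion
    configs$no_phage <- ctl
  }
  events <- list()
  truth <- list()
  for (cond in names(configs)) {
    cfg <- configs[[cond]]
    states <- simulate_encapsulation(cfg)
    ev <- lapply(cfg$timepoints_h, function(t_h) {
      render_events(states, cfg, t_h,
                    sample_id = paste(sample_id, cond, sep = "_"),
                    condition = cond)
    })
    events[[cond]] <- dplyr::bind_rows(ev)
    tr <- lapply(cfg$timepoints_h, function(t_h) {
      tibble::tibble(
        droplet_id = states$droplet_id, condition = cond,
        n_phage = states$n_phage, n_cells = states$n_cells,
        diameter_um = states$diameter_um, timepoint_h = t_h,
        genomes = simulate_propagation(states$n_phage, states$n_cells,
                                       cfg, t_h)
      )
    })
    truth[[cond]] <- dplyr::bind_rows(tr)
  }
  list(events = dplyr::bind_rows(events), truth = dplyr::bind_rows(truth))
}

# Lognormal draws parameterised by arithmetic mean and CV; degenerates to
# the constant mean when cv = 0.
rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog, sdlog)
}
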