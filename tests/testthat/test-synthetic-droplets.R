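test_that("encapsulation follows independent Poisson statistics", {
  # empty-droplet fraction tracks exp(-lambda) within binomial error
  for (lam in c(0.08, 0.8)) {
    cfg <- sim_config(lambda_phage = lam, n_droplets = 1e5, seed = 11)
    st <- simulate_encapsulation(cfg)
    p0 <- exp(-lam)
    expect_lt(abs(mean(st$n_phage == 0) - p0),
              3 * sqrt(p0 * (1 - p0) / 1e5))
  }

  # mean occupancy matches a direct Poisson-sampling oracle
  cfg <- sim_config(lambda_phage = 0.8, n_droplets = 1e5, seed = 12)
  st <- simulate_encapsulation(cfg)
  set.seed(13)
  oracle <- rpois(1e5, 0.8)
  se <- sqrt(0.8 / 1e5)  # Poisson mean SE
  expect_lt(abs(mean(st$n_phage) - 0.8), 3 * se)
  expect_lt(abs(mean(oracle) - mean(st$n_phage)), 3 * sqrt(2) * se)

  # degenerate rate: no phage anywhere
  st0 <- simulate_encapsulation(sim_config(0, n_droplets = 1000, seed = 14))
  expect_true(all(st0$n_phage == 0))

  # cells and phage are drawn independently
  expect_lt(abs(cor(st$n_phage, st$n_cells)), 3 / sqrt(1e5))
})

test_that("diameters are positive with the configured mean and CV", {
  cfg <- sim_config(0.1, n_droplets = 5e4, diameter_mean_um = 30,
                    diameter_cv = 0.05, seed = 15)
  d <- simulate_encapsulation(cfg)$diameter_um
  expect_true(all(d > 0))
  expect_lt(abs(mean(d) - 30), 3 * sd(d) / sqrt(5e4))
  expect_lt(abs(sd(d) / mean(d) - 0.05), 0.005)

  # monodisperse limit
  cfg0 <- sim_config(0.1, n_droplets = 100, diameter_cv = 0, seed = 16)
  expect_true(all(simulate_encapsulation(cfg0)$diameter_um == 30))
})

test_that("configuration is validated and a seed is mandatory", {
  expect_error(sim_config(lambda_phage = -1, seed = 1), "non-negative")
  expect_error(sim_config(0.1, n_droplets = 0, seed = 1), "at least 1")
  expect_error(sim_config(0.1, burst_size = 1, seed = 1), "exceed 1")
  expect_error(sim_config(0.1, artifact_intensity = 5, seed = 1),
               "strictly between")
  expect_error(sim_config(0.1), "seed")
})

test_that("propagation is a capped burst-cycle ladder", {
  cfg <- sim_config(0.1, latent_period_h = 1, burst_size = 100,
                    genome_cap = 1e5, seed = 17)

  # pre-latent identity and no-growth cases
  expect_equal(simulate_propagation(1, 1, cfg, 0), 1)
  expect_equal(simulate_propagation(1, 1, cfg, 0.99), 1)
  expect_equal(simulate_propagation(0, 5, cfg, 24), 0)
  expect_equal(simulate_propagation(3, 0, cfg, 24), 3)

  # step-by-step loop oracle: multiply by the burst each completed cycle
  loop_oracle <- function(n0, burst, latent, cap, t) {
    g <- n0
    tt <- latent
    while (tt <= t) {
      g <- min(cap, g * burst)
      tt <- tt + latent
    }
    g
  }
  for (t in c(0, 1, 2, 3, 5, 7, 24)) {
    expect_equal(simulate_propagation(1, 1, cfg, t),
                 loop_oracle(1, 100, 1, 1e5, t), info = paste("t =", t))
    expect_equal(simulate_propagation(2, 3, cfg, t),
                 loop_oracle(2, 100, 1, 1e5, t))
  }
  expect_equal(simulate_propagation(1, 1, cfg, 24), 1e5)

  # monotone non-decreasing in time, bounded by the cap
  traj <- vapply(seq(0, 24, by = 0.5),
                 function(t) simulate_propagation(1, 1, cfg, t), numeric(1))
  expect_true(all(diff(traj) >= 0))
  expect_true(all(traj <= 1e5))
})

test_that("rendering is reproducible and honours the signal model", {
  cfg <- quick_config(seed = 18)
  st <- simulate_encapsulation(cfg)

  # byte-identical replay of the same seed and config
  e1 <- render_events(st, cfg, 5)
  e2 <- render_events(st, cfg, 5)
  expect_identical(e1, e2)
  st_b <- simulate_encapsulation(cfg)
  expect_identical(st, st_b)

  # different timepoints use independent noise streams
  e0 <- render_events(st, cfg, 0)
  expect_false(identical(e0$fluorescence, e1$fluorescence))

  # unknown timepoint is rejected
  expect_error(render_events(st, cfg, 2), "not one of the configured")
})

test_that("baseline-only and gain-off renders are featureless", {
  # lambda 0, artifact off: fluorescence centred at the baseline
  cfg <- sim_config(0, n_droplets = 2e4, timepoints_h = c(0, 24),
                    artifact_prob = 0, fl_baseline = 10, seed = 19)
  st <- simulate_encapsulation(cfg)
  ev <- render_events(st, cfg, 24, condition = "no_phage")
  expect_lt(abs(mean(ev$fluorescence) - 10), 3 * sd(ev$fluorescence) / sqrt(2e4))

  # gain (effectively) off: with-phage and no-phage fluorescence
  # indistinguishable; the gain is kept infinitesimal rather than exactly
  # zero so the artifact-intensity ordering constraint stays satisfiable
  mk <- function(lam, seed) {
    cfg <- sim_config(lam, n_droplets = 5e3, timepoints_h = 5,
                      fl_per_genome = 1e-12, genome_cap = 1e12,
                      artifact_prob = 0, artifact_intensity = 10.5,
                      seed = seed)
    render_events(simulate_encapsulation(cfg), cfg, 5)
  }
  a <- mk(0.5, 20)
  b <- mk(0, 21)
  ks <- suppressWarnings(ks.test(a$fluorescence, b$fluorescence))
  expect_gt(ks$p.value, 0.001)
})

test_that("a propagated sample is bimodal and threshold-separable at 5 h", {
  cfg <- sim_config(0.2, lambda_cells = 19, n_droplets = 2e4,
                    timepoints_h = c(0, 5), seed = 22)
  sim <- simulate_experiment(cfg, control = FALSE)
  fl <- dplyr::filter(sim$events, timepoint_h == 5)$fluorescence

  dens <- density(log10(fl))
  peaks <- which(diff(sign(diff(dens$y))) == -2) + 1
  tall <- peaks[dens$y[peaks] > 0.05 * max(dens$y)]
  expect_gte(length(tall), 2)

  # a single cutoff separates the two modes: the gap region is empty
  expect_equal(sum(fl > 60 & fl < 300), 0)
  expect_gt(sum(fl <= 60), 0)
  expect_gt(sum(fl >= 300), 0)
})

test_that("the fluorescent fraction grows with incubation time", {
  cfg <- sim_config(0.3, n_droplets = 4e3,
                    timepoints_h = c(0, 1, 3, 5, 7, 9, 24),
                    artifact_prob = 0, fl_noise_cv = 0.05, seed = 23)
  sim <- simulate_experiment(cfg, control = FALSE)
  gs <- classify_and_summarize(sim$events, gate_policy(fixed_threshold = 130),
                               apply_size_filter = FALSE)
  gs <- dplyr::arrange(gs, timepoint_h)
  expect_true(all(diff(gs$fluorescent_fraction) >= 0))
})

test_that("occupancy estimates recover the simulated rate across replicates", {
  # gate simulated emulsions and invert the negative fraction; the true
  # rate should fall inside the 95% interval in >= 90 of 100 replicates
  for (lam in c(0.05, 0.2, 0.8)) {
    hits <- 0L
    for (r in seq_len(100)) {
      cfg <- sim_config(lam, n_droplets = 3000, timepoints_h = 5,
                        artifact_prob = 0, seed = 3000 + r)
      sim <- simulate_experiment(cfg, control = FALSE)
      gs <- classify_and_summarize(sim$events,
                                   gate_policy(fixed_threshold = 130))
      est <- lambda_from_negative_fraction(1 - gs$fluorescent_fraction,
                                           gs$n_after_size_filter)
      hits <- hits + (est$ci_low <= lam && lam <= est$ci_high)
    }
    expect_gte(hits, 90)
  }
})

test_that("the artifact channel appears only late, only without phage content", {
  cfg <- sim_config(0, lambda_cells = 19, n_droplets = 2e4,
                    timepoints_h = c(5, 24), artifact_prob = 0.02,
                    artifact_onset_h = 7, artifact_intensity = 200,
                    seed = 24)
  st <- simulate_encapsulation(cfg)
  early <- render_events(st, cfg, 5, condition = "no_phage")
  late <- render_events(st, cfg, 24, condition = "no_phage")

  # medium-intensity band is empty before onset, populated after
  expect_equal(sum(early$fluorescence > 100 & early$fluorescence < 400), 0)
  n_med <- sum(late$fluorescence > 100 & late$fluorescence < 400)
  expect_gt(n_med, 0)
  # roughly artifact_prob x P(cells above average) of droplets
  p_elig <- mean(st$n_cells > 19)
  expected <- 0.02 * p_elig * 2e4
  expect_lt(abs(n_med - expected), 3 * sqrt(expected) + 3)
})
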