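# Small, fast simulation configs used across test files.

quick_config <- function(lambda_phage = 0.2, n_droplets = 2000,
                         timepoints_h = c(0, 5), seed = 101, ...) {
  sim_config(lambda_phage = lambda_phage, n_droplets = n_droplets,
             timepoints_h = timepoints_h, seed = seed, ...)
}

# A hand-sized event table with known structure.
tiny_events <- function(fluorescence, fsc = NULL, timepoint_h = 0,
                        sample_id = "s1", condition = "phage") {
  n <- length(fluorescence)
  tibble::tibble(
    droplet_id = seq_len(n),
    sample_id = sample_id,
    condition = condition,
    timepoint_h = timepoint_h,
    fsc = if (is.null(fsc)) rep(100, n) else fsc,
    fluorescence = fluorescence
  )
}
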