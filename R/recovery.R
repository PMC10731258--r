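#' Digitize 96-well spot-assay outcomes for one sorting gate
#'
#' After single droplets are sorted into wells, ruptured and recultivated,
#' each well is read as a binary spot-assay call: `positive` (the well
#' solution cleared or disturbed the host lawn), `negative`, or `excluded`
#' (unusable well, e.g. contamination). This function reduces those calls
#' to counts and a recovery rate over the non-excluded wells; wells from
#' several plates under the same gate label may be concatenated.
#'
#' @param well_outcomes Character vector of outcomes in
#'   `{"positive", "negative", "excluded"}`, or a data frame with columns
#'   `well` and `outcome` (well IDs enable the disjointness check in
#'   [compare_gates()]).
#' @param gate_label Which sorting gate the wells came from, conventionally
#'   `"high_fluorescence"` or `"low_fluorescence"`.
#' @param conf_level Confidence level for the attached interval.
#' @return A list of class `plate_digitization`: `gate_label`,
#'   `n_positive`, `n_total` (non-excluded), `n_excluded`,
#'   `recovery_rate`, `ci_low`, `ci_high`, `wells` (IDs or `NULL`).
#' @examples
#' digitize_plate(rep(c("positive", "negative"), c(82, 148)),
#'                "high_fluorescence")
#' @export
digitize_plate <- function(well_outcomes, gate_label,
                           conf_level = 0.95) {
  wells <- NULL
  if (is.data.frame(well_outcomes)) {
    if (!all(c("well", "outcome") %in% names(well_outcomes))) {
      stop("Plate data frame needs `well` and `outcome` columns.",
           call. = FALSE)
    }
    wells <- as.character(well_outcomes$well)
    outcomes <- as.character(well_outcomes$outcome)
  } else {
    outcomes <- as.character(well_outcomes)
  }
  bad <- setdiff(unique(outcomes), c("positive", "negative", "excluded"))
  if (length(bad)) {
    stop("Unknown well outcome code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  keep <- outcomes != "excluded"
  n_total <- sum(keep)
  if (n_total == 0) {
    stop("All wells are excluded: no denominator for a recovery rate.",
         call. = FALSE)
  }
  n_positive <- sum(outcomes[keep] == "positive")
  ci <- recovery_ci(n_positive, n_total, conf_level)
  structure(list(
    gate_label = gate_label,
    n_positive = n_positive,
    n_total = n_total,
    n_excluded = sum(!keep),
    recovery_rate = n_positive / n_total,
    ci_low = ci[["lower"]],
    ci_high = ci[["upper"]],
    wells = if (!is.null(wells)) wells[keep] else NULL
  ), class = "plate_digitization")
}

#' Binomial confidence interval for a recovery rate
#'
#' 95% (by default) Wilson score interval for `n_positive` successes in
#' `n_total` wells. At the boundaries the interval honours the data: an
#' observed 0 has lower bound exactly 0, an observed `n_total` has upper
#' bound exactly 1. Clopper-Pearson is available for an exact interval.
#'
#' @param n_positive,n_total Counts, `0 <= n_positive <= n_total`,
#'   `n_total >= 1`.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' recovery_ci(82, 230)
#' @export
recovery_ci <- function(n_positive, n_total, conf_level = 0.95,
                        method = c("wilson", "clopper-pearson")) {
  if (n_total < 1) stop("`n_total` must be at least 1.", call. = FALSE)
  if (n_positive < 0 || n_positive > n_total) {
    stop("`n_positive` must lie in [0, n_total].", call. = FALSE)
  }
  binom_interval(n_positive, n_total, conf_level, match.arg(method))
}

#' Compare recovery between two sorting gates
#'
#' Contrast of the phage-positive rates of two disjoint well sets (e.g.
#' the high-fluorescence target gate against a low-fluorescence control
#' gate): difference of rates, its Newcombe score interval (built from the
#' two Wilson intervals), and the two-sided Fisher exact p-value of the
#' 2x2 table. Fisher's exact test is used rather than a chi-square
#' approximation because a zero cell — a control gate with no positives —
#' is the expected outcome and invalidates the asymptotics.
#'
#' @param high,low [digitize_plate()] results for the two gates. If both
#'   carry well IDs, overlapping IDs raise an error.
#' @param conf_level Confidence level for the difference interval.
#' @return A list: `rate_high`, `rate_low`, `difference`, `ci_low`,
#'   `ci_high`, `p_value`, `table` (the 2x2 counts).
#' @examples
#' hi <- digitize_plate(rep(c("positive", "negative"), c(82, 148)),
#'                      "high_fluorescence")
#' lo <- digitize_plate(rep("negative", 184), "low_fluorescence")
#' compare_gates(hi, lo)
#' @export
compare_gates <- function(high, low, conf_level = 0.95) {
  stopifnot(inherits(high, "plate_digitization"),
            inherits(low, "plate_digitization"))
  if (!is.null(high$wells) && !is.null(low$wells)) {
    overlap <- intersect(high$wells, low$wells)
    if (length(overlap)) {
      stop("Gates share well ID(s): ", paste(overlap, collapse = ", "),
           ". Recovery comparison requires disjoint wells.", call. = FALSE)
    }
  }
  p1 <- high$recovery_rate
  p2 <- low$recovery_rate
  w1 <- recovery_ci(high$n_positive, high$n_total, conf_level)
  w2 <- recovery_ci(low$n_positive, low$n_total, conf_level)
  # Newcombe hybrid score interval for p1 - p2
  lo_d <- (p1 - p2) - sqrt((p1 - w1[["lower"]])^2 + (w2[["upper"]] - p2)^2)
  hi_d <- (p1 - p2) + sqrt((w1[["upper"]] - p1)^2 + (p2 - w2[["lower"]])^2)
  tab <- matrix(c(high$n_positive, high$n_total - high$n_positive,
                  low$n_positive, low$n_total - low$n_positive),
                nrow = 2,
                dimnames = list(c("positive", "negative"),
                                c(high$gate_label, low$gate_label)))
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  list(rate_high = p1, rate_low = p2, difference = p1 - p2,
       ci_low = lo_d, ci_high = hi_d, p_value = p, table = tab)
}

#' Read a plate CSV and digitize per gate
#'
#' Expects columns `plate_id`, `well`, `gate_label`, `outcome`; wells are
#' pooled across plates within each gate label, with plate-qualified well
#' IDs so disjointness remains checkable.
#'
#' @param path Path to the plate CSV.
#' @return Named list of [digitize_plate()] results, one per gate label.
#' @export
read_plate_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("plate_id", "well", "gate_label", "outcome")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("Plate file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$well <- paste(df$plate_id, df$well, sep = ":")
  out <- lapply(split(df, df$gate_label), function(d) {
    digitize_plate(d[, c("well", "outcome")], gate_label = d$gate_label[1])
  })
  out
}

#' Simulate single-droplet isolation into 96-well plates
#'
#' Emulates the sorting-and-recultivation arm of the assay on simulated
#' data: from the gated events of one timepoint, draws `n_high` droplets
#' above the fluorescence threshold and `n_low` at or below it, looks up
#' each droplet's latent truth, and calls the well phage-positive when the
#' droplet carried at least one phage particle **and** survived the lumped
#' per-well loss (probability `1 - loss_prob`). The loss parameter bundles
#' mis-sorting, failed droplet rupture and adsorption of the picoliter
#' droplet onto labware — the practical reasons a genuinely phage-positive
#' droplet can fail to regrow after isolation.
#'
#' @param events Gated event tibble containing `droplet_id` (e.g. the
#'   output of [size_filter()] on one condition and timepoint).
#' @param truth Latent-truth tibble with `droplet_id` and `n_phage`
#'   (from [simulate_experiment()], one condition/timepoint slice).
#' @param threshold Fluorescence cutoff defining the high gate (strict
#'   `>`).
#' @param n_high,n_low Number of wells to fill from each gate.
#' @param loss_prob Per-well probability that a phage-positive droplet is
#'   lost before regrowth (in \[0, 1\]).
#' @param seed RNG seed (required).
#' @return A list with [digitize_plate()] results `high` and `low`.
#' @export
simulate_isolation <- function(events, truth, threshold, n_high, n_low,
                               loss_prob, seed) {
  stopifnot(is.numeric(loss_prob), loss_prob >= 0, loss_prob <= 1)
  if (missing(seed)) stop("`seed` is required.", call. = FALSE)
  if (!"droplet_id" %in% names(events)) {
    stop("`events` must carry `droplet_id` to be matched against truth.",
         call. = FALSE)
  }
  truth <- truth[!duplicated(truth$droplet_id), c("droplet_id", "n_phage")]
  hi_pool <- events$droplet_id[events$fluorescence > threshold]
  lo_pool <- events$droplet_id[events$fluorescence <= threshold]
  if (length(hi_pool) < n_high || length(lo_pool) < n_low) {
    stop("Not enough droplets in a gate to fill the requested wells ",
         "(high: ", length(hi_pool), "/", n_high,
         ", low: ", length(lo_pool), "/", n_low, ").", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    picks <- list(high = sample(hi_pool, n_high),
                  low = sample(lo_pool, n_low))
    out <- lapply(names(picks), function(g) {
      ids <- picks[[g]]
      n_phage <- truth$n_phage[match(ids, truth$droplet_id)]
      survived <- stats::runif(length(ids)) >= loss_prob
      outcome <- ifelse(n_phage >= 1 & survived, "positive", "negative")
      digitize_plate(
        tibble::tibble(well = paste0(g, "_", seq_along(ids)),
                       outcome = outcome),
        gate_label = paste0(g, "_fluorescence"))
    })
    names(out) <- names(picks)
    out
  })
}
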