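#' Gating policy for droplet event tables
#'
#' Captures the two event-level rules used on droplet cytometry exports:
#' a per-timepoint forward-scatter size filter (events whose FSC deviates
#' from the group mean by more than `fsc_sd_multiplier` standard deviations
#' are removed — abnormally sized droplets are not trusted) and a
#' fluorescence threshold separating fluorescent from non-fluorescent
#' droplets. The threshold is either a fixed instrument value (default
#' 130 a.u.) or derived from a no-phage control so that at most `fp_rate`
#' of control events exceed it (default 0.5%).
#'
#' @param fsc_sd_multiplier SD multiplier for the size filter (> 0,
#'   default 1).
#' @param threshold_mode `"fixed"` or `"from_negative_control"`.
#' @param fixed_threshold Fluorescence cutoff in a.u. used in fixed mode
#'   (default 130).
#' @param fp_rate Allowed fraction of negative-control events above a
#'   derived threshold (in (0, 1), default 0.005).
#' @return A list of class `gate_policy`.
#' @export
gate_policy <- function(fsc_sd_multiplier = 1,
                        threshold_mode = c("fixed", "from_negative_control"),
                        fixed_threshold = 130,
                        fp_rate = 0.005) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(is.numeric(fsc_sd_multiplier), length(fsc_sd_multiplier) == 1)
  if (fsc_sd_multiplier <= 0) {
    stop("`fsc_sd_multiplier` must be positive.", call. = FALSE)
  }
  stopifnot(is.numeric(fp_rate), length(fp_rate) == 1)
  if (fp_rate <= 0 || fp_rate >= 1) {
    stop("`fp_rate` must lie strictly between 0 and 1.", call. = FALSE)
  }
  if (threshold_mode == "fixed" &&
      (!is.numeric(fixed_threshold) || length(fixed_threshold) != 1 ||
       !is.finite(fixed_threshold))) {
    stop("`fixed_threshold` must be a finite number in fixed mode.",
         call. = FALSE)
  }
  structure(list(fsc_sd_multiplier = fsc_sd_multiplier,
                 threshold_mode = threshold_mode,
                 fixed_threshold = fixed_threshold,
                 fp_rate = fp_rate),
            class = "gate_policy")
}

#' Remove abnormally sized droplets by forward scatter
#'
#' Within each `(sample_id, timepoint_h)` group independently, retains
#' events whose forward scatter satisfies
#' `|fsc - mean(fsc)| <= multiplier * sd(fsc)` — only events deviating by
#' strictly more than the bound are removed. The sample (n-1) standard
#' deviation is used; group means are recomputed per timepoint because
#' instrument FSC means drift between reads. Row order is preserved and the
#' filter is applied once, before any fluorescence classification.
#'
#' @param events An event tibble (see [read_event_table()] for the schema).
#' @param policy A [gate_policy()]; only `fsc_sd_multiplier` is used.
#' @return The retained rows, in input order, with the per-group removal
#'   counts attached as attribute `"size_filter_log"` (a tibble with
#'   `sample_id`, `timepoint_h`, `n_input`, `n_removed`).
#' @examples
#' ev <- tibble::tibble(sample_id = "s", condition = "phage",
#'                      timepoint_h = 0, fsc = c(100, 101, 99, 250),
#'                      fluorescence = 1:4)
#' size_filter(ev, gate_policy())
#' @export
size_filter <- function(events, policy = gate_policy()) {
  check_event_table(events)
  grp <- interaction(events$sample_id, events$timepoint_h, drop = TRUE)
  sizes <- table(grp)
  if (any(sizes < 2)) {
    bad <- names(sizes)[sizes < 2]
    stop("Size filter needs at least 2 events per (sample_id, timepoint_h) ",
         "group to define an SD; offending group(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mult <- policy$fsc_sd_multiplier
  keep <- unsplit(lapply(split(events$fsc, grp), function(x) {
    abs(x - mean(x)) <= mult * stats::sd(x)
  }), grp)
  out <- events[keep, , drop = FALSE]
  log <- dplyr::summarise(
    dplyr::group_by(events[, c("sample_id", "timepoint_h")],
                    .data$sample_id, .data$timepoint_h),
    n_input = dplyr::n(), .groups = "drop"
  )
  removed <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(sample_id = events$sample_id,
                     timepoint_h = events$timepoint_h,
                     removed = !keep),
      .data$sample_id, .data$timepoint_h),
    n_removed = sum(.data$removed), .groups = "drop"
  )
  attr(out, "size_filter_log") <- dplyr::left_join(
    log, removed, by = c("sample_id", "timepoint_h"))
  out
}

#' Derive a fluorescence threshold from a no-phage control
#'
#' Returns the smallest observed intensity `T` such that the fraction of
#' control events strictly above `T` is at most `fp_rate`: the empirical
#' `(1 - fp_rate)` quantile taken as an order statistic (no interpolation,
#' so the result is exact on small fixtures). Classifying events as
#' fluorescent when strictly above the returned value then mislabels at
#' most `fp_rate` of the control.
#'
#' @param negative_events Event tibble (or bare numeric vector of
#'   fluorescence values) from a no-phage control, typically at the
#'   reference timepoint the threshold will be used at.
#' @param fp_rate Tolerated false-positive fraction (default 0.005).
#' @return The threshold in the same units as `fluorescence`.
#' @examples
#' derive_threshold(c(1, 2, 3, 50), fp_rate = 0.3)
#' @export
derive_threshold <- function(negative_events, fp_rate = 0.005) {
  x <- if (is.numeric(negative_events)) {
    negative_events
  } else {
    check_event_table(negative_events)
    negative_events$fluorescence
  }
  if (length(x) == 0) stop("No negative-control events.", call. = FALSE)
  stopifnot(is.numeric(fp_rate), length(fp_rate) == 1,
            fp_rate > 0, fp_rate < 1)
  n <- length(x)
  k <- n - floor(fp_rate * n)
  sort(x)[k]
}

#' Classify events and summarise fluorescent fractions per timepoint
#'
#' Applies the size filter (unless `apply_size_filter = FALSE`, for tables
#' filtered upstream) and then counts, per `(sample_id, condition,
#' timepoint_h)`, the events with fluorescence strictly greater than the
#' threshold. Plotted over incubation time, the `fluorescent_fraction`
#' column is the familiar propagation time course of these assays.
#'
#' In `"from_negative_control"` mode the threshold is derived once from
#' `control_events` via [derive_threshold()] and applied to all groups.
#'
#' @param events Event tibble to classify.
#' @param policy A [gate_policy()].
#' @param control_events No-phage control events; required in
#'   `"from_negative_control"` mode.
#' @param apply_size_filter Run [size_filter()] first (default `TRUE`).
#' @return A gate-summary tibble with one row per group: `sample_id`,
#'   `condition`, `timepoint_h`, `n_input`, `n_after_size_filter`,
#'   `n_fluorescent`, `fluorescent_fraction`, `threshold_used`.
#' @export
classify_and_summarize <- function(events, policy = gate_policy(),
                                   control_events = NULL,
                                   apply_size_filter = TRUE) {
  check_event_table(events)
  threshold <- switch(
    policy$threshold_mode,
    fixed = {
      if (is.null(policy$fixed_threshold)) {
        stop("Fixed threshold mode but no `fixed_threshold` set.",
             call. = FALSE)
      }
      policy$fixed_threshold
    },
    from_negative_control = {
      if (is.null(control_events)) {
        stop("Threshold mode 'from_negative_control' needs `control_events`.",
             call. = FALSE)
      }
      derive_threshold(control_events, policy$fp_rate)
    }
  )
  n_input <- dplyr::summarise(
    dplyr::group_by(events, .data$sample_id, .data$condition,
                    .data$timepoint_h),
    n_input = dplyr::n(), .groups = "drop"
  )
  filtered <- if (apply_size_filter) size_filter(events, policy) else events
  out <- dplyr::summarise(
    dplyr::group_by(filtered, .data$sample_id, .data$condition,
                    .data$timepoint_h),
    n_after_size_filter = dplyr::n(),
    n_fluorescent = sum(.data$fluorescence > threshold),
    .groups = "drop"
  )
  out <- dplyr::left_join(n_input, out,
                          by = c("sample_id", "condition", "timepoint_h"))
  out$n_after_size_filter[is.na(out$n_after_size_filter)] <- 0L
  out$n_fluorescent[is.na(out$n_fluorescent)] <- 0L
  out$fluorescent_fraction <-
    ifelse(out$n_after_size_filter > 0,
           out$n_fluorescent / out$n_after_size_filter, NA_real_)
  out$threshold_used <- threshold
  dplyr::arrange(out, .data$sample_id, .data$condition, .data$timepoint_h)
}
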