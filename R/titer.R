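#' Phage titer from replicate plaque counts
#'
#' Standard plaque-assay arithmetic: the titer of the ruptured droplet
#' sample is the mean replicate count at the selected dilution, scaled back
#' by the dilution factor and the plated volume,
#' `mean(counts) * dilution_factor / plated_volume_mL` (PFU/mL).
#'
#' Counts outside the conventional countable window of 3-300 plaques per
#' plate trigger a warning (too few plaques is statistically unreliable,
#' too many are unresolvable) but are never dropped.
#'
#' @param counts Replicate plaque counts at one dilution (non-negative
#'   integers, length >= 1).
#' @param dilution_factor Fold dilution of the ruptured sample (>= 1).
#' @param plated_volume_mL Volume plated per plate in mL (> 0).
#' @return Titer in PFU per mL of the ruptured sample.
#' @examples
#' titer_from_plaques(c(30, 32, 34), dilution_factor = 1e6,
#'                    plated_volume_mL = 0.1)  # 3.2e8
#' @export
titer_from_plaques <- function(counts, dilution_factor, plated_volume_mL) {
  if (length(counts) < 1) stop("Need at least one replicate count.",
                               call. = FALSE)
  stopifnot(is.numeric(counts), is.numeric(dilution_factor),
            is.numeric(plated_volume_mL))
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("`counts` must be non-negative integers.", call. = FALSE)
  }
  if (dilution_factor < 1) stop("`dilution_factor` must be >= 1.",
                                call. = FALSE)
  if (plated_volume_mL <= 0) stop("`plated_volume_mL` must be positive.",
                                  call. = FALSE)
  if (all(counts == 0)) {
    warning("All replicate counts are zero: titer is below the detection ",
            "limit of this dilution.", call. = FALSE)
  } else if (any(counts < 3 | counts > 300)) {
    warning("Plaque counts outside the countable range (3-300); the titer ",
            "estimate may be unreliable.", call. = FALSE)
  }
  mean(counts) * dilution_factor / plated_volume_mL
}

#' PFU contained in a fixed emulsion aliquot
#'
#' Expresses a titer as total PFU within a sampled aliquot (e.g. "PFU per
#' 8 uL of emulsion", the natural y-axis for droplet time courses):
#' `titer * (aliquot_volume_uL / 1000) * recovery_dilution`.
#'
#' The rupture step dilutes the aqueous phase by an amount that depends on
#' how much oil the aliquot carried, which is not generally known; pass the
#' net factor as `recovery_dilution` to undo it explicitly.
#'
#' @param titer_per_mL Titer of the ruptured sample (PFU/mL, >= 0).
#' @param aliquot_volume_uL Emulsion volume sampled, in uL (> 0).
#' @param recovery_dilution Fold dilution incurred between the emulsion and
#'   the plated sample (>= 1 typically; default 1).
#' @return PFU in the aliquot, with the aliquot recorded in attribute
#'   `"aliquot_label"`.
#' @examples
#' aliquot_pfu(1e6, aliquot_volume_uL = 8)  # 8000 PFU per 8 uL emulsion
#' @export
aliquot_pfu <- function(titer_per_mL, aliquot_volume_uL,
                        recovery_dilution = 1) {
  stopifnot(is.numeric(titer_per_mL), is.numeric(aliquot_volume_uL),
            is.numeric(recovery_dilution))
  if (any(titer_per_mL < 0)) stop("`titer_per_mL` must be non-negative.",
                                  call. = FALSE)
  if (aliquot_volume_uL <= 0 || recovery_dilution <= 0) {
    stop("Volumes and dilutions must be positive.", call. = FALSE)
  }
  out <- titer_per_mL * (aliquot_volume_uL / 1000) * recovery_dilution
  attr(out, "aliquot_label") <- sprintf("PFU per %g uL emulsion",
                                        aliquot_volume_uL)
  out
}

#' Fold change between two PFU measurements
#'
#' @param pfu_t0 Baseline PFU (> 0).
#' @param pfu_t1 Later PFU (>= 0).
#' @return `pfu_t1 / pfu_t0`.
#' @examples
#' fold_change(100, 1700)  # 17-fold rise
#' @export
fold_change <- function(pfu_t0, pfu_t1) {
  stopifnot(is.numeric(pfu_t0), is.numeric(pfu_t1))
  if (any(pfu_t0 <= 0)) {
    stop("`pfu_t0` must be positive to define a fold change.", call. = FALSE)
  }
  pfu_t1 / pfu_t0
}

#' Titer time course from a plaque-count table
#'
#' Applies [titer_from_plaques()] and [aliquot_pfu()] row-wise to a table
#' with one row per timepoint: columns `timepoint_h`, `dilution_factor`,
#' `plated_volume_mL` and one or more `count_rep*` replicate columns.
#'
#' @param plaques Data frame / tibble of plaque counts (see Details).
#' @param aliquot_volume_uL Emulsion aliquot the counts refer to (default 8).
#' @param recovery_dilution Fold dilution of the rupture step (default 1).
#' @return A tibble with `timepoint_h`, `titer_pfu_per_ml`, `pfu_aliquot`,
#'   `aliquot_label`.
#' @export
titer_timecourse <- function(plaques, aliquot_volume_uL = 8,
                             recovery_dilution = 1) {
  need <- c("timepoint_h", "dilution_factor", "plated_volume_mL")
  missing_cols <- setdiff(need, names(plaques))
  if (length(missing_cols)) {
    stop("Plaque table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rep_cols <- grep("^count_rep", names(plaques), value = TRUE)
  if (!length(rep_cols)) {
    stop("Plaque table needs at least one `count_rep*` column.",
         call. = FALSE)
  }
  titers <- vapply(seq_len(nrow(plaques)), function(i) {
    counts <- as.numeric(plaques[i, rep_cols])
    counts <- counts[!is.na(counts)]
    titer_from_plaques(counts, plaques$dilution_factor[i],
                       plaques$plated_volume_mL[i])
  }, numeric(1))
  pfu <- titers * (aliquot_volume_uL / 1000) * recovery_dilution
  tibble::tibble(
    timepoint_h = plaques$timepoint_h,
    titer_pfu_per_ml = titers,
    pfu_aliquot = pfu,
    aliquot_label = sprintf("PFU per %g uL emulsion", aliquot_volume_uL)
  )
}
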