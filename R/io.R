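#' Read a droplet event table from CSV
#'
#' The interchange format is a plain CSV with one row per measured droplet
#' and columns `sample_id`, `condition` (`phage` / `no_phage`),
#' `timepoint_h`, `fsc`, `fluorescence` (extra columns such as
#' `droplet_id` are carried through). Missing columns raise a schema error
#' naming the column; rows with non-numeric or non-finite `fsc` /
#' `fluorescence` / `timepoint_h` raise an error listing the offending
#' line numbers of the file.
#'
#' @param path Path to the CSV file.
#' @return An event tibble.
#' @export
read_event_table <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_guess()))
  need <- c("sample_id", "condition", "timepoint_h", "fsc", "fluorescence")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("Event file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in c("timepoint_h", "fsc", "fluorescence")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad)) {
        # +1 for the header line
        stop("Non-numeric `", col, "` on file line(s): ",
             paste(utils::head(bad + 1, 10), collapse = ", "),
             if (length(bad) > 10) " ..." else "", call. = FALSE)
      }
      df[[col]] <- vn
    }
    bad <- which(!is.finite(df[[col]]))
    if (length(bad)) {
      stop("Missing or non-finite `", col, "` on file line(s): ",
           paste(utils::head(bad + 1, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "", call. = FALSE)
    }
  }
  check_event_table(df)
  df
}

#' Write a droplet event table to CSV
#'
#' Inverse of [read_event_table()]; writes the documented columns (plus
#' `droplet_id` when present) in a stable order.
#'
#' @param events Event tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  check_event_table(events)
  cols <- intersect(c("droplet_id", "sample_id", "condition", "timepoint_h",
                      "fsc", "fluorescence"), names(events))
  readr::write_csv(events[, cols], path)
  invisible(path)
}

# Schema guard shared by every event-table consumer.
check_event_table <- function(events) {
  need <- c("sample_id", "condition", "timepoint_h", "fsc", "fluorescence")
  missing_cols <- setdiff(need, names(events))
  if (length(missing_cols)) {
    stop("Event table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(events) > 0) {
    if (!is.numeric(events$fsc) || any(!is.finite(events$fsc)) ||
        any(events$fsc <= 0)) {
      stop("`fsc` must be finite and positive.", call. = FALSE)
    }
    if (any(!is.finite(events$timepoint_h))) {
      stop("`timepoint_h` must be present for every row.", call. = FALSE)
    }
  }
  invisible(events)
}

#' Read a simulation or pipeline configuration from YAML
#'
#' Keys of the `simulation` block match the [sim_config()] arguments
#' one-to-one; `gate` keys match [gate_policy()]; `geometry` takes
#' `diameter_um` and/or `volume_pL`. See [run_pipeline()] for the full
#' layout.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  yaml::read_yaml(path)
}
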