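#' Write a cohort to CSV
#'
#' One row per participant; comma-separated, UTF-8, mandatory header, "."
#' decimal separator. The column set is fixed: `participant_id`, `cohort`,
#' the error counts `e1 e2 e3c e3p e4 e5 e_ds`, the secondary driving
#' measures `speed_var lat_accel brake_time dist_collision time_collision`,
#' and the covariates `moca tmt_a tmt_b cdt tug`. An optional group split is
#' serialized alongside as a `ds_group` label column.
#'
#' @param records cohort data frame.
#' @param path output file path.
#' @param split optional `group_split` to serialize as a label column.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path, split = NULL) {
  validate_cohort(records)
  out <- records[, cohort_columns()]
  if (!is.null(split)) {
    stop_if_not(inherits(split, "group_split") &&
                  length(split$labels) == nrow(records),
                "`split` must be a group_split aligned with `records`")
    out$ds_group <- as.character(split$labels)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Reads and validates a cohort written by [write_cohort_csv()] (or assembled
#' externally with the same header). Row-level problems — non-integer or
#' negative error counts, MoCA outside 0–30, non-positive times — are
#' collected and reported together with their line numbers. Unknown extra
#' columns are accepted with a warning.
#'
#' @param path CSV file path.
#' @return A validated cohort data frame (extra columns dropped); if the file
#'   carries a `ds_group` column the corresponding `group_split` is attached
#'   as attribute `"split"`.
#' @export
read_cohort_csv <- function(path) {
  stop_if_not(file.exists(path), paste("no such file:", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(cohort_columns(), names(raw))
  stop_if_not(length(missing) == 0,
              paste("cohort CSV is missing column(s):",
                    paste(missing, collapse = ", ")))
  extra <- setdiff(names(raw), c(cohort_columns(), "ds_group"))
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }

  problems <- character(0)
  note <- function(rows, field, what) {
    if (any(rows)) {
      problems <<- c(problems, sprintf(
        "row %d: %s %s", which(rows) + 1L, field, what))  # +1 for header line
    }
  }
  for (col in error_columns()) {
    v <- raw[[col]]
    note(!is.finite(v) | v < 0 | v != round(v), col,
         "must be a non-negative integer")
  }
  note(!is.finite(raw$moca) | raw$moca < 0 | raw$moca > 30, "moca",
       "must lie in [0, 30]")
  for (col in c("tmt_a", "tmt_b", "tug")) {
    note(!is.finite(raw[[col]]) | raw[[col]] <= 0, col, "must be > 0")
  }
  for (col in secondary_columns()) {
    note(!is.finite(raw[[col]]) | raw[[col]] < 0, col, "must be >= 0")
  }
  if (length(problems)) {
    stop("invalid cohort CSV:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  out <- raw[, cohort_columns()]
  for (col in error_columns()) out[[col]] <- as.integer(out[[col]])
  if ("ds_group" %in% names(raw)) {
    attr(out, "split") <- group_split(raw$ds_group)
  }
  out
}

#' Write and read generator / run configurations
#'
#' Configurations serialize to YAML (default) or JSON by file extension.
#'
#' @param config a `cohort_config` or plain list.
#' @param path destination ending in `.yaml`, `.yml`, or `.json`.
#' @return `path` invisibly (write); the configuration list (read).
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  stop_if_not(file.exists(path), paste("no such file:", path))
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
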