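#' Validate a bilateral cohort table
#'
#' A cohort table is the package's universal input: one row per
#' participant x tract x metric x hemisphere with the measured `value`
#' (`NA` encodes a failed reconstruction). Validation enforces the
#' schema invariants: exact columns, known tract/metric/hemisphere
#' labels, at most one row per key, non-negative values, and joint
#' missingness — a failed reconstruction is a tract x hemisphere event,
#' so all three metrics of that tract/hemisphere must be `NA` together.
#'
#' @param data A data frame with columns `participant_id`, `tract`,
#'   `metric`, `hemisphere`, `value`.
#' @return The validated data invisibly as a tibble, with `tract`,
#'   `metric` and `hemisphere` as factors in canonical order.
#' @export
validate_cohort <- function(data) {
  required <- c("participant_id", "tract", "metric", "hemisphere", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    abort(paste0("cohort table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)[required]

  bad_tract <- !data$tract %in% .TRACTS
  if (any(bad_tract)) {
    abort(paste0("unknown tract label(s) at row(s) ",
                 paste(utils::head(which(bad_tract), 5), collapse = ", "),
                 ": ", paste(unique(data$tract[bad_tract]), collapse = ", ")))
  }
  bad_metric <- !data$metric %in% .METRICS
  if (any(bad_metric)) {
    abort(paste0("unknown metric label(s) at row(s) ",
                 paste(utils::head(which(bad_metric), 5), collapse = ", ")))
  }
  bad_hemi <- !data$hemisphere %in% .HEMIS
  if (any(bad_hemi)) {
    abort(paste0("hemisphere must be 'L' or 'R'; offending row(s) ",
                 paste(utils::head(which(bad_hemi), 5), collapse = ", ")))
  }

  key <- paste(data$participant_id, data$tract, data$metric, data$hemisphere)
  dup <- duplicated(key)
  if (any(dup)) {
    abort(paste0("duplicated (participant, tract, metric, hemisphere) key: ",
                 key[which(dup)[1]], " (row ", which(dup)[1], ")"))
  }

  neg <- !is.na(data$value) & data$value < 0
  if (any(neg)) {
    abort(paste0("negative value(s) at row(s) ",
                 paste(utils::head(which(neg), 5), collapse = ", ")))
  }

  # Joint missingness across metrics within a tract x hemisphere.
  chk <- data |>
    dplyr::group_by(.data$participant_id, .data$tract, .data$hemisphere) |>
    dplyr::summarise(n_na = sum(is.na(.data$value)),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_na > 0, .data$n_na < .data$n)
  if (nrow(chk)) {
    abort(paste0("partial missingness within tract/hemisphere (all metrics ",
                 "must fail together): participant ", chk$participant_id[1],
                 ", tract ", chk$tract[1], ", hemisphere ", chk$hemisphere[1]))
  }

  data$tract <- factor(data$tract, levels = .TRACTS)
  data$metric <- factor(data$metric, levels = .METRICS)
  data$hemisphere <- factor(data$hemisphere, levels = .HEMIS)
  invisible(data)
}

#' Read or write a cohort table
#'
#' Plain-text TSV/CSV I/O for the cohort schema (`participant_id`,
#' `tract`, `metric`, `hemisphere`, `value`; `NA` for missing). The
#' delimiter follows the file extension (`.csv` gives comma, anything
#' else tab). Reading validates the table and fails loudly, naming the
#' offending rows.
#'
#' @param path File path.
#' @return `read_cohort()` returns a validated tibble;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data <- readr::read_delim(
    path, delim = delim, na = "NA", show_col_types = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      tract = readr::col_character(),
      metric = readr::col_character(),
      hemisphere = readr::col_character(),
      value = readr::col_double()
    )
  )
  out <- validate_cohort(data)
  out
}

#' @rdname read_cohort
#' @param data A cohort table (validated on the way out).
#' @export
write_cohort <- function(data, path) {
  data <- validate_cohort(data)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(data, path, delim = delim, na = "NA")
  invisible(path)
}
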