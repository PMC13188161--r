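#' Validate a summarized multi-chemical qAOP dataset
#'
#' The tabular exchange format has one row per dose group with columns:
#' `chemical_id` (cluster identifier; a chemical tested in two studies forms
#' two clusters), optional `study_id`, `dose` (non-negative, consistent
#' units, e.g. ng/g internal liver dose), `ke_up_n`, `ke_up_mean`,
#' `ke_up_sd` (natural-scale summaries of the continuous upstream key
#' event, e.g. BrdU %), and `ke_down_n`, `ke_down_cases` (dichotomous
#' downstream key event, e.g. tumor incidence). The downstream columns may
#' be `NA` for dose-response-only rows; likewise the upstream summary
#' columns may be `NA` on rows contributing only incidence, provided the
#' chemical has at least one upstream row to anchor its dose-response
#' curve.
#'
#' @param data A data frame in the schema above.
#' @return The validated data, as a tibble with class `"qaop_data"`.
#' @export
validate_qaop_data <- function(data) {
  stopifnot(is.data.frame(data))
  required <- c("chemical_id", "dose", "ke_up_n", "ke_up_mean", "ke_up_sd")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  if (!"ke_down_n" %in% names(data)) data$ke_down_n <- NA_integer_
  if (!"ke_down_cases" %in% names(data)) data$ke_down_cases <- NA_integer_

  check_row <- function(cond, what) {
    bad <- which(!cond)
    if (length(bad) > 0) {
      stop(sprintf("row %d: %s", bad[1], what), call. = FALSE)
    }
  }
  num_cols <- c("dose", "ke_up_n", "ke_up_mean", "ke_up_sd",
                "ke_down_n", "ke_down_cases")
  for (cl in num_cols) {
    if (!is.numeric(data[[cl]])) {
      stop(sprintf("column `%s` must be numeric", cl), call. = FALSE)
    }
  }
  check_row(!is.na(data$dose) & data$dose >= 0, "`dose` must be >= 0")
  has_up <- !is.na(data$ke_up_mean)
  has_down <- !is.na(data$ke_down_cases) | !is.na(data$ke_down_n)
  check_row(has_up | has_down,
            "row carries neither upstream nor downstream data")
  check_row(!has_up | (!is.na(data$ke_up_n) & data$ke_up_n >= 1),
            "`ke_up_n` must be >= 1 where an upstream summary is present")
  check_row(!has_up | data$ke_up_mean > 0,
            "`ke_up_mean` must be > 0 (lognormal endpoint)")
  check_row(!has_up | (!is.na(data$ke_up_sd) & data$ke_up_sd >= 0),
            "`ke_up_sd` must be >= 0")
  deg <- has_up & !is.na(data$ke_up_sd) & data$ke_up_sd == 0 & data$ke_up_n > 1
  check_row(!deg,
            "degenerate group: ke_up_sd = 0 with ke_up_n > 1")
  check_row(!has_down | (!is.na(data$ke_down_n) & data$ke_down_n >= 1),
            "`ke_down_n` must be >= 1 where downstream data are present")
  check_row(!has_down |
              (!is.na(data$ke_down_cases) & data$ke_down_cases >= 0 &
                 data$ke_down_cases <= data$ke_down_n),
            "`ke_down_cases` must satisfy 0 <= cases <= ke_down_n")
  # every cluster carrying downstream data needs upstream rows to anchor
  # its latent means through the dose-response curve
  down_only <- setdiff(unique(data$chemical_id[has_down]),
                       unique(data$chemical_id[has_up]))
  if (length(down_only) > 0) {
    stop("chemical(s) with downstream data but no upstream data: ",
         paste(down_only, collapse = ", "),
         " (latent means cannot be anchored)", call. = FALSE)
  }
  class(data) <- c("qaop_data", class(data))
  data
}

#' Read a summarized qAOP dataset from CSV
#'
#' @param path Path to a CSV file in the schema of [validate_qaop_data()].
#' @return A validated `qaop_data` tibble.
#' @export
read_qaop_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_qaop_data(raw)
}

#' Write a summarized qAOP dataset to CSV
#'
#' @param data A data frame accepted by [validate_qaop_data()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_qaop_csv <- function(data, path) {
  data <- validate_qaop_data(data)
  cols <- intersect(c("chemical_id", "study_id", "dose",
                      "ke_up_n", "ke_up_mean", "ke_up_sd",
                      "ke_down_n", "ke_down_cases"),
                    names(data))
  utils::write.csv(as.data.frame(data)[cols], path, row.names = FALSE)
  invisible(path)
}

#' Summary of a qAOP dataset
#'
#' @param object A `qaop_data` tibble.
#' @param ... Unused.
#' @return A tibble with one row per chemical cluster: number of dose
#'   groups, dose range, and subject totals.
#' @export
summary.qaop_data <- function(object, ...) {
  object |>
    dplyr::group_by(.data$chemical_id) |>
    dplyr::summarise(
      n_groups = dplyr::n(),
      dose_min = min(.data$dose),
      dose_max = max(.data$dose),
      n_ke_up = sum(.data$ke_up_n[!is.na(.data$ke_up_mean)]),
      n_ke_down = sum(.data$ke_down_n, na.rm = TRUE),
      .groups = "drop"
    )
}
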