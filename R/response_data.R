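#' Read a trial-level response table
#'
#' Reads and validates transcribed reading-aloud trials. Each row is one
#' participant x item x session trial with the transcribed response category
#' and correctness flags. Comma- or tab-delimited is auto-detected from the
#' file extension (`.csv` vs `.tsv`/`.txt`).
#'
#' Required columns: `participant_id`, `grade`, `item_id`, `condition`,
#' `session`, `response_category`, `consonant_correct`, `is_error`. Unknown
#' extra columns are kept but flagged with a warning. Error trials
#' (`is_error = TRUE`) may carry category labels outside the design (e.g.
#' `"consonant_error"`); non-error trials must use the design's valid
#' categories.
#'
#' @param path Path to a delimited text file with a header row.
#' @param design The [study_design()] the responses belong to.
#' @return A tibble of validated response records, row order preserved.
#' @export
read_responses <- function(path, design) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  reader <- if (ext == "csv") readr::read_csv else readr::read_tsv
  records <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_responses(records, design)
}

#' Write a response table
#'
#' @param records A response tibble (see [read_responses()]).
#' @param path Output path; `.csv` writes comma-, anything else tab-delimited.
#' @return `path`, invisibly.
#' @export
write_responses <- function(records, path) {
  if (tolower(tools::file_ext(path)) == "csv") {
    readr::write_csv(records, path)
  } else {
    readr::write_tsv(records, path)
  }
  invisible(path)
}

#' Validate a response table against a design
#'
#' Checks required columns, condition and category labels, logical flags and
#' uniqueness of (participant, item, session) triples. Fatal on any violation,
#' naming the first offending row.
#'
#' @inheritParams write_responses
#' @param design The [study_design()].
#' @return The validated records as a tibble (invisibly usable in pipes).
#' @export
validate_responses <- function(records, design) {
  records <- tibble::as_tibble(records)
  required <- c("participant_id", "grade", "item_id", "condition", "session",
                "response_category", "consonant_correct", "is_error")
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    stop("response table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(records), required)
  if (length(extra) > 0) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  records$participant_id <- as.character(records$participant_id)
  records$item_id <- as.character(records$item_id)
  records$condition <- as.character(records$condition)
  records$response_category <- as.character(records$response_category)
  records$consonant_correct <- as.logical(records$consonant_correct)
  records$is_error <- as.logical(records$is_error)
  bad <- which(!records$condition %in% design$conditions)
  if (length(bad) > 0) {
    stop("unknown condition '", records$condition[bad[1]], "' at row ", bad[1],
         call. = FALSE)
  }
  ok_cats <- valid_categories(design)
  bad <- which(!records$is_error & !records$response_category %in% ok_cats)
  if (length(bad) > 0) {
    stop("unknown response category '", records$response_category[bad[1]],
         "' at row ", bad[1], call. = FALSE)
  }
  if (anyNA(records$is_error) || anyNA(records$consonant_correct)) {
    stop("correctness flags must be TRUE/FALSE with no missing values",
         call. = FALSE)
  }
  key <- paste(records$participant_id, records$item_id, records$session,
               sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (participant, item, session) at row ", dup[1],
         call. = FALSE)
  }
  records
}

#' Remove participants with excessive error rates
#'
#' A participant is removed when their proportion of error trials is
#' *strictly* greater than `max_error_rate` (a participant at exactly the
#' threshold is kept). Error rates are computed on the table as given.
#'
#' @param records A validated response tibble.
#' @param max_error_rate Proportion in `[0, 1]`; default 0.5.
#' @return A list with `records` (kept rows) and `removed` (a tibble of
#'   removed `participant_id` with their `error_rate`).
#' @export
filter_participants <- function(records, max_error_rate = 0.5) {
  stopifnot(max_error_rate >= 0, max_error_rate <= 1)
  if (nrow(records) == 0) {
    return(list(records = records,
                removed = tibble::tibble(participant_id = character(),
                                         error_rate = numeric())))
  }
  rates <- records |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(error_rate = mean(.data$is_error), .groups = "drop")
  removed <- rates[rates$error_rate > max_error_rate, ]
  list(records = records[!records$participant_id %in% removed$participant_id, ],
       removed = removed)
}

#' Remove items with excessive error rates
#'
#' As [filter_participants()], but grouped by item; strict inequality at the
#' threshold.
#'
#' @inheritParams filter_participants
#' @param max_error_rate Proportion in `[0, 1]`; default 0.6.
#' @return A list with `records` and `removed` (tibble of `item_id`,
#'   `error_rate`).
#' @export
filter_items <- function(records, max_error_rate = 0.6) {
  stopifnot(max_error_rate >= 0, max_error_rate <= 1)
  if (nrow(records) == 0) {
    return(list(records = records,
                removed = tibble::tibble(item_id = character(),
                                         error_rate = numeric())))
  }
  rates <- records |>
    dplyr::group_by(.data$item_id) |>
    dplyr::summarise(error_rate = mean(.data$is_error), .groups = "drop")
  removed <- rates[rates$error_rate > max_error_rate, ]
  list(records = records[!records$item_id %in% removed$item_id, ],
       removed = removed)
}

#' Apply the standard preprocessing filters
#'
#' Removes high-error participants first, then high-error items, with both
#' error rates computed on the unfiltered table (so the two filters commute
#' and the result does not depend on application order).
#'
#' @inheritParams filter_participants
#' @param participant_threshold Maximum participant error proportion
#'   (default 0.5, strict).
#' @param item_threshold Maximum item error proportion (default 0.6, strict).
#' @return A list with `records`, `removed_participants`, `removed_items`.
#' @export
apply_filters <- function(records, participant_threshold = 0.5,
                          item_threshold = 0.6) {
  fp <- filter_participants(records, participant_threshold)
  fi_report <- filter_items(records, item_threshold)$removed
  kept <- fp$records[!fp$records$item_id %in% fi_report$item_id, ]
  list(records = kept,
       removed_participants = fp$removed,
       removed_items = fi_report)
}

#' Summarise responses per condition and category
#'
#' For each group (e.g. grade) and condition, reports the across-participant
#' mean and sample SD of per-participant response counts (`english_style`) or
#' percentages (`german_style`, or `as_percentage = TRUE`). Percentages are
#' per participant per condition and sum to 100 across categories; they are
#' preferable when conditions have unequal trial counts. Error trials appear
#' under the category `"error"`.
#'
#' @param records A validated response tibble.
#' @param design The [study_design()].
#' @param group_by Optional grouping column name (e.g. `"grade"`,
#'   `"session"`); `NULL` summarises the whole sample.
#' @param as_percentage Report percentages instead of counts; defaults to
#'   `TRUE` for `german_style` designs.
#' @return A tibble with columns `condition`, the grouping column (if any),
#'   `category`, `mean`, `sd`, `n_participants`.
#' @export
condition_summary <- function(records, design, group_by = NULL,
                              as_percentage = design$language_mode ==
                                "german_style") {
  if (!is.null(group_by) && !group_by %in% names(records)) {
    stop("grouping column '", group_by, "' not found", call. = FALSE)
  }
  dat <- tibble::as_tibble(records)
  dat$category <- ifelse(dat$is_error, "error", dat$response_category)
  cats <- c(valid_categories(design), "error")
  keys <- c("participant_id", group_by, "condition")
  per_part <- dat |>
    dplyr::count(dplyr::across(dplyr::all_of(c(keys, "category")))) |>
    tidyr::complete(
      tidyr::nesting(!!!rlang::syms(keys)),
      category = cats,
      fill = list(n = 0L)
    )
  if (as_percentage) {
    per_part <- per_part |>
      dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
      dplyr::mutate(n = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
  }
  per_part |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("condition", group_by, "category")))) |>
    dplyr::summarise(
      mean = mean(.data$n),
      sd = if (dplyr::n() > 1) stats::sd(.data$n) else NA_real_,
      n_participants = dplyr::n(),
      .groups = "drop"
    )
}
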