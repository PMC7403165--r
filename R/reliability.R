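#' Code test-retest response overlap
#'
#' Pairs each participant's two sessions item by item and codes agreement:
#' a pair is coded 1 when both sessions produced the same vowel category or
#' both were scored incorrect (consonant error / non-response), and 0 when
#' the vowel differed or the response was incorrect in one session only.
#' All trials enter the coding, including incorrect ones. Items present in
#' only one of the two sessions are excluded, with a message giving the count.
#'
#' @param records A validated response tibble containing sessions 1 and 2.
#' @param sessions Length-2 vector naming the sessions to compare
#'   (default `c(1, 2)`).
#' @return A tibble with `participant_id`, `grade`, `item_id`, `condition`,
#'   `outcome_1`, `outcome_2` (the category, or `"incorrect"`), and `agree`
#'   (0/1).
#' @export
code_overlap <- function(records, sessions = c(1, 2)) {
  stopifnot(length(sessions) == 2)
  dat <- tibble::as_tibble(records)
  dat <- dat[dat$session %in% sessions, ]
  dat$outcome <- ifelse(dat$is_error, "incorrect", dat$response_category)
  s1 <- dat[dat$session == sessions[1],
            c("participant_id", "grade", "item_id", "condition", "outcome")]
  s2 <- dat[dat$session == sessions[2], c("participant_id", "item_id",
                                          "outcome")]
  paired <- dplyr::inner_join(s1, s2, by = c("participant_id", "item_id"),
                              suffix = c("_1", "_2"))
  n_unpaired <- nrow(s1) + nrow(s2) - 2 * nrow(paired)
  if (n_unpaired > 0) {
    message(n_unpaired, " trial(s) without a counterpart in the other ",
            "session were excluded")
  }
  paired$agree <- as.integer(paired$outcome_1 == paired$outcome_2)
  paired
}

#' Per-participant overlap proportions and their summary
#'
#' The proportion of items on which a participant gave the same coded
#' response in both sessions, plus overall and (when available) per-grade
#' summary statistics.
#'
#' @param overlaps Output of [code_overlap()].
#' @return A list with `per_participant` (tibble: `participant_id`, `grade`,
#'   `n_items`, `overlap`) and `summary` (tibble with rows per grade and an
#'   overall row: `group`, `mean`, `sd`, `min`, `max`, `n_participants`).
#' @export
participant_overlap <- function(overlaps) {
  per_part <- overlaps |>
    dplyr::group_by(.data$participant_id, .data$grade) |>
    dplyr::summarise(n_items = dplyr::n(),
                     overlap = mean(.data$agree),
                     .groups = "drop")
  summarise_grp <- function(d, label) {
    tibble::tibble(
      group = label,
      mean = mean(d$overlap),
      sd = if (nrow(d) > 1) stats::sd(d$overlap) else NA_real_,
      min = min(d$overlap),
      max = max(d$overlap),
      n_participants = nrow(d)
    )
  }
  by_grade <- lapply(split(per_part, per_part$grade), function(d) {
    summarise_grp(d, paste0("grade_", d$grade[1]))
  })
  summary <- dplyr::bind_rows(c(by_grade,
                                list(summarise_grp(per_part, "overall"))))
  list(per_participant = per_part, summary = summary)
}
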