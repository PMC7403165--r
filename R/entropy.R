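#' Shannon entropy of a categorical distribution
#'
#' `H = -sum(p * log2(p))` in bits, with `0 * log2(0)` defined as 0. Counts
#' are normalised to probabilities first, so the result is invariant to
#' scaling all counts by a constant. Unanimous responses give `H = 0`; a
#' uniform distribution over `k` categories gives `log2(k)`.
#'
#' @param distribution Numeric vector of non-negative counts or
#'   probabilities, at least one positive (names optional; zeros are allowed
#'   and contribute nothing).
#' @return Entropy in bits (non-negative scalar).
#' @export
shannon_entropy <- function(distribution) {
  x <- as.numeric(distribution)
  if (length(x) == 0 || anyNA(x) || any(x < 0) || sum(x) <= 0) {
    stop("distribution must be non-negative with a positive total",
         call. = FALSE)
  }
  p <- x[x > 0] / sum(x)
  -sum(p * log2(p))
}

# per-design inclusion rule: which trials enter an entropy distribution.
# english_style keeps every trial without a consonant error / non-response
# (any transcribed vowel, modelled or not, is a valid response);
# german_style keeps correct trials only, so the outcome is binary.
entropy_trials <- function(records, design) {
  if (design$language_mode == "german_style") {
    records[!records$is_error, ]
  } else {
    records[!records$is_error & records$consonant_correct, ]
  }
}

#' Item-level response entropy
#'
#' Entropy of the distribution of response categories each item elicited
#' across participants, after excluding consonant-error trials
#' (`english_style`) or all incorrect trials (`german_style`). Low entropy
#' means participants agree on the item's pronunciation.
#'
#' @param records A validated response tibble.
#' @param design The [study_design()].
#' @param group_by Optional grouping column (e.g. `"grade"`) computed in
#'   addition to pooling; `NULL` pools the whole sample.
#' @return A tibble with `item_id`, `condition`, the grouping column (if
#'   any), `n_trials`, `n_categories` and `entropy_bits`. Items with no
#'   includable trials in a group are omitted.
#' @export
item_entropy <- function(records, design, group_by = NULL) {
  dat <- entropy_trials(tibble::as_tibble(records), design)
  keys <- c("item_id", "condition", group_by)
  dat |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      n_categories = dplyr::n_distinct(.data$response_category),
      entropy_bits = shannon_entropy(table(.data$response_category)),
      .groups = "drop"
    )
}

#' Summarise item entropies per condition
#'
#' Mean and sample SD of item-level entropy per condition (and group), i.e.
#' the shape in which item entropy is conventionally reported.
#'
#' @param entropies Output of [item_entropy()].
#' @param group_by Grouping column present in `entropies`, or `NULL`.
#' @return A tibble with `condition`, the grouping column (if any), `mean`,
#'   `sd`, `n_items`.
#' @export
entropy_by_condition <- function(entropies, group_by = NULL) {
  keys <- c("condition", group_by)
  entropies |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean = mean(.data$entropy_bits),
      sd = if (dplyr::n() > 1) stats::sd(.data$entropy_bits) else NA_real_,
      n_items = dplyr::n(),
      .groups = "drop"
    )
}

#' Participant-level response entropy
#'
#' Entropy of each participant's own response distribution — how variably one
#' reader pronounces the critical grapheme — overall and, optionally, within
#' each condition. The same trial-inclusion rules as [item_entropy()] apply.
#'
#' @inheritParams item_entropy
#' @param per_condition Also return one row per participant x condition.
#' @return A tibble with `participant_id`, `grade`, `condition` (the label
#'   `"overall"` for the pooled rows), `n_trials`, `n_categories`,
#'   `entropy_bits`.
#' @export
participant_entropy <- function(records, design, per_condition = TRUE) {
  dat <- entropy_trials(tibble::as_tibble(records), design)
  ent <- function(d, cond) {
    d |>
      dplyr::group_by(.data$participant_id, .data$grade) |>
      dplyr::summarise(
        n_trials = dplyr::n(),
        n_categories = dplyr::n_distinct(.data$response_category),
        entropy_bits = shannon_entropy(table(.data$response_category)),
        .groups = "drop"
      ) |>
      dplyr::mutate(condition = cond, .after = "grade")
  }
  out <- ent(dat, "overall")
  if (per_condition) {
    per_cond <- lapply(unname(split(dat, dat$condition)),
                       function(d) ent(d, d$condition[1]))
    out <- dplyr::bind_rows(c(list(out), per_cond))
  }
  out
}

#' Bonferroni-adjusted significance threshold
#'
#' The per-comparison alpha level `alpha / m` used when screening a family of
#' `m` correlations or tests.
#'
#' @param alpha Family-wise alpha (default 0.05).
#' @param m Number of comparisons.
#' @return The adjusted threshold.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha <= 1, m >= 1)
  alpha / m
}
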