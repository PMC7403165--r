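#' Read a pronounced wordlist
#'
#' A lexicon is a delimited table of words annotated with the orthographic
#' cluster of interest and the pronunciation that cluster takes in the word:
#' columns `orthography`, `cluster`, `pronunciation`, and optionally
#' `token_frequency` (non-negative). Cluster membership and monosyllabicity
#' are input properties; no segmentation is performed.
#'
#' @param path Path to a `.csv` or `.tsv` file with a header.
#' @return A tibble of lexicon entries.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  reader <- if (tolower(tools::file_ext(path)) == "csv") readr::read_csv
            else readr::read_tsv
  lex <- reader(path, show_col_types = FALSE, progress = FALSE)
  validate_lexicon(lex)
}

validate_lexicon <- function(lexicon) {
  lexicon <- tibble::as_tibble(lexicon)
  required <- c("orthography", "cluster", "pronunciation")
  missing <- setdiff(required, names(lexicon))
  if (length(missing) > 0) {
    stop("lexicon lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(lexicon$cluster))) {
    stop("every lexicon entry needs a non-empty cluster", call. = FALSE)
  }
  if ("token_frequency" %in% names(lexicon) &&
      any(lexicon$token_frequency < 0, na.rm = TRUE)) {
    stop("token_frequency must be non-negative", call. = FALSE)
  }
  lexicon
}

#' Frequency, consistency and pronunciation entropy of an orthographic cluster
#'
#' For one cluster: (1) its frequency — the number of words containing it;
#' (2) its consistency — the proportion of those words carrying the cluster's
#' most frequent pronunciation; and (3) the Shannon entropy over its possible
#' pronunciations, which, unlike consistency, reflects the full shape of the
#' pronunciation distribution when more than two pronunciations exist.
#' Entropy is reported both type-based (each word counts once) and, when
#' token frequencies are available, token-weighted. Consistency 1 and
#' type entropy 0 are equivalent. Modal-pronunciation ties are broken
#' lexicographically and flagged.
#'
#' @param lexicon A lexicon tibble (see [read_lexicon()]).
#' @param cluster Cluster key to summarise.
#' @return A one-row tibble: `cluster`, `frequency`, `consistency`,
#'   `modal_pronunciation`, `tie` (logical), `entropy_type`, `entropy_token`
#'   (`NA` without token frequencies).
#' @export
cluster_statistics <- function(lexicon, cluster) {
  lexicon <- validate_lexicon(lexicon)
  sub <- lexicon[lexicon$cluster == cluster, ]
  if (nrow(sub) == 0) {
    stop("cluster '", cluster, "' not found in lexicon", call. = FALSE)
  }
  counts <- table(sub$pronunciation)
  modal <- counts[counts == max(counts)]
  tie <- length(modal) > 1
  modal_label <- sort(names(modal))[1]
  entropy_token <- NA_real_
  if ("token_frequency" %in% names(sub) && !anyNA(sub$token_frequency) &&
      sum(sub$token_frequency) > 0) {
    mass <- tapply(sub$token_frequency, sub$pronunciation, sum)
    entropy_token <- shannon_entropy(mass)
  }
  tibble::tibble(
    cluster = cluster,
    frequency = nrow(sub),
    consistency = max(counts) / nrow(sub),
    modal_pronunciation = modal_label,
    tie = tie,
    entropy_type = shannon_entropy(counts),
    entropy_token = entropy_token
  )
}

#' Cluster statistics for every cluster in a lexicon
#'
#' @inheritParams cluster_statistics
#' @return A tibble with one [cluster_statistics()] row per distinct cluster.
#' @export
all_cluster_statistics <- function(lexicon) {
  lexicon <- validate_lexicon(lexicon)
  dplyr::bind_rows(lapply(sort(unique(lexicon$cluster)),
                          function(cl) cluster_statistics(lexicon, cl)))
}

#' Group averages of cluster statistics
#'
#' Unweighted arithmetic means of frequency, consistency and entropy per
#' cluster group (e.g. clusters shared between two item sets vs clusters
#' unique to one).
#'
#' @param stats A tibble with columns `cluster`, `frequency`, `consistency`
#'   and an entropy column (`entropy`, or `entropy_type` as produced by
#'   [all_cluster_statistics()]).
#' @param grouping Named character vector or named list mapping each cluster
#'   to a group label; every cluster in `stats` must be assigned.
#' @return A tibble with `group`, `mean_frequency`, `mean_consistency`,
#'   `mean_entropy`, `n_clusters`.
#' @export
group_averages <- function(stats, grouping) {
  stats <- tibble::as_tibble(stats)
  grouping <- unlist(grouping)
  unassigned <- setdiff(stats$cluster, names(grouping))
  if (length(unassigned) > 0) {
    stop("cluster(s) without a group: ", paste(unassigned, collapse = ", "),
         call. = FALSE)
  }
  entropy_col <- if ("entropy" %in% names(stats)) "entropy" else "entropy_type"
  stats |>
    dplyr::mutate(group = unname(grouping[.data$cluster])) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      mean_frequency = mean(.data$frequency),
      mean_consistency = mean(.data$consistency),
      mean_entropy = mean(.data[[entropy_col]]),
      n_clusters = dplyr::n(),
      .groups = "drop"
    )
}

#' Reference statistics for the critical letter clusters
#'
#' Bundled frequency, consistency and pronunciation-entropy values for nine
#' English onset/body letter clusters, computed from monosyllabic words of
#' the English Lexicon Project. The `group` column splits the clusters into
#' those probed by the current pseudoword design as well as an earlier
#' comparison item set (`"shared"`: alC, qua, wa) and those appearing only in
#' the comparison set (`"comparison_only"`: ead, ild, ind, old, olt, ook).
#' These rows serve as input to [group_averages()] in the worked examples.
#'
#' @return A nine-row tibble: `cluster`, `frequency`, `consistency`,
#'   `entropy`, `group`.
#' @export
critical_cluster_stats <- function() {
  tibble::tribble(
    ~cluster, ~frequency, ~consistency, ~entropy, ~group,
    "alC",    69L,        0.61,         0.46,     "shared",
    "ead",    14L,        0.57,         0.30,     "comparison_only",
    "ild",     6L,        0.50,         0.30,     "comparison_only",
    "ind",     9L,        0.89,         0.15,     "comparison_only",
    "old",    10L,        1.00,         0.00,     "comparison_only",
    "olt",     5L,        1.00,         0.00,     "comparison_only",
    "ook",    12L,        0.92,         0.12,     "comparison_only",
    "qua",    17L,        0.71,         0.35,     "shared",
    "wa",     45L,        0.56,         0.48,     "shared"
  )
}

#' Derive a corpus-probability table from a wordlist
#'
#' Builds `P(category | rule type, condition)` entries as relative
#' frequencies of each pronunciation category among the lexicon words that a
#' (condition, rule type)-specific context predicate selects. This is how
#' language-level conditional probabilities are obtained from any
#' user-supplied pronounced wordlist.
#'
#' @param lexicon A lexicon tibble whose `pronunciation` labels are the
#'   design's response categories.
#' @param design The [study_design()].
#' @param context_definitions A nested named list
#'   `condition -> rule_type -> predicate`, where each predicate is either a
#'   cluster key (string; selects entries with that cluster) or a function of
#'   the lexicon tibble returning a logical row mask. Must cover every
#'   (condition, rule type) pair.
#' @param token_weighted Weight words by `token_frequency` instead of
#'   counting types.
#' @return A [corpus_probs()] table.
#' @export
derive_corpus_probabilities <- function(lexicon, design, context_definitions,
                                        token_weighted = FALSE) {
  lexicon <- validate_lexicon(lexicon)
  rows <- list()
  for (cond in design$conditions) {
    for (rule in design$rule_types) {
      pred <- context_definitions[[cond]][[rule]]
      if (is.null(pred)) {
        stop("no context predicate for (", cond, ", ", rule, ")",
             call. = FALSE)
      }
      mask <- if (is.function(pred)) pred(lexicon)
              else lexicon$cluster == pred
      sub <- lexicon[mask, ]
      if (nrow(sub) == 0) {
        stop("context predicate for (", cond, ", ", rule,
             ") matches no words", call. = FALSE)
      }
      w <- if (token_weighted) sub$token_frequency else rep(1, nrow(sub))
      mass <- tapply(w, sub$pronunciation, sum)
      mass <- mass / sum(mass)
      keep <- names(mass) %in% design$response_categories
      rows[[length(rows) + 1]] <- tibble::tibble(
        condition = cond, rule_type = rule,
        category = names(mass)[keep], prob = as.numeric(mass[keep])
      )
    }
  }
  corpus_probs(dplyr::bind_rows(rows), design)
}
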