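#' Corpus conditional-probability table
#'
#' Holds `P(response category | rule type, condition)`: the probability that a
#' given correspondence type, applied in a given condition's orthographic
#' context, yields each modelled response category. For `english_style`
#' designs the probabilities over modelled categories may sum to less than 1
#' per (condition, rule type); the residual mass is the chance of an
#' unmodelled ("other") vowel. For `german_style` (binary) designs each
#' (condition, rule type) distribution must sum to exactly 1.
#'
#' @param entries A data frame with columns `condition`, `rule_type`,
#'   `category`, `prob`.
#' @param design The [study_design()] the table belongs to.
#'
#' @return An object of class `corpus_probs`: a tibble of entries with the
#'   design attached as an attribute.
#' @export
corpus_probs <- function(entries, design) {
  entries <- tibble::as_tibble(entries)
  required <- c("condition", "rule_type", "category", "prob")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0) {
    stop("corpus_probs entries lack column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  entries <- entries[required]
  bad_cond <- setdiff(entries$condition, design$conditions)
  if (length(bad_cond) > 0) {
    stop("unknown condition(s) in probability table: ",
         paste(bad_cond, collapse = ", "), call. = FALSE)
  }
  bad_rule <- setdiff(entries$rule_type, design$rule_types)
  if (length(bad_rule) > 0) {
    stop("unknown rule type(s) in probability table: ",
         paste(bad_rule, collapse = ", "), call. = FALSE)
  }
  bad_cat <- setdiff(entries$category, design$response_categories)
  if (length(bad_cat) > 0) {
    stop("unmodelled categor(ies) in probability table: ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  if (any(entries$prob < 0 | entries$prob > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  sums <- stats::aggregate(prob ~ condition + rule_type, entries, sum)
  tol <- 1e-8
  if (design$language_mode == "german_style") {
    if (any(abs(sums$prob - 1) > tol)) {
      stop("binary-design probabilities must sum to 1 per (condition, rule type)",
           call. = FALSE)
    }
  } else if (any(sums$prob > 1 + tol)) {
    stop("probabilities sum to more than 1 for some (condition, rule type)",
         call. = FALSE)
  }
  # every (condition, rule_type) pair must be present
  combos <- expand.grid(condition = design$conditions,
                        rule_type = design$rule_types,
                        stringsAsFactors = FALSE)
  have <- unique(entries[c("condition", "rule_type")])
  miss <- dplyr::anti_join(combos, have, by = c("condition", "rule_type"))
  if (nrow(miss) > 0) {
    stop("probability table misses (condition, rule type) pair(s): ",
         paste(paste(miss$condition, miss$rule_type, sep = "/"),
               collapse = ", "),
         call. = FALSE)
  }
  structure(entries, class = c("corpus_probs", class(entries)),
            design = design)
}

# build a corpus_probs from nested list condition -> rule_type -> named probs
corpus_probs_from_nested <- function(nested, design) {
  rows <- purrr::imap(nested, function(rules, cond) {
    purrr::imap(rules, function(p, rule) {
      tibble::tibble(condition = cond, rule_type = rule,
                     category = names(p), prob = as.numeric(unlist(p)))
    })
  })
  corpus_probs(dplyr::bind_rows(purrr::flatten(rows)), design)
}

#' Read a corpus-probability table from YAML or JSON
#'
#' The file holds a nested mapping `condition -> rule_type -> category ->
#' probability`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param design The matching [study_design()].
#' @return A [corpus_probs()] table.
#' @export
read_corpus_probs <- function(path, design) {
  nested <- read_structured(path)
  corpus_probs_from_nested(nested, design)
}

#' Write a corpus-probability table to YAML
#'
#' @param probs A [corpus_probs()] table.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_corpus_probs <- function(probs, path) {
  nested <- split(probs, probs$condition)
  nested <- purrr::map(nested, function(df) {
    purrr::map(split(df, df$rule_type),
               function(r) as.list(stats::setNames(r$prob, r$category)))
  })
  yaml::write_yaml(nested, path)
  invisible(path)
}

# matrix of rule-type prediction columns for one condition:
# rows = modelled categories, cols = rule types (design order)
prob_matrix <- function(probs, condition) {
  design <- attr(probs, "design")
  if (!condition %in% design$conditions) {
    stop("condition '", condition, "' not in design", call. = FALSE)
  }
  sub <- probs[probs$condition == condition, , drop = FALSE]
  m <- matrix(0, nrow = length(design$response_categories),
              ncol = length(design$rule_types),
              dimnames = list(design$response_categories, design$rule_types))
  idx <- cbind(match(sub$category, design$response_categories),
               match(sub$rule_type, design$rule_types))
  m[idx] <- sub$prob
  m
}

#' Predict response-category probabilities from rule weights
#'
#' Computes the mixture prediction for one condition: the predicted
#' probability of each modelled category is the weight-weighted sum of the
#' rule types' conditional probabilities,
#' `predicted(c) = sum_j beta_j * P(c | rule j, condition)`.
#'
#' @param beta Numeric weight vector of length 3, ordered as the design's
#'   rule types (names, if present, are checked).
#' @param probs A [corpus_probs()] table.
#' @param condition Condition label present in the table.
#' @return A named numeric vector over the design's modelled categories.
#' @export
predict_probabilities <- function(beta, probs, condition) {
  design <- attr(probs, "design")
  beta <- as.numeric(check_beta(beta, design))
  m <- prob_matrix(probs, condition)
  drop(m %*% beta)
}

check_beta <- function(beta, design) {
  if (length(beta) != 3L) {
    stop("beta must have length 3 (one weight per rule type)", call. = FALSE)
  }
  if (!is.null(names(beta)) && !identical(names(beta), design$rule_types)) {
    beta <- beta[design$rule_types]
    if (anyNA(beta)) {
      stop("beta names do not match the design's rule types", call. = FALSE)
    }
  }
  beta
}
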