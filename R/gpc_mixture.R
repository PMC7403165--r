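#' Observed response proportions per participant and condition
#'
#' Computes, for each participant and condition, the proportion of each
#' modelled response category among that participant's non-error trials.
#' Incorrect responses are removed before fitting. By default the denominator
#' is all non-error trials, so valid-but-unmodelled responses (e.g. "other
#' vowel") dilute the modelled proportions; set `renormalize_modeled = TRUE`
#' to restrict the denominator to modelled categories.
#'
#' Conditions in which a participant has no non-error trials are dropped from
#' that participant's table (and hence from the fit) with a message.
#'
#' @param records A validated, pre-filtered response tibble.
#' @param design The [study_design()].
#' @param participant_id Optional single participant to restrict to.
#' @param renormalize_modeled Restrict denominators to modelled categories.
#' @return A tibble with columns `participant_id`, `condition`, `category`,
#'   `proportion`, `n_trials` (the denominator used), one row per modelled
#'   category per usable condition.
#' @export
observed_proportions <- function(records, design, participant_id = NULL,
                                 renormalize_modeled = FALSE) {
  dat <- tibble::as_tibble(records)
  if (!is.null(participant_id)) {
    dat <- dat[dat$participant_id %in% participant_id, ]
  }
  dat <- dat[!dat$is_error, ]
  if (renormalize_modeled) {
    dat <- dat[dat$response_category %in% design$response_categories, ]
  }
  denom <- dat |>
    dplyr::count(.data$participant_id, .data$condition, name = "n_trials")
  # conditions a participant never produced a usable trial in simply have no
  # rows here; fit_weights counts the usable conditions it receives
  counts <- dat |>
    dplyr::filter(.data$response_category %in% design$response_categories) |>
    dplyr::count(.data$participant_id, .data$condition,
                 .data$response_category, name = "k")
  out <- denom |>
    tidyr::crossing(category = design$response_categories) |>
    dplyr::left_join(counts,
                     by = c("participant_id", "condition",
                            category = "response_category")) |>
    dplyr::mutate(k = dplyr::coalesce(.data$k, 0L),
                  proportion = .data$k / .data$n_trials) |>
    dplyr::select("participant_id", "condition", "category", "proportion",
                  "n_trials")
  dropped <- length(unique(dat$participant_id)) * length(design$conditions) -
    nrow(dplyr::distinct(denom, .data$participant_id, .data$condition))
  if (!is.null(participant_id) && dropped > 0) {
    message(dropped, " condition(s) dropped (no usable trials)")
  }
  out
}

#' Fit correspondence weights for one participant
#'
#' Finds the weight vector `beta` over the design's three rule types that
#' minimises the sum of squared differences between the observed
#' per-condition category proportions and the mixture predictions
#' `sum_j beta_j * P(category | rule j, condition)`, pooled over all usable
#' (condition, category) cells with equal weight.
#'
#' With `constrained = TRUE` (the default) the weights are restricted to the
#' probability simplex (`beta_j in [0, 1]`, `sum(beta) = 1`), interpreting
#' each weight as the probability of relying on that correspondence type. The
#' problem is then a 3-parameter convex quadratic programme, solved exactly by
#' enumerating the simplex's faces and taking the feasible equality-
#' constrained least-squares minimiser, so the returned loss is the global
#' simplex minimum (up to numerical tolerance). With `constrained = FALSE`
#' all constraints (sum-to-one and both bounds) are dropped and the fit is
#' ordinary least squares; the relaxed loss can therefore never exceed the
#' constrained loss.
#'
#' Inputs on a percentage scale (values above 1) are rescaled to proportions
#' so that both scales yield identical weights.
#'
#' @param observed A tibble with columns `condition`, `category`,
#'   `proportion` (as from [observed_proportions()], one participant).
#' @param probs A [corpus_probs()] table covering all conditions present.
#' @param constrained Restrict `beta` to the probability simplex.
#' @return A list of class `weight_fit`: `beta` (named numeric, design rule
#'   order), `loss`, `constrained`, `converged`, `identifiable` (`FALSE` when
#'   the three rule-prediction vectors are linearly dependent, in which case
#'   the minimiser is not unique), and `n_conditions_used`.
#' @export
fit_weights <- function(observed, probs, constrained = TRUE) {
  design <- attr(probs, "design")
  observed <- tibble::as_tibble(observed)
  stopifnot(all(c("condition", "category", "proportion") %in% names(observed)))
  observed <- observed[observed$category %in% design$response_categories, ]
  conds <- intersect(design$conditions, unique(observed$condition))
  if (length(conds) < 2L) {
    stop("fit needs observed data in at least 2 conditions, got ",
         length(conds), call. = FALSE)
  }
  X <- do.call(rbind, lapply(conds, function(cd) prob_matrix(probs, cd)))
  key <- paste(rep(conds, each = length(design$response_categories)),
               rep(design$response_categories, length(conds)))
  y <- observed$proportion[match(key, paste(observed$condition,
                                            observed$category))]
  keep <- !is.na(y)
  X <- X[keep, , drop = FALSE]
  y <- y[keep]
  if (max(y) > 1 + 1e-9) y <- y / 100  # percentage-scale input
  identifiable <- qr(X, tol = 1e-10)$rank == 3L

  if (constrained) {
    sol <- solve_simplex_lsq(X, y)
  } else {
    fit <- stats::lm.fit(X, y)
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0  # rank-deficient: drop aliased directions
    sol <- list(beta = beta, converged = TRUE)
  }
  beta <- stats::setNames(as.numeric(sol$beta), design$rule_types)
  structure(
    list(beta = beta,
         loss = sum((y - drop(X %*% beta))^2),
         constrained = constrained,
         converged = sol$converged,
         identifiable = identifiable,
         n_conditions_used = length(conds)),
    class = "weight_fit"
  )
}

#' @export
print.weight_fit <- function(x, ...) {
  cat("<weight_fit> ", if (x$constrained) "simplex-constrained" else "relaxed",
      "\n", sep = "")
  print(round(x$beta, 4))
  cat("loss:", format(x$loss, digits = 6),
      " identifiable:", x$identifiable,
      " conditions:", x$n_conditions_used, "\n")
  invisible(x)
}

# exact minimiser of ||X b - y||^2 over the 3-simplex by face enumeration:
# every KKT point of a convex QP over the simplex lies on some face; solve the
# equality-constrained LS problem on each face and keep the best feasible one.
solve_simplex_lsq <- function(X, y) {
  p <- ncol(X)
  best <- NULL
  best_loss <- Inf
  faces <- unlist(lapply(seq_len(p), function(k) {
    utils::combn(p, k, simplify = FALSE)
  }), recursive = FALSE)
  for (free in faces) {
    b <- rep(0, p)
    if (length(free) == 1L) {
      b[free] <- 1
    } else {
      Xf <- X[, free, drop = FALSE]
      k <- length(free)
      # KKT system for min ||Xf b - y||^2 s.t. sum(b) = 1
      A <- rbind(cbind(2 * crossprod(Xf), rep(1, k)), c(rep(1, k), 0))
      rhs <- c(2 * crossprod(Xf, y), 1)
      bf <- tryCatch(solve(A, rhs)[seq_len(k)], error = function(e) NULL)
      if (is.null(bf)) next  # singular face (degenerate rule vectors)
      if (any(bf < -1e-9)) next
      b[free] <- pmax(bf, 0)
      b <- b / sum(b)
    }
    loss <- sum((y - drop(X %*% b))^2)
    if (loss < best_loss - 1e-12 ||
        (loss < best_loss + 1e-12 && is.null(best))) {
      best <- b
      best_loss <- loss
    }
  }
  list(beta = best, converged = !is.null(best))
}

#' Fit correspondence weights for every participant
#'
#' Runs [observed_proportions()] and [fit_weights()] per participant and
#' collects the results in a tidy table. Participants with fewer than two
#' usable conditions are skipped with a warning naming them.
#'
#' @inheritParams observed_proportions
#' @param probs A [corpus_probs()] table.
#' @param constrained Passed to [fit_weights()].
#' @return A tibble with one row per fitted participant: `participant_id`,
#'   `grade`, one `beta_<rule type>` column per rule type, `loss`,
#'   `converged`, `identifiable`, `n_conditions_used`.
#' @export
fit_participants <- function(records, design, probs, constrained = TRUE,
                             renormalize_modeled = FALSE) {
  obs <- observed_proportions(records, design,
                              renormalize_modeled = renormalize_modeled)
  grades <- records |>
    dplyr::distinct(.data$participant_id, .data$grade)
  skipped <- character()
  rows <- lapply(split(obs, obs$participant_id), function(o) {
    if (length(unique(o$condition)) < 2L) {
      skipped <<- c(skipped, o$participant_id[1])
      return(NULL)
    }
    fit <- fit_weights(o, probs, constrained = constrained)
    out <- tibble::tibble(participant_id = o$participant_id[1],
                          loss = fit$loss,
                          converged = fit$converged,
                          identifiable = fit$identifiable,
                          n_conditions_used = fit$n_conditions_used)
    for (j in seq_along(fit$beta)) {
      out[[paste0("beta_", names(fit$beta)[j])]] <- fit$beta[[j]]
    }
    out
  })
  if (length(skipped) > 0) {
    warning("skipped participant(s) with < 2 usable conditions: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  dplyr::bind_rows(rows) |>
    dplyr::left_join(grades, by = "participant_id") |>
    dplyr::relocate("grade", .after = "participant_id")
}

#' Correlation between observed and model-predicted response percentages
#'
#' For each group (default: grade), pools every fitted participant's observed
#' and predicted percentages across conditions and modelled categories and
#' returns the Pearson correlation — a global measure of how well the mixture
#' model describes the response pattern.
#'
#' @param fits Output of [fit_participants()].
#' @param records The response tibble the fits were computed from.
#' @param design The [study_design()].
#' @param probs The [corpus_probs()] table used for fitting.
#' @param group_by Grouping column in `fits` (default `"grade"`); `NULL`
#'   pools the whole sample.
#' @param renormalize_modeled Must match the value used when fitting.
#' @return A tibble with the grouping column, `r` (Pearson correlation;
#'   `NA` when either pooled vector has zero variance) and `n_pairs`.
#' @export
model_fit_correlation <- function(fits, records, design, probs,
                                  group_by = "grade",
                                  renormalize_modeled = FALSE) {
  obs <- observed_proportions(records, design,
                              renormalize_modeled = renormalize_modeled)
  obs <- obs[obs$participant_id %in% fits$participant_id, ]
  beta_cols <- paste0("beta_", design$rule_types)
  pred_tab <- tidyr::crossing(condition = design$conditions,
                              category = design$response_categories)
  preds <- lapply(seq_len(nrow(fits)), function(i) {
    beta <- as.numeric(fits[i, beta_cols])
    pr <- unlist(lapply(design$conditions, function(cd) {
      predict_probabilities(beta, probs, cd)
    }))
    tibble::tibble(participant_id = fits$participant_id[i],
                   condition = rep(design$conditions,
                                   each = length(design$response_categories)),
                   category = rep(design$response_categories,
                                  length(design$conditions)),
                   predicted = 100 * pr)
  })
  paired <- dplyr::bind_rows(preds) |>
    dplyr::inner_join(obs, by = c("participant_id", "condition", "category")) |>
    dplyr::mutate(observed = 100 * .data$proportion)
  if (!is.null(group_by)) {
    paired <- dplyr::left_join(
      paired,
      dplyr::distinct(fits, .data$participant_id,
                      dplyr::across(dplyr::all_of(group_by))),
      by = "participant_id"
    )
  }
  keys <- if (is.null(group_by)) character() else group_by
  paired |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      r = if (dplyr::n() < 3 ||
              stats::sd(.data$observed) == 0 ||
              stats::sd(.data$predicted) == 0) NA_real_
          else stats::cor(.data$observed, .data$predicted),
      n_pairs = dplyr::n(),
      .groups = "drop"
    )
}

#' Aggregate fitted weights by group
#'
#' Arithmetic mean and sample SD of each rule type's weight per group
#' (default: grade). Non-identifiable fits are excluded with a message giving
#' the count; a single fit in a group has SD `NA`.
#'
#' @inheritParams model_fit_correlation
#' @param design The [study_design()] (for rule-type column names).
#' @return A tibble with the grouping column, `rule_type`, `mean`, `sd`, `n`.
#' @export
aggregate_weights <- function(fits, design, group_by = "grade") {
  excluded <- sum(!fits$identifiable)
  if (excluded > 0) {
    message(excluded, " non-identifiable fit(s) excluded from aggregation")
    fits <- fits[fits$identifiable, ]
  }
  beta_cols <- paste0("beta_", design$rule_types)
  keys <- if (is.null(group_by)) character() else group_by
  fits |>
    tidyr::pivot_longer(dplyr::all_of(beta_cols),
                        names_to = "rule_type", values_to = "beta",
                        names_prefix = "beta_") |>
    dplyr::mutate(rule_type = factor(.data$rule_type,
                                     levels = design$rule_types)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys)), .data$rule_type) |>
    dplyr::summarise(
      mean = mean(.data$beta),
      sd = if (dplyr::n() > 1) stats::sd(.data$beta) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    )
}
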