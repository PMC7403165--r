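#' Define a simulation profile
#'
#' Describes a population of simulated readers under the response mechanism
#' the analyses assume: on each trial a reader first samples one of the three
#' correspondence types according to their weight vector, then samples a
#' response from that rule's conditional distribution for the item's
#' condition; with probability `lapse_rate` the response is overwritten by an
#' unsystematic draw — uniform over the modelled categories plus any
#' unmodelled valid category — and with probability `consonant_error_rate`
#' the trial is a consonant error / non-response (`is_error = TRUE`).
#'
#' Defaults emulate a three-grade cohort (21/20/20 readers in grades 2-4)
#' whose grade-level weight mixtures shift between the simple and the
#' onset-context correspondence, with a 10% consonant-error rate.
#'
#' @param n_participants_per_grade Named integer vector, grade -> count.
#' @param true_beta Either one numeric weight vector of length 3 (applied to
#'   every grade) or a named list of such vectors, one per grade. Each must
#'   lie on the probability simplex.
#' @param lapse_rate Probability in `[0, 1]` of an unsystematic response.
#' @param consonant_error_rate Probability in `[0, 1]` a trial is an error.
#' @param n_sessions 1 or 2; sessions are independent given the profile.
#' @param dirichlet_concentration Optional positive scalar; when set, each
#'   participant's weights are drawn from a Dirichlet centred on the grade
#'   weights with this concentration (larger = less heterogeneity). `NULL`
#'   (default) gives every participant the grade weights exactly, which is
#'   what parameter-recovery checks need.
#' @param seed Integer root seed; per-participant streams are derived from it
#'   deterministically, so enlarging one grade never perturbs the trials of
#'   existing participants in other grades.
#' @return An object of class `simulation_profile`.
#' @export
simulation_profile <- function(n_participants_per_grade = c("2" = 21L,
                                                            "3" = 20L,
                                                            "4" = 20L),
                               true_beta = list(
                                 "2" = c(0.24, 0.63, 0.13),
                                 "3" = c(0.07, 0.79, 0.14),
                                 "4" = c(0.23, 0.63, 0.14)
                               ),
                               lapse_rate = 0,
                               consonant_error_rate = 0.10,
                               n_sessions = 1L,
                               dirichlet_concentration = NULL,
                               seed = 1L) {
  grades <- names(n_participants_per_grade)
  if (is.null(grades)) {
    stop("n_participants_per_grade must be named by grade", call. = FALSE)
  }
  if (!is.list(true_beta)) {
    true_beta <- stats::setNames(rep(list(true_beta), length(grades)), grades)
  }
  missing_beta <- setdiff(grades, names(true_beta))
  if (length(missing_beta) > 0) {
    stop("true_beta missing for grade(s): ",
         paste(missing_beta, collapse = ", "), call. = FALSE)
  }
  for (g in grades) {
    b <- true_beta[[g]]
    if (length(b) != 3 || any(b < 0) || abs(sum(b) - 1) > 1e-8) {
      stop("true_beta for grade ", g, " must be length 3, non-negative, ",
           "and sum to 1", call. = FALSE)
    }
  }
  stopifnot(lapse_rate >= 0, lapse_rate <= 1,
            consonant_error_rate >= 0, consonant_error_rate <= 1,
            n_sessions %in% c(1L, 2L))
  structure(
    list(n_participants_per_grade = n_participants_per_grade,
         true_beta = true_beta[grades],
         lapse_rate = lapse_rate,
         consonant_error_rate = consonant_error_rate,
         n_sessions = as.integer(n_sessions),
         dirichlet_concentration = dirichlet_concentration,
         seed = as.integer(seed)),
    class = "simulation_profile"
  )
}

# deterministic per-participant seed, independent of other grades' counts
participant_seed <- function(root, grade_index, within_index) {
  ((root %% 100000L) * 7919 + grade_index * 99991 + within_index * 101) %%
    2147483629 + 1
}

#' Simulate a trial-level response table
#'
#' Generates one `ResponseRecord` row per participant x condition x item x
#' session under the mixture-plus-lapse mechanism of [simulation_profile()].
#' Fully reproducible: the same profile (including its seed), design and
#' probability table always yield the same table.
#'
#' @param profile A [simulation_profile()].
#' @param design A [study_design()].
#' @param probs A [corpus_probs()] table for the design.
#' @param items_per_condition Optional named override of the design's item
#'   counts.
#' @return A validated response tibble with an extra `true_` attribute-free
#'   column set: standard columns only, ready for [apply_filters()] etc.
#' @export
simulate_study <- function(profile, design, probs,
                           items_per_condition = NULL) {
  stopifnot(inherits(profile, "simulation_profile"),
            inherits(design, "study_design"),
            inherits(probs, "corpus_probs"))
  n_items <- design$items_per_condition
  if (!is.null(items_per_condition)) {
    if (!is.null(names(items_per_condition))) {
      items_per_condition <- items_per_condition[design$conditions]
    } else if (length(items_per_condition) == 1L) {
      items_per_condition <- rep(items_per_condition, 4L)
    }
    n_items[] <- as.integer(items_per_condition)
    if (anyNA(n_items) || any(n_items < 1L)) {
      stop("items_per_condition must give a positive count per condition",
           call. = FALSE)
    }
  }
  lapse_set <- valid_categories(design)
  # per-condition sampling matrix: modelled categories plus residual "other"
  # mass per rule column (english rows may sum < 1)
  samp <- lapply(design$conditions, function(cd) {
    m <- prob_matrix(probs, cd)
    residual <- pmax(0, 1 - colSums(m))
    if (any(residual > 1e-12)) {
      other <- design$other_categories[1]
      if (is.na(other)) {
        stop("probability table leaves residual mass but the design has no ",
             "unmodelled category to absorb it", call. = FALSE)
      }
      m <- rbind(m, residual)
      rownames(m)[nrow(m)] <- other
    }
    m
  })
  names(samp) <- design$conditions

  grades <- names(profile$n_participants_per_grade)
  out <- vector("list", sum(profile$n_participants_per_grade))
  k <- 0L
  for (gi in seq_along(grades)) {
    g <- grades[gi]
    beta_g <- profile$true_beta[[g]]
    for (i in seq_len(profile$n_participants_per_grade[[g]])) {
      k <- k + 1L
      set.seed(participant_seed(profile$seed, gi, i))
      beta <- beta_g
      if (!is.null(profile$dirichlet_concentration)) {
        shape <- profile$dirichlet_concentration * beta_g
        draw <- stats::rgamma(3, shape = pmax(shape, 1e-8))
        beta <- draw / sum(draw)
      }
      trials <- tidyr::crossing(
        session = seq_len(profile$n_sessions),
        condition = design$conditions
      ) |>
        dplyr::group_by(.data$session, .data$condition) |>
        dplyr::reframe(item_id = sprintf("%s_%02d", .data$condition,
                                         seq_len(n_items[[.data$condition[1]]])))
      n <- nrow(trials)
      rule <- sample.int(3L, n, replace = TRUE, prob = beta)
      category <- character(n)
      for (cd in design$conditions) {
        m <- samp[[cd]]
        for (j in 1:3) {
          idx <- which(trials$condition == cd & rule == j)
          if (length(idx) > 0) {
            category[idx] <- sample(rownames(m), length(idx), replace = TRUE,
                                    prob = m[, j])
          }
        }
      }
      lapse <- stats::runif(n) < profile$lapse_rate
      if (any(lapse)) {
        category[lapse] <- sample(lapse_set, sum(lapse), replace = TRUE)
      }
      err <- stats::runif(n) < profile$consonant_error_rate
      category[err] <- "consonant_error"
      out[[k]] <- tibble::tibble(
        participant_id = sprintf("g%s_p%02d", g, i),
        grade = as.integer(g),
        item_id = trials$item_id,
        condition = trials$condition,
        session = as.integer(trials$session),
        response_category = category,
        consonant_correct = !err,
        is_error = err
      )
    }
  }
  validate_responses(dplyr::bind_rows(out), design)
}
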