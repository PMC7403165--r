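#' Configure a full analysis run
#'
#' Collects everything [run_pipeline()] needs: a design and probability table
#' (objects or file paths), the responses (a tibble, a file path, or a
#' [simulation_profile()] to generate them), filter thresholds, fitting
#' flags, an output directory and a seed.
#'
#' @param design A [study_design()] or path to a design YAML/JSON.
#' @param probs A [corpus_probs()] or path to a probability YAML/JSON.
#' @param responses A response tibble, a path to a delimited response table,
#'   or `NULL` to simulate from `profile`.
#' @param profile A [simulation_profile()] used when `responses` is `NULL`.
#' @param participant_threshold,item_threshold Error-rate filter thresholds
#'   (strict inequality; defaults 0.5 and 0.6).
#' @param relaxed Also fit the unconstrained (relaxed) variant.
#' @param renormalize_modeled Passed to the fitting stage.
#' @param out_dir Directory the report tables are written to.
#' @param seed Integer seed used when simulating.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(design, probs, responses = NULL, profile = NULL,
                            participant_threshold = 0.5, item_threshold = 0.6,
                            relaxed = FALSE, renormalize_modeled = FALSE,
                            out_dir = "results", seed = 1L) {
  stopifnot(participant_threshold >= 0, participant_threshold <= 1,
            item_threshold >= 0, item_threshold <= 1)
  if (is.character(design)) design <- read_design(design)
  if (is.character(probs)) probs <- read_corpus_probs(probs, design)
  if (is.null(responses) && is.null(profile)) {
    stop("provide either responses or a simulation profile", call. = FALSE)
  }
  structure(
    list(design = design, probs = probs, responses = responses,
         profile = profile, participant_threshold = participant_threshold,
         item_threshold = item_threshold, relaxed = relaxed,
         renormalize_modeled = renormalize_modeled, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: load or simulate responses; apply the participant and
#' item error-rate filters; condition x category descriptives; per-participant
#' weight fits (constrained, plus the relaxed variant on request) with
#' per-grade aggregation and model-fit correlations; item- and
#' participant-level entropy; and, when two sessions are present, test-retest
#' overlap. All tables are returned and written as CSV to the configured
#' output directory together with a run log and a configuration echo. Output
#' is deterministic given the configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the report tables plus `log` (character
#'   vector of log lines).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  design <- config$design
  probs <- config$probs
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))

  responses <- config$responses
  if (is.null(responses)) {
    profile <- config$profile
    profile$seed <- config$seed
    responses <- simulate_study(profile, design, probs)
    note("simulated ", nrow(responses), " trials (seed ", config$seed, ")")
  } else if (is.character(responses)) {
    responses <- read_responses(responses, design)
    note("read ", nrow(responses), " trials")
  } else {
    responses <- validate_responses(responses, design)
    note("validated ", nrow(responses), " trials")
  }

  filt <- apply_filters(responses, config$participant_threshold,
                        config$item_threshold)
  note("removed ", nrow(filt$removed_participants), " participant(s) with ",
       "error rate > ", config$participant_threshold)
  note("removed ", nrow(filt$removed_items), " item(s) with error rate > ",
       config$item_threshold)
  kept <- filt$records

  tables <- list()
  tables$condition_summary <- condition_summary(kept, design,
                                                group_by = "grade")
  fits <- fit_participants(kept, design, probs, constrained = TRUE,
                           renormalize_modeled = config$renormalize_modeled)
  note("fitted ", nrow(fits), " participants (constrained)")
  tables$weight_fits <- fits
  tables$weights_by_grade <- aggregate_weights(fits, design)
  tables$model_fit <- model_fit_correlation(
    fits, kept, design, probs,
    renormalize_modeled = config$renormalize_modeled
  )
  if (config$relaxed) {
    relaxed_fits <- fit_participants(
      kept, design, probs, constrained = FALSE,
      renormalize_modeled = config$renormalize_modeled
    )
    tables$weight_fits_relaxed <- relaxed_fits
    tables$weights_by_grade_relaxed <- aggregate_weights(relaxed_fits, design)
    note("fitted ", nrow(relaxed_fits), " participants (relaxed)")
  }

  items <- item_entropy(kept, design, group_by = "grade")
  tables$item_entropy <- items
  tables$item_entropy_by_condition <- entropy_by_condition(items,
                                                           group_by = "grade")
  tables$participant_entropy <- participant_entropy(kept, design)

  # participant-level screening family: overall + per-condition entropy,
  # a raw and a standardised ability score -> choose(6, 2) = 15 comparisons
  m <- choose(2 + length(design$conditions), 2)
  alpha <- bonferroni_alpha(0.05, m)
  note("multiple comparisons: alpha 0.05/", m, " = ", round(alpha, 3),
       " for the participant-level correlation family")
  tables$multiple_comparisons <- tibble::tibble(
    family = "participant_entropy_by_ability",
    n_comparisons = m,
    alpha_family = 0.05,
    alpha_per_comparison = alpha
  )

  if (2L %in% kept$session) {
    ov <- code_overlap(kept)
    po <- participant_overlap(ov)
    tables$overlap_per_participant <- po$per_participant
    tables$overlap_summary <- po$summary
    note("test-retest overlap computed for ",
         nrow(po$per_participant), " participants")
  }

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(config$out_dir,
                                             paste0(nm, ".csv")))
  }
  writeLines(log, file.path(config$out_dir, "run.log"))
  echo <- config[c("participant_threshold", "item_threshold", "relaxed",
                   "renormalize_modeled", "seed")]
  jsonlite::write_json(echo, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  note("wrote ", length(tables), " tables to ", config$out_dir)
  invisible(c(tables, list(log = log)))
}
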