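#!/usr/bin/env Rscript
# Generate the synthetic study cohorts every later step analyses: an English
# and a German 4-condition pseudoword experiment, plus an English two-session
# retest cohort. Readers are mixture-of-rules responders (grade-level weight
# vectors) with a 10% consonant-error rate; the retest cohort adds a 20% lapse
# rate so session-to-session instability is visible downstream.

library(gpcmix)

seed <- 20260101L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)
pd <- preset_designs()

english <- simulate_study(
  simulation_profile(seed = seed),
  pd$english$design, pd$english$probs
)
write_responses(english, "results/data/english_responses.csv")
cat("English cohort:", length(unique(english$participant_id)),
    "children,", nrow(english), "trials\n")

german <- simulate_study(
  simulation_profile(
    true_beta = list("2" = c(0.60, 0.34, 0.06),
                     "3" = c(0.62, 0.27, 0.11),
                     "4" = c(0.51, 0.29, 0.20)),
    n_participants_per_grade = c("2" = 19L, "3" = 19L, "4" = 17L),
    consonant_error_rate = 0.09, seed = seed + 1L
  ),
  pd$german$design, pd$german$probs
)
write_responses(german, "results/data/german_responses.csv")
cat("German cohort:", length(unique(german$participant_id)),
    "children,", nrow(german), "trials\n")

retest <- simulate_study(
  simulation_profile(
    n_participants_per_grade = c("2" = 3L, "3" = 5L, "4" = 9L),
    true_beta = c(0.2, 0.7, 0.1),
    lapse_rate = 0.2, consonant_error_rate = 0.08,
    n_sessions = 2L, seed = seed + 2L
  ),
  pd$english$design, pd$english$probs
)
write_responses(retest, "results/data/retest_responses.csv")
cat("Retest cohort:", length(unique(retest$participant_id)),
    "children x 2 sessions,", nrow(retest), "trials\n")
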