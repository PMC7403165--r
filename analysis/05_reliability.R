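#!/usr/bin/env Rscript
# Test-retest stability: code each item 1 when a child gave the same vowel
# category in both sessions (or was incorrect in both) and 0 otherwise, then
# summarise the per-child overlap proportion.

library(gpcmix)

pd <- preset_designs()
records <- read_responses("results/data/retest_responses.csv",
                          pd$english$design)
overlaps <- code_overlap(records)
po <- participant_overlap(overlaps)
readr::write_csv(po$per_participant, "results/retest_overlap_participants.csv")
readr::write_csv(po$summary, "results/retest_overlap_summary.csv")

overall <- po$summary[po$summary$group == "overall", ]
cat(sprintf(
  "overlap across sessions: mean %.2f (SD %.2f), range %.2f-%.2f, n = %d\n",
  overall$mean, overall$sd, overall$min, overall$max, overall$n_participants
))
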