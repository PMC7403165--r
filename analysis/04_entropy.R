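#!/usr/bin/env Rscript
# Quantify response variability with Shannon entropy: per item (how much do
# children disagree on one pseudoword?) and per participant (how variably does
# one child pronounce the critical grapheme?), overall and per condition.
# Participant-level entropies feed a 15-comparison correlation family, so the
# screening threshold is Bonferroni-adjusted to 0.05/15 = 0.003.

library(gpcmix)

pd <- preset_designs()

for (lang in c("english", "german")) {
  des <- pd[[lang]]$design
  records <- read_responses(sprintf("results/data/%s_filtered.csv", lang), des)

  items <- item_entropy(records, des, group_by = "grade")
  readr::write_csv(items, sprintf("results/%s_item_entropy.csv", lang))
  by_cond <- entropy_by_condition(items, group_by = "grade")
  readr::write_csv(by_cond,
                   sprintf("results/%s_item_entropy_by_condition.csv", lang))
  parts <- participant_entropy(records, des)
  readr::write_csv(parts, sprintf("results/%s_participant_entropy.csv", lang))

  cat(sprintf("%s mean item entropy by condition (whole sample):\n", lang))
  pooled <- entropy_by_condition(item_entropy(records, des))
  print(as.data.frame(pooled), digits = 2)
  cat("\n")
}

alpha <- bonferroni_alpha(0.05, 15)
cat(sprintf("participant-level correlation screening: alpha 0.05/15 = %.3f\n",
            alpha))
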