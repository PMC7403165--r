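#!/usr/bin/env Rscript
# Preprocessing and descriptives: drop children with > 50% errors and items
# with > 60% errors (rates computed on the raw table), then tabulate mean (SD)
# response counts (English) and percentages (German) per condition and grade.

library(gpcmix)

pd <- preset_designs()
dir.create("results", showWarnings = FALSE)

for (lang in c("english", "german")) {
  des <- pd[[lang]]$design
  records <- read_responses(sprintf("results/data/%s_responses.csv", lang),
                            des)
  filt <- apply_filters(records)
  cat(sprintf(
    "%s: removed %d participant(s) (> 50%% errors), %d item(s) (> 60%% errors)\n",
    lang, nrow(filt$removed_participants), nrow(filt$removed_items)
  ))
  write_responses(filt$records,
                  sprintf("results/data/%s_filtered.csv", lang))
  summary <- condition_summary(filt$records, des, group_by = "grade")
  readr::write_csv(summary,
                   sprintf("results/%s_condition_summary.csv", lang))
  cat(sprintf("%s: condition summary over %d grade x condition x category cells\n",
              lang, nrow(summary)))
}
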