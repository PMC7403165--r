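#!/usr/bin/env Rscript
# Orthographic-cluster statistics: group means of frequency, consistency and
# pronunciation entropy for the nine bundled reference clusters, split into
# clusters probed by the current design ("shared") vs the earlier comparison
# set only. Higher-frequency, lower-consistency clusters are the ones whose
# context-sensitive correspondences children pick up earliest.

library(gpcmix)

stats <- critical_cluster_stats()
ga <- group_averages(stats, setNames(stats$group, stats$cluster))
readr::write_csv(stats, "results/cluster_stats.csv")
readr::write_csv(ga, "results/cluster_group_means.csv")
print(as.data.frame(ga), digits = 3)
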