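#!/usr/bin/env Rscript
# Pulse-chase waning: a cohort labeled once by tamoxifen, with labeled
# clones stochastically replaced by unlabeled ones ("going dark") at
# 6%/day. Pooled labeling density declines across days 4 -> 32 while
# follicles that keep a labeled clone keep their labeled-cell counts.

suppressPackageStartupMessages(library(tfrtrace))
dir.create("results", showWarnings = FALSE)

cfg <- example_scenarios(20240904)$fig3_godark
print(cfg)
bundle <- run_scenario(cfg)

write.table(bundle$day_summary, "results/waning_day_summary.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(bundle$follicle_stats, "results/waning_follicle_stats.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)

ds <- bundle$day_summary
cat("\nPooled labeling density by day:\n")
print(ds[, c("day", "labeling_density", "n_labeled_follicles",
             "mean_labeled_per_labeled_follicle")], row.names = FALSE,
      digits = 3)
cat("\nDensity declines", sprintf("%.1f-fold", ds$labeling_density[1] /
      ds$labeling_density[3]),
    "from day 4 to day 32, while labeled-cell counts inside",
    "still-labeled follicles remain roughly constant (few follicles\n",
    "remain at late days, so those means are noisy): whole follicles",
    "go dark, individual labeled follicles do not fade.\n")
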