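#!/usr/bin/env Rscript
# When can the divergence test see oligoclonal expansion? Power across a
# grid of effect sizes (Dirichlet concentration; small = strong skew)
# and labeled cells per follicle, at test level 0.05.

suppressPackageStartupMessages(library(tfrtrace))
dir.create("results", showWarnings = FALSE)

cfg <- scenario_config(seed = 20240904)
pw <- power_analysis(cfg,
                     effect_grid = c(0.05, 0.3, 1, 3, 10, 1e6),
                     n_grid = c(5, 15, 30, 100),
                     reps = 400, alpha = 0.05, seed = 99)
write.table(pw, "results/power_grid.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Power to call a follicle oligoclonal (alpha = 0.05):\n")
print(xtabs(power ~ effect + n_cells, data = pw))
cat("\nAt the labeled-cell counts the imaging readout typically yields",
    "(5-15 per follicle),\nonly strong skew (concentration <= 0.3) is",
    "reliably detectable; a finding of\n'no difference' at such counts",
    "bounds only gross oligoclonality.\n")
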