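#!/usr/bin/env Rscript
# The generative cassette model: distinguishable color states, their
# closed-form probabilities across recombination rates, and the
# small-sample bias of the two clonality statistics under the null.

suppressPackageStartupMessages(library(tfrtrace))
dir.create("results", showWarnings = FALSE)

states <- confetti_states(2)
cat("Homozygous Confetti cassette:", length(states),
    "distinguishable labeled states\n")
cat(paste(states, collapse = ", "), "\n\n")

grid <- data.frame(rate = c(0.1, 0.25, 0.5, 0.75, 0.9))
dist_tab <- do.call(rbind, lapply(grid$rate, function(r) {
  d <- state_distribution(recombination_model(r))
  data.frame(rate = r, state = names(d), probability = as.numeric(d))
}))
write.table(dist_tab, "results/cassette_state_distribution.tsv",
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("Labeling probability 1-(1-r)^2 at r = 0.5:",
    labeling_probability(recombination_model(0.5)), "\n")

# Null bias: with few labeled cells both statistics are inflated, the
# reason per-follicle readouts below a minimum cell count are withheld.
unif10 <- setNames(rep(0.1, 10), states)
bp <- rbind(
  cbind(statistic = "clonal_dominance",
        bias_profile("clonal_dominance", unif10,
                     c(2, 5, 10, 20, 50, 100, 500), reps = 5000,
                     seed = 1)),
  cbind(statistic = "divergence_index",
        bias_profile("divergence_index", unif10,
                     c(2, 5, 10, 20, 50, 100, 500), reps = 5000,
                     seed = 2))
)
write.table(bp, "results/null_bias_profile.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\nNull means by sample size (uniform-10 baseline):\n")
print(bp[, c("statistic", "n", "mean", "q95")], row.names = FALSE,
      digits = 3)
cat("\nBoth statistics shrink toward their large-n limits;",
    "per-follicle values at n < 5 are dominated by this bias.\n")
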