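# Shared helpers: independent brute-force oracles and small scenario
# builders used across test files.

# Brute-force state distribution: enumerate every ordered combination of
# per-copy outcomes ("none" with prob 1-r, fluorophore a with prob
# r * p[a]) and collapse to observable states. Independent of the
# package's closed form.
brute_force_state_distribution <- function(rate, p, copies) {
  outcomes <- c("none", CONFETTI_FLUOROPHORES)
  probs <- c(1 - rate, rate * p)
  grids <- rep(list(seq_along(outcomes)), copies)
  combos <- expand.grid(grids)
  states <- c("unlabeled", confetti_states(2))
  acc <- stats::setNames(numeric(length(states)), states)
  for (i in seq_len(nrow(combos))) {
    idx <- as.integer(combos[i, ])
    pr <- prod(probs[idx])
    fl <- sort(unique(setdiff(outcomes[idx], "none")))
    st <- if (length(fl) == 0) "unlabeled" else
      paste(fl[order(match(fl, CONFETTI_FLUOROPHORES))], collapse = "+")
    acc[st] <- acc[st] + pr
  }
  acc
}

# A small, fast scenario for structural tests.
mini_config <- function(...) {
  defaults <- list(
    seed = 42, n_cells = 2000, n_follicles = 8,
    founders_per_follicle = 6, tzone_founders = 20,
    expansion_concentration = 100, homeostatic_target = 100,
    observation_days = c(2, 6), cells_sampled_per_follicle = 100,
    recombination = recombination_model(0.5)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(scenario_config, args)
}

uniform10 <- stats::setNames(rep(0.1, 10), confetti_states(2))
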