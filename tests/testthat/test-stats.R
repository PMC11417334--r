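# Clonality statistics, resampling nulls and the expansion classifier.
# Frozen expected values were computed by independent per-cell sampling
# oracles (sample() loops over individual cells) before the statistics
# were wired to them:
#   mean clonal dominance,   n = 200, uniform-10, 1e4 draws: 0.1358845
#     (MC se 1.2e-4)
#   mean TVD divergence,     n = 30,  uniform-10, 1e4 draws: 0.2122467
#     (MC se 5.5e-4)
#   null TVD 95th percentile, n = 100, uniform-10: ~0.17

cells_from_states <- function(states, follicle = "f001") {
  n <- length(states)
  data.frame(
    mouse_id = rep("m1", n), tissue = rep("spleen", n),
    compartment = rep("follicle", n), follicle_id = rep(follicle, n),
    day = rep(0L, n), origin_genotype = rep("confetti", n),
    foxp3 = rep(TRUE, n), state = states,
    clone_id = sprintf("c%03d", seq_along(states)),
    stringsAsFactors = FALSE
  )
}

test_that("labeling density is the labeled fraction of the gate", {
  cells <- cells_from_states(c(rep("RFP", 3), rep("unlabeled", 9)))
  r <- labeling_density(cells)
  expect_equal(r$value, 0.25)
  expect_identical(r$n_labeled, 3L)
  expect_identical(r$n_total, 12L)

  none <- cells_from_states(rep("unlabeled", 50))
  expect_equal(labeling_density(none)$value, 0)

  empty <- labeling_density(cells, gate = function(df) df$day > 0)
  expect_true(empty$below_threshold)
  expect_true(is.na(empty$value))

  # gate as predicate
  gated <- labeling_density(cells, gate = function(df) df$state != "unlabeled")
  expect_equal(gated$value, 1)
})

test_that("labeling density recovers the cassette closed form", {
  model <- recombination_model(0.6)
  mix <- marrow_mix(data.frame(genotype = "c", parts = 1,
                               confetti_labelable = TRUE,
                               dtx_ablatable = FALSE))
  cells <- apply_labeling(simulate_chimera(mix, 1e5, seed = 1), model,
                          seed = 2)
  r <- labeling_density(cells)
  expect_lt(abs(r$value - 0.84), 3 * sqrt(0.84 * 0.16 / 1e5))
})

test_that("clonal dominance is the top color-state share", {
  expect_equal(clonal_dominance(c(RFP = 7))$value, 1)
  expect_equal(clonal_dominance(c(RFP = 5, YFP = 5))$value, 0.5)
  # canonical tie-break: YFP precedes RFP in fluorophore order
  expect_identical(clonal_dominance(c(RFP = 5, YFP = 5))$dominant_state,
                   "YFP")
  expect_true(clonal_dominance(c(RFP = 2), min_cells = 5)$below_threshold)
  expect_true(clonal_dominance(cells_from_states(character(0)))$below_threshold)
  # dominance never below 1/10 over the 10-state panel
  counts <- stats::setNames(rep(3, 10), confetti_states(2))
  expect_equal(clonal_dominance(counts)$value, 0.1)
})

test_that("null dominance mean matches the frozen per-cell oracle", {
  null <- null_statistics("clonal_dominance", 200, uniform10,
                          reps = 1e4, seed = 314)
  # combined MC se of the two 1e4-draw means is ~1.7e-4
  expect_lt(abs(mean(null$samples) - 0.1358845), 6e-4)
})

test_that("divergence index is total variation distance by default", {
  counts <- stats::setNames(rep(5, 10), confetti_states(2))
  expect_equal(divergence_index(counts, uniform10)$value, 0)
  # all mass on one state vs uniform-10: 0.5*(0.9 + 9*0.1) = 0.9
  expect_equal(divergence_index(c(RFP = 12), uniform10)$value, 0.9)
  # Euclidean option
  expect_equal(divergence_index(c(RFP = 12), uniform10,
                                metric = "euclidean")$value,
               sqrt(0.9^2 + 9 * 0.01))
  expect_error(divergence_index(c(RFP = 1), rep(0.2, 10)), "sum to 1")
  expect_true(divergence_index(c(RFP = 1), uniform10,
                               min_cells = 5)$below_threshold)
})

test_that("TVD is symmetric and bounded on random frequency pairs", {
  set.seed(21)
  for (i in 1:20) {
    f <- as.numeric(stats::rmultinom(1, 50, uniform10)) / 50
    b <- rgamma(10, 1); b <- b / sum(b)
    tv_fb <- 0.5 * sum(abs(f - b))
    names(f) <- confetti_states(2)
    d <- divergence_index(f * 50, b)$value
    expect_equal(d, tv_fb)
    expect_gte(d, 0); expect_lte(d, 1)
    # symmetry of the metric in its arguments
    expect_equal(0.5 * sum(abs(b - f)), tv_fb)
  }
})

test_that("small-sample divergence bias matches the frozen oracle", {
  null <- null_statistics("divergence_index", 30, uniform10,
                          reps = 1e4, seed = 159)
  expect_lt(abs(mean(null$samples) - 0.2122467), 2.5e-3)
})

test_that("degenerate nulls at n = 1 are forced by the formulas", {
  nd <- null_statistics("clonal_dominance", 1, uniform10, reps = 200,
                        seed = 3)
  expect_true(all(nd$samples == 1))
  nv <- null_statistics("divergence_index", 1, uniform10, reps = 200,
                        seed = 4)
  expect_true(all(abs(nv$samples - 0.9) < 1e-12))
})

test_that("statistics ignore row order and clone relabeling", {
  set.seed(8)
  states <- sample(confetti_states(2), 60, replace = TRUE)
  a <- cells_from_states(states)
  b <- a[sample.int(nrow(a)), ]
  b$clone_id <- rev(b$clone_id)
  expect_equal(clonal_dominance(a)$value, clonal_dominance(b)$value)
  expect_equal(divergence_index(a, uniform10)$value,
               divergence_index(b, uniform10)$value)
  expect_equal(labeling_density(a)$value, labeling_density(b)$value)
})

test_that("bias profile decreases with n for both statistics", {
  grid <- c(1, 5, 20, 100, 500)
  bp_dom <- bias_profile("clonal_dominance", uniform10, grid,
                         reps = 2000, seed = 5)
  expect_equal(bp_dom$mean[1], 1)
  expect_true(all(diff(bp_dom$mean) <= 0))
  expect_gt(bp_dom$mean[bp_dom$n == 5], bp_dom$mean[bp_dom$n == 500])

  bp_div <- bias_profile("divergence_index", uniform10, grid,
                         reps = 2000, seed = 6)
  expect_true(all(diff(bp_div$mean) <= 0))
  # LLN: the null divergence vanishes at large n
  big <- bias_profile("divergence_index", uniform10, 1e4,
                      reps = 500, seed = 7)
  expect_lt(big$mean, 0.05)
})

test_that("resampling p-values are valid and classifier calls are sane", {
  # strong skew: 90 of 100 cells in one state vs uniform-10
  counts <- stats::setNames(c(90, 2, 1, 1, 2, 1, 1, 1, 0, 1),
                            confetti_states(2))
  cls <- classify_expansion(counts, uniform10, reps = 2000, seed = 9)
  expect_identical(cls$call, "oligoclonal")
  expect_lt(cls$p_value, 0.05)

  # below the min-cells threshold: no call
  cls3 <- classify_expansion(c(RFP = 3), uniform10, reps = 100, seed = 10,
                             min_cells = 5)
  expect_identical(cls3$call, "indeterminate")
  expect_true(is.na(cls3$p_value))

  # add-one p-value never 0, never above 1
  null <- null_statistics("divergence_index", 20, uniform10, reps = 99,
                          seed = 11)
  expect_gt(null_p_value(null, 2), 0)
  expect_lte(null_p_value(null, -1), 1)
})

test_that("a matched-n null is required: baseline must be a distribution", {
  expect_error(null_statistics("divergence_index", 10, rep(0.05, 10)),
               "sum to 1")
  expect_error(null_statistics("clonal_dominance", 0, uniform10))
})
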