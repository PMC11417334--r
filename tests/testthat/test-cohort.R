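# Chimera simulation: marrow mixing, labeling, founding, clone dynamics,
# ablation and observation sampling.

three_part_mix <- function() {
  marrow_mix(data.frame(
    genotype = c("driver", "dtr", "confetti"),
    parts = c(1, 1, 1),
    confetti_labelable = c(FALSE, FALSE, TRUE),
    dtx_ablatable = c(TRUE, TRUE, FALSE)
  ))
}

test_that("marrow mixing reproduces part ratios", {
  n <- 30000
  cells <- simulate_chimera(three_part_mix(), n, seed = 1)
  frac <- mean(cells$labelable)
  se <- sqrt((1 / 3) * (2 / 3) / n)
  expect_lt(abs(frac - 1 / 3), 3 * se)

  # 2:1 parts
  mix21 <- marrow_mix(data.frame(
    genotype = c("YFP", "GFP"), parts = c(2, 1),
    confetti_labelable = c(FALSE, FALSE), dtx_ablatable = c(FALSE, FALSE)
  ))
  cells21 <- simulate_chimera(mix21, n, seed = 2)
  n_yfp <- sum(cells21$origin_genotype == "YFP")
  p_hat <- n_yfp / n
  se_p <- sqrt(p_hat * (1 - p_hat) / n)
  expect_lt(abs(p_hat - 2 / 3), 3 * se_p)

  # single-donor trivia
  solo <- marrow_mix(data.frame(genotype = "only", parts = 1,
                                confetti_labelable = TRUE,
                                dtx_ablatable = FALSE))
  expect_true(all(simulate_chimera(solo, 100, seed = 3)$labelable))
  expect_error(marrow_mix(data.frame()), "at least one donor")
})

test_that("host fraction adds a recipient-derived compartment", {
  mix <- marrow_mix(data.frame(genotype = "d", parts = 1,
                               confetti_labelable = TRUE,
                               dtx_ablatable = FALSE),
                    host_fraction = 0.25)
  cells <- simulate_chimera(mix, 20000, seed = 4)
  frac_host <- mean(cells$origin_genotype == "host")
  expect_lt(abs(frac_host - 0.25), 3 * sqrt(0.25 * 0.75 / 20000))
  expect_false(any(cells$labelable[cells$origin_genotype == "host"]))
})

test_that("labeling hits only labelable cells at the closed-form rate", {
  mix <- three_part_mix()
  cells <- simulate_chimera(mix, 1e5, seed = 5)

  lab1 <- apply_labeling(cells, recombination_model(1), seed = 6)
  expect_true(all(lab1$state[lab1$labelable] != "unlabeled"))
  expect_true(all(lab1$state[!lab1$labelable] == "unlabeled"))

  model <- recombination_model(0.6)
  lab <- apply_labeling(cells, model, seed = 7)
  n_elig <- sum(cells$labelable)
  frac <- mean(lab$state[lab$labelable] != "unlabeled")
  expect_lt(abs(frac - 0.84), 3 * sqrt(0.84 * 0.16 / n_elig))
})

test_that("follicle founding draws without replacement from the pool", {
  cfg <- mini_config(founders_per_follicle = 1)
  cells <- apply_labeling(simulate_chimera(cfg$marrow, 2000, seed = 8),
                          cfg$recombination, seed = 9)
  clones <- found_follicles(cells, cfg, seed = 10)
  fol <- clones[clones$compartment == "follicle", ]
  expect_true(all(table(fol$follicle_id) == 1))  # monoclonal founding
  expect_true(all(clones$size == 1L))

  cfg0 <- mini_config(n_follicles = 0, tzone_founders = 0)
  expect_identical(nrow(found_follicles(cells, cfg0, seed = 1)), 0L)

  # expected labeled founders: pool labelable 1/3 (Fig5-style mix), r=0.6
  mix <- three_part_mix()
  big <- apply_labeling(simulate_chimera(mix, 3e4, seed = 11),
                        recombination_model(0.6), seed = 12)
  cfg20 <- scenario_config(seed = 1, n_follicles = 100,
                           founders_per_follicle = 20, tzone_founders = 0,
                           marrow = mix)
  cl <- found_follicles(big, cfg20, seed = 13)
  n_lab <- sum(cl$founder_state != "unlabeled")
  expect_n <- 2000 * (1 / 3) * 0.84
  expect_lt(abs(n_lab - expect_n),
            3 * sqrt(2000 * (1 / 3) * 0.84 * (1 - (1 / 3) * 0.84)))

  # under-seeded pool warns and founds with what exists
  tiny <- cells[1:10, ]
  expect_warning(found_follicles(tiny, mini_config(), seed = 14),
                 "pool")
})

test_that("exchangeable growth keeps the labeled fraction constant", {
  cfg <- mini_config(expansion_concentration = 1e6, go_dark_rate = 0,
                     n_follicles = 40, homeostatic_target = 200)
  cells <- apply_labeling(simulate_chimera(cfg$marrow, 5000, seed = 15),
                          cfg$recombination, seed = 16)
  clones <- found_follicles(cells, cfg, seed = 17)
  snaps <- evolve_clones(clones, cfg, until_day = 10, seed = 18)
  frac_by_day <- tapply(
    snaps$size * (snaps$founder_state != "unlabeled"),
    snaps$day, sum
  ) / tapply(snaps$size, snaps$day, sum)
  f0 <- mean(clones$founder_state != "unlabeled")
  expect_true(all(abs(frac_by_day[-1] - f0) < 0.05))
})

test_that("go-dark replacement follows geometric clone survival", {
  cfg <- mini_config(go_dark_rate = 0.05, expansion_concentration = 1e6,
                     n_follicles = 200, founders_per_follicle = 4,
                     tzone_founders = 0, homeostatic_target = 100)
  cells <- apply_labeling(simulate_chimera(cfg$marrow, 30000, seed = 19),
                          cfg$recombination, seed = 20)
  clones <- found_follicles(cells, cfg, seed = 21)
  n0 <- sum(clones$founder_state != "unlabeled")
  snaps <- evolve_clones(clones, cfg, until_day = 28, seed = 22)
  d28 <- snaps[snaps$day == 28, ]
  surv <- sum(d28$founder_state != "unlabeled")
  p <- 0.95^28
  expect_lt(abs(surv - n0 * p), 3 * sqrt(n0 * p * (1 - p)))
})

test_that("small concentration drives oligoclonal dominance over time", {
  cfg <- mini_config(expansion_concentration = 0.1, n_follicles = 50,
                     founders_per_follicle = 8, tzone_founders = 0,
                     homeostatic_target = 200)
  cells <- apply_labeling(simulate_chimera(cfg$marrow, 10000, seed = 23),
                          recombination_model(1), seed = 24)
  clones <- found_follicles(cells, cfg, seed = 25)
  snaps <- evolve_clones(clones, cfg, until_day = 30, seed = 26)
  dom_at <- function(d) {
    sub <- snaps[snaps$day == d, ]
    mean(vapply(split(sub, sub$follicle_id), function(s) {
      if (sum(s$size) == 0) return(NA_real_)
      max(tapply(s$size, s$founder_state, sum)) / sum(s$size)
    }, numeric(1)), na.rm = TRUE)
  }
  expect_gt(dom_at(30), dom_at(0))
})

test_that("proportional recovery rescales survivors exchangeably", {
  # 200 follicles, each: 1 labeled non-ablatable clone (size 100) and
  # 2 ablatable unlabeled clones (sizes 100 each); full ablation with
  # recovery to the original 300 should triple the labeled count.
  n_fol <- 200
  clones <- data.frame(
    clone_id = sprintf("c%04d", seq_len(3 * n_fol)),
    mouse_id = "m1", tissue = "spleen", compartment = "follicle",
    follicle_id = rep(sprintf("f%03d", seq_len(n_fol)), each = 3),
    founder_state = rep(c("RFP", "unlabeled", "unlabeled"), n_fol),
    origin_genotype = rep(c("confetti", "dtr", "dtr"), n_fol),
    labelable = rep(c(TRUE, FALSE, FALSE), n_fol),
    ablatable = rep(c(FALSE, TRUE, TRUE), n_fol),
    size = 100L, stringsAsFactors = FALSE
  )
  cfg <- mini_config(dtx = list(start_day = 0, every_k_days = 3,
                                ablation_efficiency = 1))
  post <- apply_ablation(clones, cfg, day = 0, seed = 27)
  lab_post <- tapply(post$size * (post$founder_state != "unlabeled"),
                     post$follicle_id, sum)
  expect_equal(mean(lab_post), 300, tolerance = 3 * 8 / sqrt(n_fol))
  expect_equal(sum(post$size), 300L * n_fol)  # compartment restored

  # efficiency 0 leaves clones untouched
  cfg0 <- mini_config(dtx = list(start_day = 0, every_k_days = 3,
                                 ablation_efficiency = 0))
  expect_identical(apply_ablation(clones, cfg0, day = 0, seed = 28)$size,
                   clones$size)
})

test_that("proportional recovery leaves labeled composition unbiased", {
  # two labeled clones per follicle; ablating unrelated cells and
  # recovering proportionally must not shift dominance on average
  n_fol <- 150
  set.seed(29)
  s1 <- rpois(n_fol, 40) + 1L
  s2 <- rpois(n_fol, 40) + 1L
  clones <- data.frame(
    clone_id = sprintf("c%04d", seq_len(3 * n_fol)),
    mouse_id = "m1", tissue = "spleen", compartment = "follicle",
    follicle_id = rep(sprintf("f%03d", seq_len(n_fol)), each = 3),
    founder_state = rep(c("RFP", "YFP", "unlabeled"), n_fol),
    origin_genotype = rep(c("confetti", "confetti", "dtr"), n_fol),
    labelable = rep(c(TRUE, TRUE, FALSE), n_fol),
    ablatable = rep(c(FALSE, FALSE, TRUE), n_fol),
    size = as.integer(rbind(s1, s2, 200L)), stringsAsFactors = FALSE
  )
  cfg <- mini_config(dtx = list(start_day = 0, every_k_days = 3,
                                ablation_efficiency = 0.9))
  post <- apply_ablation(clones, cfg, day = 0, seed = 30)
  rfp_share <- function(df) {
    vapply(split(df, df$follicle_id), function(s) {
      lab <- s[s$founder_state != "unlabeled", ]
      lab$size[lab$founder_state == "RFP"] / sum(lab$size)
    }, numeric(1))
  }
  diffs <- rfp_share(post) - rfp_share(clones)
  ci <- mean(diffs) + c(-1, 1) * 2 * sd(diffs) / sqrt(n_fol)
  expect_true(ci[1] <= 0 && 0 <= ci[2])
})

test_that("observation sampling censuses small follicles", {
  cfg <- mini_config(cells_sampled_per_follicle = 1000)
  cells <- apply_labeling(simulate_chimera(cfg$marrow, 2000, seed = 31),
                          cfg$recombination, seed = 32)
  clones <- found_follicles(cells, cfg, seed = 33)
  snaps <- evolve_clones(clones, cfg, until_day = 2, seed = 34)
  obs <- sample_observation(snaps, cfg, day = 2, seed = 35)
  d2 <- snaps[snaps$day == 2, ]
  expect_identical(nrow(obs), as.integer(sum(d2$size)))
  # each clone appears exactly at its size
  sz <- table(obs$clone_id)
  d2pos <- d2[d2$size > 0, ]
  expect_identical(as.integer(sz[d2pos$clone_id]), d2pos$size)
})

test_that("misclassification acts as the configured confusion matrix", {
  states <- confetti_states(2)
  mis <- matrix(0.1 / 9, 10, 10, dimnames = list(states, states))
  diag(mis) <- 0.9
  id <- diag(10); dimnames(id) <- list(states, states)

  truth <- c(0.5, 0.3, 0.2)
  tstates <- c("RFP", "YFP", "nGFP+mCFP")
  n <- 1e5
  sizes <- as.integer(round(n * truth))
  clones <- data.frame(
    clone_id = c("a", "b", "c"), mouse_id = "m1", tissue = "spleen",
    compartment = "follicle", follicle_id = "f001",
    founder_state = tstates, origin_genotype = "confetti",
    labelable = TRUE, ablatable = FALSE, size = sizes,
    stringsAsFactors = FALSE
  )
  cfg_id <- mini_config(cells_sampled_per_follicle = n,
                        misclassification = id)
  obs_id <- sample_observation(clones, cfg_id, day = 0, seed = 36)
  expect_identical(sort(unique(obs_id$state)), sort(tstates))

  cfg_mis <- mini_config(cells_sampled_per_follicle = n,
                         misclassification = mis)
  obs <- sample_observation(clones, cfg_mis, day = 0, seed = 37)
  f_true <- stats::setNames(numeric(10), states)
  f_true[tstates] <- truth
  expected <- as.numeric(f_true %*% mis)
  freq <- as.numeric(table(factor(obs$state, levels = states))) / n
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(freq - expected) <= 3 * se + 1e-12))
})

test_that("identical configuration gives byte-identical output", {
  cfg <- mini_config(seed = 99)
  b1 <- run_scenario(cfg)
  b2 <- run_scenario(cfg)
  expect_identical(b1$cells, b2$cells)
  expect_identical(b1$follicle_stats, b2$follicle_stats)
  expect_identical(report_json(report(b1)), report_json(report(b2)))
})

test_that("clone sizes stay non-negative integers throughout", {
  cfg <- mini_config(go_dark_rate = 0.1, expansion_concentration = 0.5)
  cells <- apply_labeling(simulate_chimera(cfg$marrow, 2000, seed = 38),
                          cfg$recombination, seed = 39)
  clones <- found_follicles(cells, cfg, seed = 40)
  snaps <- evolve_clones(clones, cfg, until_day = 12, seed = 41)
  expect_true(is.integer(snaps$size))
  expect_true(all(snaps$size >= 0))
})
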