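# Seeded simulator of mixed bone-marrow chimera experiments on the
# FoxP3+ Treg/Tfr compartment: marrow mixing, tamoxifen-pulse Confetti
# labeling, clonal founding of follicles and T-cell zones, Dirichlet-
# multinomial clone growth, "go dark" clone replacement, diphtheria-toxin
# ablation with homeostatic recovery, and per-follicle sampling.

CELL_COLUMNS <- c("mouse_id", "tissue", "compartment", "follicle_id",
                  "day", "origin_genotype", "foxp3", "state", "clone_id")

#' Define a mixed bone-marrow chimera
#'
#' Donor marrows are mixed in stated part ratios (e.g. 1:1:1) into an
#' irradiated recipient; a radio-resistant host-derived Treg fraction can
#' be retained. Per-donor flags mark whether cells of that origin carry
#' the Confetti cassette (labelable) and/or the diphtheria-toxin receptor
#' (ablatable).
#'
#' @param donors data.frame with columns `genotype` (unique ids), `parts`
#'   (positive mixing ratio) and logical flags `confetti_labelable`,
#'   `dtx_ablatable` (missing flags default to `FALSE`).
#' @param host_fraction fraction of the compartment that is
#'   recipient-derived, in \[0, 1\]; the host is neither labelable nor
#'   ablatable unless flagged.
#' @param host_genotype,host_labelable,host_ablatable host annotation.
#' @return Object of class `marrow_mix` with per-genotype fractions.
#' @export
marrow_mix <- function(donors, host_fraction = 0,
                       host_genotype = "host",
                       host_labelable = FALSE, host_ablatable = FALSE) {
  donors <- as.data.frame(donors)
  if (nrow(donors) == 0L) {
    stop("`donors` must contain at least one donor", call. = FALSE)
  }
  if (!all(c("genotype", "parts") %in% names(donors))) {
    stop("`donors` needs columns `genotype` and `parts`", call. = FALSE)
  }
  if (any(donors$parts <= 0) || any(is.na(donors$parts))) {
    stop("donor `parts` must be positive", call. = FALSE)
  }
  if (anyDuplicated(donors$genotype)) {
    stop("donor genotypes must be unique", call. = FALSE)
  }
  if (!is_prob(host_fraction)) {
    stop("`host_fraction` must be in [0, 1]", call. = FALSE)
  }
  for (fl in c("confetti_labelable", "dtx_ablatable")) {
    if (is.null(donors[[fl]])) donors[[fl]] <- FALSE
    donors[[fl]] <- as.logical(donors[[fl]])
  }
  tab <- data.frame(
    genotype = as.character(donors$genotype),
    fraction = donors$parts / sum(donors$parts) * (1 - host_fraction),
    confetti_labelable = donors$confetti_labelable,
    dtx_ablatable = donors$dtx_ablatable,
    stringsAsFactors = FALSE
  )
  if (host_fraction > 0) {
    tab <- rbind(tab, data.frame(
      genotype = host_genotype, fraction = host_fraction,
      confetti_labelable = host_labelable, dtx_ablatable = host_ablatable,
      stringsAsFactors = FALSE
    ))
  }
  structure(list(table = tab), class = "marrow_mix")
}

#' @export
print.marrow_mix <- function(x, ...) {
  cat("Mixed bone-marrow chimera\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Simulate the pre-labeling Treg compartment of a chimera
#'
#' Draws each cell's origin genotype multinomially from the donor/host
#' fractions. The simulator models the FoxP3+ compartment only, so every
#' record is FoxP3+.
#'
#' @param mix a [marrow_mix()].
#' @param n_cells number of Treg cells to generate (>= 1).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param mouse_id,tissue annotation applied to all records.
#' @return data.frame of cell records (state `"unlabeled"`, compartment
#'   unassigned) with helper columns `labelable` and `ablatable`.
#' @export
simulate_chimera <- function(mix, n_cells, seed = NULL,
                             mouse_id = "m1", tissue = "spleen") {
  stopifnot(inherits(mix, "marrow_mix"))
  if (!is_count(n_cells) || n_cells < 1) {
    stop("`n_cells` must be a positive count", call. = FALSE)
  }
  tab <- mix$table
  with_seed(seed, {
    origin_idx <- sample.int(nrow(tab), n_cells, replace = TRUE,
                             prob = tab$fraction)
    data.frame(
      mouse_id = mouse_id,
      tissue = tissue,
      compartment = NA_character_,
      follicle_id = NA_character_,
      day = 0L,
      origin_genotype = tab$genotype[origin_idx],
      foxp3 = TRUE,
      state = "unlabeled",
      clone_id = NA_character_,
      labelable = tab$confetti_labelable[origin_idx],
      ablatable = tab$dtx_ablatable[origin_idx],
      stringsAsFactors = FALSE
    )
  })
}

#' Apply tamoxifen-pulse Confetti labeling
#'
#' Each labelable FoxP3+ cell receives a color state drawn from the
#' cassette [state_distribution()]; all other cells stay unlabeled. The
#' pulse is a single Bernoulli event per cassette copy (single-gavage
#' protocol), so labeling happens once.
#'
#' @param cells population from [simulate_chimera()].
#' @param model a [recombination_model()].
#' @param seed integer seed or `NULL`.
#' @return `cells` with the `state` column filled in.
#' @export
apply_labeling <- function(cells, model, seed = NULL) {
  stopifnot(is.data.frame(cells), inherits(model, "recombination_model"))
  d <- state_distribution(model)
  eligible <- cells$labelable & cells$foxp3
  with_seed(seed, {
    n <- sum(eligible)
    if (n > 0) {
      cells$state[eligible] <- sample(names(d), n, replace = TRUE, prob = d)
    }
    cells
  })
}

#' Found follicular and T-zone clones from a labeled population
#'
#' Samples clone founders without replacement from the shared FoxP3+ pool
#' of each mouse: `founders_per_follicle` per follicle plus
#' `tzone_founders` for one T-cell-zone compartment per mouse. Founder
#' color and origin are inherited clonally; initial clone size is 1.
#'
#' @param cells labeled population from [apply_labeling()].
#' @param config a [scenario_config()] (uses `n_follicles`,
#'   `founders_per_follicle`, `tzone_founders`).
#' @param seed integer seed or `NULL`.
#' @return data.frame of clones: `clone_id`, `mouse_id`, `tissue`,
#'   `compartment`, `follicle_id`, `founder_state`, `origin_genotype`,
#'   `labelable`, `ablatable`, `size`.
#' @export
found_follicles <- function(cells, config, seed = NULL) {
  stopifnot(is.data.frame(cells))
  n_fol <- config$n_follicles
  n_found <- config$founders_per_follicle
  n_tz <- config$tzone_founders
  need <- n_fol * n_found + n_tz
  if (n_fol == 0 && n_tz == 0) {
    return(empty_clones())
  }
  with_seed(seed, {
    pool <- which(cells$foxp3)
    if (length(pool) < need) {
      warning("founder pool (", length(pool), ") smaller than requested (",
              need, "); founding with available pool", call. = FALSE)
      need <- length(pool)
    }
    picked <- pool[sample.int(length(pool), need)]
    fol_ids <- c(
      if (n_fol > 0) rep(sprintf("f%03d", seq_len(n_fol)),
                         each = n_found)[seq_len(min(n_fol * n_found, need))],
      if (n_tz > 0) rep("tz", max(0L, need - n_fol * n_found))
    )
    picked <- picked[seq_along(fol_ids)]
    data.frame(
      clone_id = sprintf("c%05d", seq_along(picked)),
      mouse_id = cells$mouse_id[picked],
      tissue = cells$tissue[picked],
      compartment = ifelse(fol_ids == "tz", "t_zone", "follicle"),
      follicle_id = fol_ids,
      founder_state = cells$state[picked],
      origin_genotype = cells$origin_genotype[picked],
      labelable = cells$labelable[picked],
      ablatable = cells$ablatable[picked],
      size = 1L,
      stringsAsFactors = FALSE
    )
  })
}

empty_clones <- function() {
  data.frame(
    clone_id = character(0), mouse_id = character(0), tissue = character(0),
    compartment = character(0), follicle_id = character(0),
    founder_state = character(0), origin_genotype = character(0),
    labelable = logical(0), ablatable = logical(0), size = integer(0),
    stringsAsFactors = FALSE
  )
}

#' Evolve clone sizes day by day
#'
#' Per follicle and day, new clone proportions are drawn from a Dirichlet
#' distribution centered on the previous proportions with concentration
#' `expansion_concentration * n_clones * prev_props` (symmetric
#' `Dirichlet(alpha)` at uniform proportions), then realized by a
#' multinomial draw at the compartment size `homeostatic_target`
#' (follicular compartments are treated as homeostatically sized from the
#' first day; founding abstracts the seeding). Large concentrations give
#' exchangeable, proportion-preserving (polyclonal) growth; small ones
#' give oligoclonal skew. Independently, each labeled clone is replaced
#' by an unlabeled clone of equal size with per-day probability
#' `go_dark_rate`.
#'
#' @param clones founding clones from [found_follicles()].
#' @param config a [scenario_config()].
#' @param until_day last day to simulate (>= 0).
#' @param seed integer seed or `NULL`.
#' @return data.frame of per-day clone snapshots (`day` column prepended
#'   to the clone columns), days 0..`until_day`.
#' @export
evolve_clones <- function(clones, config, until_day, seed = NULL) {
  stopifnot(is.data.frame(clones), is_count(until_day))
  if (nrow(clones) == 0L) {
    out <- cbind(day = integer(0), empty_clones())
    return(out)
  }
  alpha <- config$expansion_concentration
  dark <- config$go_dark_rate
  target <- config$homeostatic_target
  with_seed(seed, {
    cur <- clones
    snaps <- vector("list", until_day + 1L)
    snaps[[1L]] <- cbind(day = 0L, cur)
    if (until_day >= 1) {
      groups <- split(seq_len(nrow(cur)),
                      paste(cur$mouse_id, cur$follicle_id, sep = "\r"))
      for (d in seq_len(until_day)) {
        for (g in groups) {
          sizes <- cur$size[g]
          tot <- sum(sizes)
          if (tot == 0) next
          new_tot <- target
          props <- sizes / tot
          w <- rdirichlet1(alpha * length(g) * props)
          cur$size[g] <- as.integer(stats::rmultinom(1L, new_tot, w))
        }
        # whole-clone "go dark" replacement
        if (dark > 0) {
          labeled <- cur$founder_state != "unlabeled"
          goes <- labeled & stats::runif(nrow(cur)) < dark
          if (any(goes)) {
            cur$founder_state[goes] <- "unlabeled"
            cur$clone_id[goes] <- paste0(cur$clone_id[goes], ".d", d)
          }
        }
        snaps[[d + 1L]] <- cbind(day = d, cur)
      }
    }
    out <- do.call(rbind, snaps)
    rownames(out) <- NULL
    out
  })
}

#' Number of DTX doses administered by a given day
#'
#' @param dtx list with `start_day`, `every_k_days`, `ablation_efficiency`.
#' @param day observation day.
#' @return Integer count of administrations at or before `day`.
#' @export
dtx_doses_by <- function(dtx, day) {
  if (is.null(dtx) || day < dtx$start_day) {
    return(0L)
  }
  as.integer(floor((day - dtx$start_day) / dtx$every_k_days) + 1)
}

#' Ablate DTR-marrow-derived cells and recover homeostatically
#'
#' Each cell of DTX-ablatable origin survives each administration
#' independently with probability `1 - ablation_efficiency`; clone sizes
#' are thinned binomially over `n_doses` doses. Surviving clones in each
#' follicle then expand back to the pre-ablation compartment size:
#' proportionally to surviving size (`recovery_mode = "proportional"`,
#' exchangeable), or Dirichlet-reweighted with
#' `expansion_concentration` (`"oligoclonal"`).
#'
#' @param clones one day's clone snapshot.
#' @param config a [scenario_config()] with a `dtx` schedule.
#' @param day observation day, used to count administered doses.
#' @param seed integer seed or `NULL`.
#' @return Clones after ablation and recovery.
#' @export
apply_ablation <- function(clones, config, day, seed = NULL) {
  stopifnot(is.data.frame(clones))
  dtx <- config$dtx
  if (is.null(dtx)) {
    stop("scenario has no `dtx` schedule configured", call. = FALSE)
  }
  n_doses <- dtx_doses_by(dtx, day)
  if (n_doses == 0L || nrow(clones) == 0L) {
    return(clones)
  }
  surv_p <- (1 - dtx$ablation_efficiency)^n_doses
  alpha <- config$expansion_concentration
  with_seed(seed, {
    cur <- clones
    hit <- cur$ablatable
    cur$size[hit] <- stats::rbinom(sum(hit), cur$size[hit], surv_p)
    groups <- split(seq_len(nrow(cur)),
                    paste(cur$mouse_id, cur$follicle_id, sep = "\r"))
    for (g in groups) {
      pre_tot <- sum(clones$size[g])
      sizes <- cur$size[g]
      tot <- sum(sizes)
      if (tot == 0) {
        if (pre_tot > 0) {
          warning("all clones ablated in ", cur$follicle_id[g[1L]],
                  "; compartment left empty", call. = FALSE)
        }
        next
      }
      if (tot >= pre_tot) next
      if (identical(config$recovery_mode, "oligoclonal")) {
        w <- rdirichlet1(alpha * length(g) * sizes / tot)
      } else {
        w <- sizes / tot
      }
      cur$size[g] <- as.integer(stats::rmultinom(1L, pre_tot, w))
    }
    cur
  })
}

#' Sample observed cells per follicle
#'
#' Per follicle, draws `min(cells_sampled_per_follicle, follicle size)`
#' cells without replacement (multivariate hypergeometric over clone
#' sizes), so small follicles are censused. An optional row-stochastic
#' misclassification matrix over the 10 labeled states is applied to
#' labeled cells to emulate spectral channel confusion.
#'
#' @param clones per-day snapshots from [evolve_clones()], or one day's
#'   clone table with a `day` column.
#' @param config a [scenario_config()].
#' @param day day to observe.
#' @param seed integer seed or `NULL`.
#' @return data.frame of cell records sorted by mouse, tissue, follicle,
#'   clone.
#' @export
sample_observation <- function(clones, config, day, seed = NULL) {
  stopifnot(is.data.frame(clones))
  if ("day" %in% names(clones)) {
    clones <- clones[clones$day == day, , drop = FALSE]
  }
  k <- config$cells_sampled_per_follicle
  mis <- config$misclassification
  with_seed(seed, {
    rows <- list()
    groups <- split(seq_len(nrow(clones)),
                    paste(clones$mouse_id, clones$follicle_id, sep = "\r"))
    for (g in groups) {
      sizes <- clones$size[g]
      tot <- sum(sizes)
      if (tot == 0) next
      take <- min(k, tot)
      cell_clone <- rep.int(g, sizes)
      picked <- if (take == tot) cell_clone else sample(cell_clone, take)
      rows[[length(rows) + 1L]] <- data.frame(
        mouse_id = clones$mouse_id[picked],
        tissue = clones$tissue[picked],
        compartment = clones$compartment[picked],
        follicle_id = clones$follicle_id[picked],
        day = as.integer(day),
        origin_genotype = clones$origin_genotype[picked],
        foxp3 = TRUE,
        state = clones$founder_state[picked],
        clone_id = clones$clone_id[picked],
        stringsAsFactors = FALSE
      )
    }
    if (length(rows) == 0L) {
      out <- data.frame(mouse_id = character(0), tissue = character(0),
                        compartment = character(0), follicle_id = character(0),
                        day = integer(0), origin_genotype = character(0),
                        foxp3 = logical(0), state = character(0),
                        clone_id = character(0), stringsAsFactors = FALSE)
      return(out)
    }
    out <- do.call(rbind, rows)
    if (!is.null(mis)) {
      states <- confetti_states(2)
      lab <- which(out$state != "unlabeled")
      for (i in lab) {
        out$state[i] <- sample(states, 1L, prob = mis[out$state[i], ])
      }
    }
    out <- out[order(out$mouse_id, out$tissue, out$follicle_id,
                     out$clone_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}
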