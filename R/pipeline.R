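# Scenario runner and group-level inference: executes a full in-silico
# chimera experiment from a scenario_config, summarizes per-follicle
# clonality statistics per day, compares treated/untreated readouts by
# rank-sum, and estimates power to detect oligoclonal expansion.

#' Run a full in-silico chimera scenario
#'
#' Generates the chimeric Treg compartment, applies the tamoxifen-pulse
#' labeling, founds and evolves clones, applies the DTX ablation schedule
#' where configured (cumulative doses by each observation day, followed by
#' homeostatic recovery), samples each follicle, and computes per-follicle
#' and per-day clonality statistics. Deterministic given the config seed.
#'
#' The divergence reference defaults to the pooled T-cell-zone labeled
#' color frequencies when at least 50 such cells were observed (the
#' non-clonally-selected compartment), else the theoretical labeled
#' baseline of the cassette model.
#'
#' @param config a [scenario_config()].
#' @return Object of class `scenario_bundle`: `config`, `cells` (all
#'   sampled records), `follicle_stats` (per day x follicle), and
#'   `day_summary`, `comparisons`, `baseline`, `baseline_source`.
#' @export
run_scenario <- function(config) {
  validate_config(config)
  with_seed(config$seed, {
    cells0 <- simulate_chimera(config$marrow, config$n_cells)
    cells <- apply_labeling(cells0, config$recombination)
    clones <- found_follicles(cells, config)
    days <- config$observation_days
    max_day <- if (length(days)) max(days) else 0L
    snaps <- evolve_clones(clones, config, until_day = max_day)
    obs <- lapply(days, function(day) {
      cl <- snaps[snaps$day == day, , drop = FALSE]
      if (!is.null(config$dtx) && dtx_doses_by(config$dtx, day) > 0) {
        cl <- apply_ablation(cl, config, day)
      }
      sample_observation(cl, config, day)
    })
    all_cells <- if (length(obs)) do.call(rbind, obs) else
      sample_observation(clones[0, ], config, 0)
    bundle_from_cells(all_cells, config)
  })
}

# Assemble statistics from a sampled cell table (shared by run_scenario
# and re-analysis of cell tables read from disk).
bundle_from_cells <- function(all_cells, config) {
  tz <- all_cells[all_cells$compartment == "t_zone" &
                    all_cells$state != "unlabeled", , drop = FALSE]
  if (nrow(tz) >= 50) {
    baseline <- baseline_from_counts(table(tz$state))
    baseline_source <- "empirical_t_zone"
  } else {
    baseline <- labeled_baseline(config$recombination)
    baseline_source <- "theoretical"
  }

  fol_stats <- follicle_statistics(all_cells, baseline, config$min_cells)
  day_summary <- summarize_days(all_cells, fol_stats)
  comparisons <- NULL
  if (!is.null(config$dtx)) {
    comparisons <- ablation_comparisons(fol_stats, config)
  }
  structure(
    list(config = config, cells = all_cells, follicle_stats = fol_stats,
         day_summary = day_summary, comparisons = comparisons,
         baseline = baseline, baseline_source = baseline_source),
    class = "scenario_bundle"
  )
}

follicle_statistics <- function(cells, baseline, min_cells) {
  if (nrow(cells) == 0L) {
    return(data.frame(day = integer(0), mouse_id = character(0),
                      compartment = character(0), follicle_id = character(0),
                      n_sampled = integer(0), n_labeled = integer(0),
                      dominance = numeric(0), divergence = numeric(0),
                      stringsAsFactors = FALSE))
  }
  key <- paste(cells$day, cells$mouse_id, cells$follicle_id, sep = "\r")
  rows <- lapply(split(seq_len(nrow(cells)), key), function(i) {
    sub <- cells[i, , drop = FALSE]
    counts <- state_counts(sub)
    dom <- clonal_dominance(counts, min_cells = min_cells)
    div <- divergence_index(counts, baseline, min_cells = min_cells)
    data.frame(
      day = sub$day[1L], mouse_id = sub$mouse_id[1L],
      compartment = sub$compartment[1L], follicle_id = sub$follicle_id[1L],
      n_sampled = nrow(sub), n_labeled = sum(counts),
      dominance = dom$value, divergence = div$value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$day, out$mouse_id, out$follicle_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

summarize_days <- function(cells, fol_stats) {
  days <- sort(unique(cells$day))
  if (length(days) == 0L) {
    return(data.frame(day = integer(0), n_cells = integer(0),
                      labeling_density = numeric(0),
                      n_follicles = integer(0),
                      n_labeled_follicles = integer(0),
                      mean_labeled_per_labeled_follicle = numeric(0),
                      mean_dominance = numeric(0),
                      mean_divergence = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(days, function(d) {
    sub <- cells[cells$day == d, , drop = FALSE]
    fs <- fol_stats[fol_stats$day == d &
                      fol_stats$compartment == "follicle", , drop = FALSE]
    lit <- fs[fs$n_labeled > 0, , drop = FALSE]
    data.frame(
      day = d,
      n_cells = nrow(sub),
      labeling_density = mean(sub$state != "unlabeled"),
      n_follicles = nrow(fs),
      n_labeled_follicles = nrow(lit),
      mean_labeled_per_labeled_follicle =
        if (nrow(lit)) mean(lit$n_labeled) else NA_real_,
      mean_dominance = mean(fs$dominance, na.rm = TRUE),
      mean_divergence = mean(fs$divergence, na.rm = TRUE),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

ablation_comparisons <- function(fol_stats, config) {
  doses <- vapply(fol_stats$day, function(d) dtx_doses_by(config$dtx, d),
                  integer(1))
  fs <- fol_stats[fol_stats$compartment == "follicle", , drop = FALSE]
  doses <- doses[fol_stats$compartment == "follicle"]
  pre <- fs[doses == 0L, , drop = FALSE]
  post <- fs[doses > 0L, , drop = FALSE]
  if (nrow(pre) == 0L || nrow(post) == 0L) {
    return(NULL)
  }
  cmp <- function(col) {
    a <- pre[[col]][!is.na(pre[[col]])]
    b <- post[[col]][!is.na(post[[col]])]
    if (!length(a) || !length(b)) return(NULL)
    compare_groups(a, b, labels = c("pre_ablation", "post_ablation"))
  }
  list(n_labeled = cmp("n_labeled"),
       dominance = cmp("dominance"),
       divergence = cmp("divergence"))
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat("Scenario bundle:", x$config$name, "\n")
  cat("  cells sampled:", nrow(x$cells),
      "  baseline:", x$baseline_source, "\n")
  print(x$day_summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Wilcoxon-Mann-Whitney rank-sum comparison of two groups
#'
#' Exact two-sided p by enumeration when both groups have at most 12
#' tie-free observations; otherwise normal approximation with continuity
#' and tie correction. The U statistic counts pairs in which a group-one
#' value exceeds a group-two value (midranks for ties).
#'
#' @param a,b non-empty numeric vectors.
#' @param labels group labels for reporting.
#' @return List of class `group_comparison`: `group_labels`,
#'   `n_per_group`, `u_statistic`, `p_value`, `method`.
#' @export
compare_groups <- function(a, b, labels = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L || anyNA(a) || anyNA(b)) {
    stop("both groups must be non-empty and free of NA", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && length(a) <= 12L && length(b) <= 12L
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  p <- res$p.value
  if (is.nan(p)) p <- 1  # fully tied groups carry no evidence
  structure(
    list(group_labels = labels,
         n_per_group = c(length(a), length(b)),
         u_statistic = unname(res$statistic),
         p_value = min(1, p),
         method = if (use_exact) "exact" else "normal_approximation"),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Rank-sum: ", x$group_labels[1L], " (n=", x$n_per_group[1L], ") vs ",
      x$group_labels[2L], " (n=", x$n_per_group[2L], "): U=",
      x$u_statistic, ", p=", format(x$p_value, digits = 4),
      " [", x$method, "]\n", sep = "")
  invisible(x)
}

# One follicle's labeled color counts under an oligoclonal effect of
# strength `concentration`: the color distribution is a Dirichlet
# perturbation of the baseline (concentration * n_states * baseline), so
# the polyclonal limit (concentration -> Inf) reduces exactly to the
# multinomial null and power equals the test level there.
simulate_follicle_counts <- function(concentration, n_cells, baseline) {
  p <- rdirichlet1(concentration * length(baseline) * baseline)
  stats::setNames(as.numeric(stats::rmultinom(1L, n_cells, p)),
                  names(baseline))
}

#' Power to detect oligoclonal expansion
#'
#' For each (expansion concentration, cells per follicle) grid cell,
#' simulates labeled follicles whose color distribution is a Dirichlet
#' perturbation of the baseline with that concentration, and reports the
#' fraction called oligoclonal by [classify_expansion()]. The polyclonal
#' limit (large concentration) coincides with the multinomial null, so
#' power equals the test level there; power decreases with concentration
#' and increases with cells per follicle.
#'
#' @param base_config a [scenario_config()] providing the theoretical
#'   baseline.
#' @param effect_grid expansion-concentration values to test.
#' @param n_grid labeled-cells-per-follicle values to test.
#' @param reps simulated follicles per cell, default 200.
#' @param alpha test level, default 0.05.
#' @param seed integer seed or `NULL`.
#' @param null_reps resamples for each null, default 1000.
#' @return data.frame with columns `effect`, `n_cells`, `n_follicles`
#'   (= `reps`), `power`, `alpha`.
#' @export
power_analysis <- function(base_config, effect_grid, n_grid, reps = 200,
                           alpha = 0.05, seed = NULL, null_reps = 1000) {
  if (length(effect_grid) == 0L || length(n_grid) == 0L) {
    stop("`effect_grid` and `n_grid` must be non-empty", call. = FALSE)
  }
  baseline <- labeled_baseline(base_config$recombination)
  with_seed(seed, {
    rows <- list()
    for (eff in effect_grid) {
      for (n_cells in n_grid) {
        # shared null across the reps of one cell: matched n throughout
        null <- null_statistics("divergence_index", n_cells, baseline,
                                reps = null_reps)
        hits <- vapply(seq_len(reps), function(i) {
          counts <- simulate_follicle_counts(eff, n_cells, baseline)
          obs <- divergence_index(counts, baseline)$value
          null_p_value(null, obs) < alpha
        }, logical(1))
        rows[[length(rows) + 1L]] <- data.frame(
          effect = eff, n_cells = n_cells, n_follicles = reps,
          power = mean(hits), alpha = alpha
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Machine- and human-readable scenario report
#'
#' Per-panel tables (follicular labeled counts, dominance, divergence,
#' labeling density) with group means and SDs, the group comparisons, and
#' stable field ordering so the JSON form is byte-reproducible.
#'
#' @param bundle a [run_scenario()] bundle.
#' @return Object of class `scenario_report`; serialize with
#'   [report_json()].
#' @export
report <- function(bundle) {
  stopifnot(inherits(bundle, "scenario_bundle"))
  ds <- bundle$day_summary
  panel <- function(col) {
    fs <- bundle$follicle_stats
    fs <- fs[fs$compartment == "follicle", , drop = FALSE]
    lapply(split(fs, fs$day), function(sub) {
      v <- sub[[col]][!is.na(sub[[col]])]
      list(day = sub$day[1L], n = length(v),
           mean = if (length(v)) mean(v) else NA_real_,
           sd = if (length(v) > 1L) stats::sd(v) else NA_real_)
    })
  }
  cmp <- lapply(bundle$comparisons, function(x) {
    if (is.null(x)) return(NULL)
    list(groups = x$group_labels, n = x$n_per_group,
         u = x$u_statistic, p_value = x$p_value, method = x$method)
  })
  structure(
    list(
      scenario = bundle$config$name,
      seed = bundle$config$seed,
      baseline_source = bundle$baseline_source,
      n_cells_sampled = nrow(bundle$cells),
      panels = list(
        labeled_count = panel("n_labeled"),
        dominance = panel("dominance"),
        divergence = panel("divergence"),
        labeling_density = lapply(seq_len(nrow(ds)), function(i) {
          list(day = ds$day[i], n = ds$n_cells[i],
               mean = ds$labeling_density[i], sd = NA_real_)
        })
      ),
      comparisons = cmp,
      note = "follicles are the statistical unit; mouse-level clustering not modeled"
    ),
    class = "scenario_report"
  )
}

#' Serialize a scenario report to JSON
#'
#' Fixed key order, unboxed scalars, 10 significant digits; the same
#' report always yields byte-identical JSON.
#'
#' @param rep a [report()] object.
#' @return JSON string.
#' @export
report_json <- function(rep) {
  stopifnot(inherits(rep, "scenario_report"))
  as.character(jsonlite::toJSON(unclass(rep), auto_unbox = TRUE,
                                digits = 10, null = "null", na = "null"))
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("Report for scenario:", x$scenario, "(seed", x$seed, ")\n")
  cat("  baseline:", x$baseline_source,
      " cells sampled:", x$n_cells_sampled, "\n")
  for (nm in names(x$panels)) {
    cat("  ", nm, ":\n", sep = "")
    for (p in x$panels[[nm]]) {
      cat(sprintf("    day %2d: mean %.3f (sd %s, n=%d)\n", p$day,
                  p$mean, ifelse(is.na(p$sd), "-", sprintf("%.3f", p$sd)),
                  p$n))
    }
  }
  if (length(x$comparisons)) {
    cat("  comparisons (rank-sum):\n")
    for (nm in names(x$comparisons)) {
      p <- x$comparisons[[nm]]
      if (is.null(p)) next
      cat(sprintf("    %s: U=%.1f p=%.4g [%s]\n", nm, p$u, p$p_value,
                  p$method))
    }
  }
  invisible(x)
}
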