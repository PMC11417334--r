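# Packaged example scenarios. Each mirrors one of the chimera
# experiments the simulator emulates; all are sized to run in seconds.

#' Packaged example scenarios
#'
#' Four small, fully specified scenario configurations:
#'
#' * `fig3_godark` — pulse-chase labeling with clone waning: 1 part
#'   non-labelable autoreactive driver marrow + 2 parts Confetti marrow,
#'   exchangeable growth, labeled clones replaced by unlabeled ones at
#'   6%/day; observed at days 4, 18 and 32. Pooled labeling density
#'   declines while still-labeled follicles keep their counts.
#' * `fig4_baseline` — the same chimera without waning: stable polyclonal
#'   follicular populations across days 4-32.
#' * `fig5_polyclonal` — three-part marrow (1 driver-DTR : 1 DTR :
#'   1 Confetti, so one-third of Tregs are labelable and two-thirds
#'   DTX-ablatable), DTX every 3 days from day 4, proportional
#'   homeostatic recovery; observed pre (day 3) and post (day 15).
#' * `fig5_oligoclonal` — as `fig5_polyclonal` but with a small
#'   expansion concentration and Dirichlet-reweighted recovery, a
#'   constructed oligoclonal effect the divergence test must detect.
#'
#' @param seed base seed recorded in every config.
#' @return Named list of [scenario_config()] objects.
#' @export
example_scenarios <- function(seed = 20240904) {
  fig3_marrow <- marrow_mix(data.frame(
    genotype = c("564Igi", "FoxP3-Confetti"),
    parts = c(1, 2),
    confetti_labelable = c(FALSE, TRUE),
    dtx_ablatable = c(FALSE, FALSE)
  ))
  fig5_marrow <- marrow_mix(data.frame(
    genotype = c("564Igi-FoxP3-DTR", "FoxP3-DTR", "FoxP3-Confetti"),
    parts = c(1, 1, 1),
    confetti_labelable = c(FALSE, FALSE, TRUE),
    dtx_ablatable = c(TRUE, TRUE, FALSE)
  ))
  list(
    fig3_godark = scenario_config(
      name = "fig3_godark", seed = seed,
      n_cells = 20000, marrow = fig3_marrow,
      recombination = recombination_model(0.2),
      n_follicles = 40, founders_per_follicle = 4, tzone_founders = 60,
      expansion_concentration = 1e6, go_dark_rate = 0.06,
      homeostatic_target = 300, observation_days = c(4, 18, 32),
      cells_sampled_per_follicle = 300, min_cells = 5
    ),
    fig4_baseline = scenario_config(
      name = "fig4_baseline", seed = seed + 1,
      n_cells = 20000, marrow = fig3_marrow,
      recombination = recombination_model(0.5),
      n_follicles = 30, founders_per_follicle = 12, tzone_founders = 60,
      expansion_concentration = 1e4, go_dark_rate = 0,
      homeostatic_target = 2000, observation_days = c(4, 18, 32),
      cells_sampled_per_follicle = 300, min_cells = 5
    ),
    fig5_polyclonal = scenario_config(
      name = "fig5_polyclonal", seed = seed + 2,
      n_cells = 30000, marrow = fig5_marrow,
      recombination = recombination_model(0.6),
      n_follicles = 40, founders_per_follicle = 12, tzone_founders = 60,
      expansion_concentration = 1e4, go_dark_rate = 0,
      dtx = list(start_day = 4, every_k_days = 3,
                 ablation_efficiency = 0.5),
      recovery_mode = "proportional", homeostatic_target = 2000,
      observation_days = c(3, 15), cells_sampled_per_follicle = 300,
      min_cells = 5
    ),
    fig5_oligoclonal = scenario_config(
      name = "fig5_oligoclonal", seed = seed + 3,
      n_cells = 30000, marrow = fig5_marrow,
      recombination = recombination_model(0.6),
      n_follicles = 40, founders_per_follicle = 12, tzone_founders = 60,
      expansion_concentration = 0.3, go_dark_rate = 0,
      dtx = list(start_day = 4, every_k_days = 3,
                 ablation_efficiency = 0.5),
      recovery_mode = "oligoclonal", homeostatic_target = 2000,
      observation_days = c(3, 15), cells_sampled_per_follicle = 300,
      min_cells = 5
    )
  )
}

config_to_list <- function(cfg) {
  tab <- cfg$marrow$table
  host <- tab$genotype == "host"
  donors <- lapply(which(!host), function(i) {
    list(genotype = tab$genotype[i],
         parts = tab$fraction[i] / sum(tab$fraction[!host]),
         confetti_labelable = tab$confetti_labelable[i],
         dtx_ablatable = tab$dtx_ablatable[i])
  })
  out <- list(
    name = cfg$name,
    seed = cfg$seed,
    n_cells = cfg$n_cells,
    marrow = list(host_fraction = sum(tab$fraction[host]),
                  donors = donors),
    recombination = list(
      rate = cfg$recombination$rate,
      outcome_probs = as.numeric(cfg$recombination$outcome_probs),
      cassette_copies = cfg$recombination$cassette_copies
    ),
    n_follicles = cfg$n_follicles,
    founders_per_follicle = cfg$founders_per_follicle,
    tzone_founders = cfg$tzone_founders,
    expansion_concentration = cfg$expansion_concentration,
    go_dark_rate = cfg$go_dark_rate,
    recovery_mode = cfg$recovery_mode,
    homeostatic_target = cfg$homeostatic_target,
    observation_days = as.integer(cfg$observation_days),
    cells_sampled_per_follicle = cfg$cells_sampled_per_follicle,
    min_cells = cfg$min_cells
  )
  if (!is.null(cfg$dtx)) out$dtx <- cfg$dtx
  if (!is.null(cfg$misclassification)) {
    out$misclassification <- apply(cfg$misclassification, 1L, as.numeric,
                                   simplify = FALSE)
  }
  out
}

#' Write a scenario configuration to YAML or JSON
#'
#' @param cfg a [scenario_config()].
#' @param path output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  lst <- config_to_list(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    writeLines(as.character(jsonlite::toJSON(lst, auto_unbox = TRUE,
                                             digits = 12, pretty = TRUE)),
               path)
  } else {
    yaml::write_yaml(lst, path)
  }
  invisible(path)
}

#' Generate the packaged fixture set
#'
#' Writes the [example_scenarios()] configs as YAML plus one small
#' pre-simulated cell table (day-4 sample of `fig4_baseline`, first two
#' follicles). Content is deterministic given `seed`.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed base seed.
#' @return Character vector of written paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 20240904) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", out_dir, call. = FALSE)
  }
  scen <- example_scenarios(seed)
  paths <- character(0)
  for (nm in names(scen)) {
    p <- file.path(out_dir, paste0(nm, ".yaml"))
    write_config(scen[[nm]], p)
    paths <- c(paths, p)
  }
  bundle <- run_scenario(scen$fig4_baseline)
  cells <- bundle$cells
  keep_fol <- utils::head(sort(unique(
    cells$follicle_id[cells$compartment == "follicle"])), 2L)
  sub <- cells[cells$day == min(cells$day) &
                 cells$follicle_id %in% keep_fol, , drop = FALSE]
  p <- file.path(out_dir, "fig4_baseline_day4_cells.csv")
  write_cells(sub, p)
  invisible(c(paths, p))
}
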