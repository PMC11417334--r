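# Scenario configuration: one object describes a full in-silico chimera
# experiment (marrow mix, labeling, clonal dynamics, ablation schedule,
# sampling plan, seed). Validation is strict -- stochastic pipelines are
# only reproducible if configs cannot silently carry typos.

SCENARIO_KEYS <- c(
  "name", "seed", "n_cells", "marrow", "recombination", "n_follicles",
  "founders_per_follicle", "tzone_founders", "expansion_concentration",
  "go_dark_rate", "dtx", "recovery_mode", "homeostatic_target",
  "observation_days", "cells_sampled_per_follicle", "misclassification",
  "min_cells"
)

#' Build a scenario configuration
#'
#' Defaults describe a chimera of 1 part non-labelable autoreactive
#' driver marrow and 2 parts Confetti-labelable marrow (so one-third of
#' donor parts drive the response and two-thirds can be labeled),
#' homozygous cassette, polyclonal growth, and observation at days 4, 18
#' and 32 after the tamoxifen pulse.
#'
#' @param seed integer seed (mandatory; reproducibility is the product).
#' @param n_cells Treg compartment size generated per mouse.
#' @param marrow a [marrow_mix()].
#' @param recombination a [recombination_model()].
#' @param n_follicles,founders_per_follicle,tzone_founders clonal
#'   founding plan.
#' @param expansion_concentration Dirichlet concentration for clone
#'   growth; large = exchangeable/polyclonal, small = oligoclonal skew.
#' @param go_dark_rate per-day probability a labeled clone is replaced by
#'   an unlabeled one.
#' @param dtx `NULL`, or list `start_day`, `every_k_days`,
#'   `ablation_efficiency` (per-dose kill probability of DTR+ cells).
#' @param recovery_mode `"proportional"` or `"oligoclonal"` post-ablation
#'   expansion.
#' @param homeostatic_target steady-state follicle compartment size.
#' @param observation_days days (post pulse) at which cells are sampled.
#' @param cells_sampled_per_follicle sampling cap per follicle (follicles
#'   at or below it are censused).
#' @param misclassification optional 10x10 row-stochastic matrix over
#'   labeled states (spectral channel confusion).
#' @param min_cells labeled cells per follicle required to report
#'   dominance/divergence.
#' @param name scenario label used in reports.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(seed,
                            n_cells = 30000,
                            marrow = default_marrow(),
                            recombination = recombination_model(0.5),
                            n_follicles = 30,
                            founders_per_follicle = 12,
                            tzone_founders = 60,
                            expansion_concentration = 50,
                            go_dark_rate = 0,
                            dtx = NULL,
                            recovery_mode = c("proportional",
                                              "oligoclonal"),
                            homeostatic_target = 400,
                            observation_days = c(4, 18, 32),
                            cells_sampled_per_follicle = 400,
                            misclassification = NULL,
                            min_cells = 5,
                            name = "scenario") {
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory in a scenario configuration", call. = FALSE)
  }
  recovery_mode <- match.arg(recovery_mode)
  cfg <- structure(
    list(
      name = name, seed = as.integer(seed), n_cells = n_cells,
      marrow = marrow, recombination = recombination,
      n_follicles = n_follicles,
      founders_per_follicle = founders_per_follicle,
      tzone_founders = tzone_founders,
      expansion_concentration = expansion_concentration,
      go_dark_rate = go_dark_rate, dtx = dtx,
      recovery_mode = recovery_mode,
      homeostatic_target = homeostatic_target,
      observation_days = as.integer(observation_days),
      cells_sampled_per_follicle = cells_sampled_per_follicle,
      misclassification = misclassification, min_cells = min_cells
    ),
    class = "scenario_config"
  )
  validate_config(cfg)
}

#' Default marrow mix: 1 part driver, 2 parts Confetti
#' @return A [marrow_mix()].
#' @keywords internal
default_marrow <- function() {
  marrow_mix(data.frame(
    genotype = c("564Igi", "FoxP3-Confetti"),
    parts = c(1, 2),
    confetti_labelable = c(FALSE, TRUE),
    dtx_ablatable = c(FALSE, FALSE)
  ))
}

validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(ok, msg) if (!ok) bad <<- c(bad, msg)
  chk(inherits(cfg$marrow, "marrow_mix"), "marrow: not a marrow_mix")
  chk(inherits(cfg$recombination, "recombination_model"),
      "recombination: not a recombination_model")
  chk(is_count(cfg$n_cells) && cfg$n_cells >= 1, "n_cells: positive count")
  chk(is_count(cfg$n_follicles), "n_follicles: non-negative count")
  chk(is_count(cfg$founders_per_follicle),
      "founders_per_follicle: non-negative count")
  chk(is_count(cfg$tzone_founders), "tzone_founders: non-negative count")
  chk(is.numeric(cfg$expansion_concentration) &&
        cfg$expansion_concentration > 0,
      "expansion_concentration: positive real")
  chk(is_prob(cfg$go_dark_rate), "go_dark_rate: probability in [0,1]")
  chk(is_count(cfg$homeostatic_target),
      "homeostatic_target: non-negative count")
  chk(length(cfg$observation_days) >= 0 &&
        all(cfg$observation_days >= 0),
      "observation_days: non-negative days")
  chk(is_count(cfg$cells_sampled_per_follicle),
      "cells_sampled_per_follicle: non-negative count")
  chk(is_count(cfg$min_cells), "min_cells: non-negative count")
  if (!is.null(cfg$dtx)) {
    chk(is.list(cfg$dtx) &&
          all(c("start_day", "every_k_days", "ablation_efficiency") %in%
                names(cfg$dtx)),
        "dtx: needs start_day, every_k_days, ablation_efficiency")
    if (is.list(cfg$dtx) && !is.null(cfg$dtx$ablation_efficiency)) {
      chk(is_prob(cfg$dtx$ablation_efficiency),
          "dtx.ablation_efficiency: probability in [0,1]")
      chk(is_count(cfg$dtx$start_day), "dtx.start_day: non-negative count")
      chk(is.numeric(cfg$dtx$every_k_days) && cfg$dtx$every_k_days >= 1,
          "dtx.every_k_days: >= 1")
    }
  }
  if (!is.null(cfg$misclassification)) {
    m <- cfg$misclassification
    chk(is.matrix(m) && all(dim(m) == c(10L, 10L)) && all(m >= 0) &&
          all(abs(rowSums(m) - 1) < 1e-9),
        "misclassification: 10x10 row-stochastic matrix")
  }
  if (length(bad)) {
    stop("invalid scenario configuration:\n  - ",
         paste(bad, collapse = "\n  - "), call. = FALSE)
  }
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario:", x$name, "(seed", x$seed, ")\n")
  cat("  cells:", x$n_cells, " follicles:", x$n_follicles,
      " founders/follicle:", x$founders_per_follicle,
      " t-zone founders:", x$tzone_founders, "\n")
  cat("  recombination rate:", x$recombination$rate,
      " copies:", x$recombination$cassette_copies, "\n")
  cat("  expansion concentration:", x$expansion_concentration,
      " go-dark rate/day:", x$go_dark_rate, "\n")
  if (!is.null(x$dtx)) {
    cat("  DTX: start day", x$dtx$start_day, ", every",
        x$dtx$every_k_days, "days, per-dose efficiency",
        x$dtx$ablation_efficiency, "; recovery", x$recovery_mode, "\n")
  }
  cat("  observation days:", paste(x$observation_days, collapse = ", "),
      "\n")
  invisible(x)
}

#' Load a scenario configuration from YAML or JSON
#'
#' Strict: unknown keys and a missing seed are errors; defaults injected
#' for absent optional keys are reported via `message()`.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @param quiet suppress the injected-defaults message.
#' @return A validated [scenario_config()].
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(raw), SCENARIO_KEYS)
  if (length(unknown)) {
    stop("unknown configuration keys: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(raw$seed)) {
    stop("configuration must specify `seed`", call. = FALSE)
  }
  args <- raw
  if (!is.null(raw$marrow)) {
    donors <- if (is.data.frame(raw$marrow$donors)) {
      raw$marrow$donors
    } else {
      do.call(rbind, lapply(raw$marrow$donors, as.data.frame))
    }
    hf <- raw$marrow$host_fraction
    args$marrow <- marrow_mix(donors,
                              host_fraction = if (is.null(hf)) 0 else hf)
  }
  if (!is.null(raw$recombination)) {
    rc <- raw$recombination
    args$recombination <- recombination_model(
      rate = rc$rate,
      outcome_probs = if (is.null(rc$outcome_probs)) rep(0.25, 4)
                      else as.numeric(rc$outcome_probs),
      cassette_copies = if (is.null(rc$cassette_copies)) 2
                        else rc$cassette_copies
    )
  }
  if (!is.null(raw$misclassification)) {
    args$misclassification <- matrix(unlist(raw$misclassification),
                                     nrow = 10, byrow = TRUE,
                                     dimnames = list(confetti_states(2),
                                                     confetti_states(2)))
  }
  if (!is.null(raw$dtx)) args$dtx <- raw$dtx
  defaults <- setdiff(setdiff(SCENARIO_KEYS, names(raw)),
                      c("dtx", "misclassification", "name"))
  if (length(defaults) && !quiet) {
    message("load_config: using defaults for ",
            paste(defaults, collapse = ", "))
  }
  do.call(scenario_config, args)
}
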