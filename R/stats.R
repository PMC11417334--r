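# Clonality statistics for multicolor lineage tracing and their
# matched-sample-size multinomial resampling nulls.
#
# Three statistics, all in [0, 1]:
#   labeling density  — XFP+ fraction of a gated population;
#   clonal dominance  — frequency of the most abundant color state among
#                       labeled cells;
#   divergence index  — distance of the observed labeled color-state
#                       frequencies from a reference ("random")
#                       distribution; total variation distance by default.

stat_result <- function(statistic, value, n_labeled, n_total,
                        below_threshold = FALSE, extra = list()) {
  structure(
    c(list(
      statistic = statistic,
      value = value,
      n_labeled = as.integer(n_labeled),
      n_total = as.integer(n_total),
      below_threshold = isTRUE(below_threshold)
    ), extra),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$statistic, ": ",
      if (x$below_threshold) "NA (below min-cells threshold)"
      else format(x$value, digits = 4),
      "  [n_labeled=", x$n_labeled, ", n_total=", x$n_total, "]\n",
      sep = "")
  invisible(x)
}

#' Labeling density of a gated population
#'
#' Fraction of labeled (XFP+) cells among the cells selected by `gate`,
#' e.g. XFP+ cells out of CD4+ CXCR5+ CD25- T cells in the flow readout
#' this emulates.
#'
#' @param cells cell-record data.frame with a `state` column.
#' @param gate `NULL` (all rows), a logical vector, or a predicate
#'   function applied to `cells` returning one.
#' @return A `stat_result`; `below_threshold` with missing value when the
#'   gate selects no cells.
#' @export
labeling_density <- function(cells, gate = NULL) {
  stopifnot(is.data.frame(cells))
  keep <- if (is.null(gate)) rep(TRUE, nrow(cells))
          else if (is.function(gate)) gate(cells)
          else as.logical(gate)
  sub <- cells[keep, , drop = FALSE]
  n <- nrow(sub)
  n_lab <- sum(sub$state != "unlabeled")
  if (n == 0L) {
    return(stat_result("labeling_density", NA_real_, 0L, 0L,
                       below_threshold = TRUE))
  }
  stat_result("labeling_density", n_lab / n, n_lab, n)
}

#' Tabulate labeled color-state counts over the canonical panel
#'
#' @param cells cell-record data.frame (unlabeled rows are dropped).
#' @param cassette_copies 1 or 2; fixes the state panel.
#' @return Named integer vector over [confetti_states()].
#' @export
state_counts <- function(cells, cassette_copies = 2) {
  states <- confetti_states(cassette_copies)
  lab <- cells$state[cells$state != "unlabeled"]
  tab <- table(factor(normalize_state(lab), levels = states))
  stats::setNames(as.integer(tab), states)
}

as_state_counts <- function(x, cassette_copies = 2) {
  if (is.data.frame(x)) {
    return(state_counts(x, cassette_copies))
  }
  x <- unlist(x)
  states <- confetti_states(cassette_copies)
  if (is.null(names(x))) {
    if (length(x) != length(states)) {
      stop("unnamed counts must cover all ", length(states),
           " labeled states", call. = FALSE)
    }
    return(stats::setNames(as.numeric(x), states))
  }
  if (any(x < 0) || any(is.na(x))) {
    stop("counts must be non-negative", call. = FALSE)
  }
  out <- stats::setNames(numeric(length(states)), states)
  nm <- normalize_state(names(x))
  for (i in seq_along(x)) out[nm[i]] <- out[nm[i]] + x[i]
  out
}

#' Clonal dominance: frequency of the most abundant color state
#'
#' Computed among labeled cells only (the statistic the imaging readout
#' reports as "frequency of the most dominant XFP"). Ties are reported as
#' the canonically first state; the value itself is tie-invariant.
#'
#' @param x cell-record data.frame or named labeled-state counts.
#' @param min_cells labeled cells required for a non-missing value.
#' @param cassette_copies 1 or 2.
#' @return A `stat_result` with `dominant_state` attached.
#' @export
clonal_dominance <- function(x, min_cells = 1, cassette_copies = 2) {
  counts <- as_state_counts(x, cassette_copies)
  n <- sum(counts)
  if (n < max(1, min_cells)) {
    return(stat_result("clonal_dominance", NA_real_, n, n,
                       below_threshold = TRUE,
                       extra = list(dominant_state = NA_character_)))
  }
  top <- which.max(counts)  # first max = canonical tie-break
  stat_result("clonal_dominance", unname(counts[top]) / n, n, n,
              extra = list(dominant_state = names(counts)[top]))
}

#' Clonal divergence index
#'
#' Distance of the observed labeled color-state frequencies from a
#' reference ("random") distribution. Default metric is total variation
#' distance, `0.5 * sum(|f - b|)`, bounded in \[0, 1\]; Euclidean (L2)
#' distance is available as an option. Unlabeled cells are excluded and
#' frequencies renormalized before comparison.
#'
#' @param x cell-record data.frame or named labeled-state counts.
#' @param baseline probability vector over the canonical labeled states.
#' @param metric `"tvd"` (default) or `"euclidean"`.
#' @param min_cells labeled cells required for a non-missing value.
#' @param cassette_copies 1 or 2.
#' @return A `stat_result`.
#' @export
divergence_index <- function(x, baseline, metric = c("tvd", "euclidean"),
                             min_cells = 1, cassette_copies = 2) {
  metric <- match.arg(metric)
  counts <- as_state_counts(x, cassette_copies)
  if (length(baseline) != length(counts) || any(baseline < 0)) {
    stop("`baseline` must be a probability vector over the ",
         length(counts), " labeled states", call. = FALSE)
  }
  if (abs(sum(baseline) - 1) > 1e-9) {
    stop("`baseline` must sum to 1 (within 1e-9)", call. = FALSE)
  }
  n <- sum(counts)
  if (n < max(1, min_cells)) {
    return(stat_result("divergence_index", NA_real_, n, n,
                       below_threshold = TRUE,
                       extra = list(metric = metric)))
  }
  f <- counts / n
  value <- switch(metric,
    tvd = 0.5 * sum(abs(f - baseline)),
    euclidean = sqrt(sum((f - baseline)^2))
  )
  stat_result("divergence_index", value, n, n,
              extra = list(metric = metric))
}

divergence_from_freq <- function(f, baseline, metric = "tvd") {
  switch(metric,
         tvd = 0.5 * colSums(abs(f - baseline)),
         euclidean = sqrt(colSums((f - baseline)^2)))
}

#' Multinomial resampling null for a clonality statistic
#'
#' Draws `reps` multinomial samples of size `n` from `baseline` and
#' computes the statistic on each: the matched-sample-size null
#' distribution under random (non-clonal) color assignment.
#'
#' @param statistic `"clonal_dominance"` or `"divergence_index"`.
#' @param n matched number of labeled cells (>= 1).
#' @param baseline probability vector over the canonical labeled states.
#' @param reps number of resamples, default 10000.
#' @param seed integer seed or `NULL`.
#' @param metric divergence metric, see [divergence_index()].
#' @return Object of class `null_distribution` with fields `statistic`,
#'   `n`, `baseline`, `reps`, `samples`, `seed`.
#' @export
null_statistics <- function(statistic = c("clonal_dominance",
                                          "divergence_index"),
                            n, baseline, reps = 10000, seed = NULL,
                            metric = "tvd") {
  statistic <- match.arg(statistic)
  stopifnot(is_count(n), n >= 1, is_count(reps), reps >= 1)
  if (abs(sum(baseline) - 1) > 1e-9) {
    stop("`baseline` must sum to 1 (within 1e-9)", call. = FALSE)
  }
  samples <- with_seed(seed, {
    draws <- stats::rmultinom(reps, n, baseline)
    f <- draws / n
    if (statistic == "clonal_dominance") {
      apply(f, 2L, max)
    } else {
      divergence_from_freq(f, as.numeric(baseline), metric)
    }
  })
  structure(
    list(statistic = statistic, n = as.integer(n),
         baseline = as.numeric(baseline), reps = as.integer(reps),
         samples = as.numeric(samples), seed = seed, metric = metric),
    class = "null_distribution"
  )
}

#' Upper-tail resampling p-value
#'
#' Add-one construction `(#{null >= observed} + 1) / (reps + 1)`, valid
#' (super-uniform under the null). Upper tail: both dominance and
#' divergence increase under clonal skew.
#'
#' @param null a [null_statistics()] result.
#' @param observed observed statistic value.
#' @return p-value in (0, 1\].
#' @export
null_p_value <- function(null, observed) {
  stopifnot(inherits(null, "null_distribution"))
  (sum(null$samples >= observed) + 1) / (null$reps + 1)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Multinomial null for", x$statistic, "at n =", x$n,
      "(", x$reps, "resamples )\n")
  cat("  mean", format(mean(x$samples), digits = 4),
      " q95", format(stats::quantile(x$samples, 0.95, names = FALSE),
                     digits = 4), "\n")
  invisible(x)
}

#' Small-sample bias profile of a null statistic
#'
#' Null mean, SD and quantiles of a statistic across a grid of sample
#' sizes. Both dominance and divergence are biased upward at small n
#' (few observed cells skew toward higher dominance and higher
#' divergence), so the null mean decreases with n.
#'
#' @param statistic,baseline,reps,seed,metric as in [null_statistics()].
#' @param n_grid non-empty vector of sample sizes.
#' @return data.frame with columns `n`, `mean`, `sd`, `q05`, `q95`.
#' @export
bias_profile <- function(statistic, baseline, n_grid, reps = 2000,
                         seed = NULL, metric = "tvd") {
  if (length(n_grid) == 0L) {
    stop("`n_grid` must be non-empty", call. = FALSE)
  }
  with_seed(seed, {
    rows <- lapply(n_grid, function(n) {
      s <- null_statistics(statistic, n, baseline, reps = reps,
                           seed = NULL, metric = metric)$samples
      data.frame(n = n, mean = mean(s), sd = stats::sd(s),
                 q05 = stats::quantile(s, 0.05, names = FALSE),
                 q95 = stats::quantile(s, 0.95, names = FALSE))
    })
    do.call(rbind, rows)
  })
}

#' Classify a follicle as polyclonal or oligoclonal
#'
#' Upper-tail test of the observed divergence index against its
#' matched-sample-size multinomial null. Follicles with fewer than
#' `min_cells` labeled cells are `"indeterminate"` (small counts inflate
#' both statistics).
#'
#' @param x cell-record data.frame or named labeled-state counts.
#' @param baseline probability vector over the canonical labeled states.
#' @param reps null resamples, default 2000.
#' @param alpha significance level, default 0.05.
#' @param seed integer seed or `NULL`.
#' @param min_cells threshold below which no call is made, default 5.
#' @param metric divergence metric.
#' @return List with `call` (`"consistent_with_polyclonal"`,
#'   `"oligoclonal"` or `"indeterminate"`), `p_value`, `statistic_used`,
#'   `n_labeled`, `observed`.
#' @export
classify_expansion <- function(x, baseline, reps = 2000, alpha = 0.05,
                               seed = NULL, min_cells = 5,
                               metric = "tvd") {
  counts <- as_state_counts(x)
  n <- sum(counts)
  if (n < min_cells) {
    return(list(call = "indeterminate", p_value = NA_real_,
                statistic_used = "divergence_index",
                n_labeled = as.integer(n), observed = NA_real_))
  }
  obs <- divergence_index(counts, baseline, metric = metric)$value
  null <- null_statistics("divergence_index", n, baseline, reps = reps,
                          seed = seed, metric = metric)
  p <- null_p_value(null, obs)
  list(
    call = if (p < alpha) "oligoclonal" else "consistent_with_polyclonal",
    p_value = p,
    statistic_used = "divergence_index",
    n_labeled = as.integer(n),
    observed = obs
  )
}
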