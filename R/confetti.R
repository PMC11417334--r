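# Generative model of Brainbow2.1/Confetti cassette recombination.
#
# Each cassette copy, once recombined by tamoxifen-pulsed Cre, commits to
# one of four fluorophores. A homozygous carrier has two independent
# copies, so a cell displays either no color (neither copy recombined),
# one color (one copy recombined, or both to the same fluorophore), or an
# unordered pair of two distinct colors: 10 distinguishable labeled states.

#' Canonical Confetti fluorophores
#'
#' The four fluorophores a recombined Brainbow2.1 cassette copy can
#' express, in the canonical order used for all serialization and
#' tie-breaking throughout the package.
#'
#' @format Character vector of length 4: `nGFP`, `YFP`, `RFP`, `mCFP`.
#' @export
CONFETTI_FLUOROPHORES <- c("nGFP", "YFP", "RFP", "mCFP")

#' Enumerate distinguishable labeled color states
#'
#' For a homozygous cassette (two copies) there are exactly 10 labeled
#' states: 4 single colors plus the 6 unordered pairs of distinct colors
#' (two copies recombined to the same fluorophore are indistinguishable
#' from one). A hemizygous cassette yields the 4 single colors; no
#' cassette yields none.
#'
#' @param cassette_copies number of cassette copies: 0, 1 or 2.
#' @return Character vector of state labels in canonical order:
#'   singletons in fluorophore order, then pairs in lexicographic order of
#'   fluorophore indices, each pair joined by `"+"`.
#' @examples
#' confetti_states(2)  # 10 states
#' @export
confetti_states <- function(cassette_copies = 2) {
  if (!is_count(cassette_copies) || !cassette_copies %in% c(0, 1, 2)) {
    stop("`cassette_copies` must be 0, 1 or 2", call. = FALSE)
  }
  if (cassette_copies == 0) {
    return(character(0))
  }
  singles <- CONFETTI_FLUOROPHORES
  if (cassette_copies == 1) {
    return(singles)
  }
  idx <- utils::combn(4L, 2L)
  pairs <- apply(idx, 2L, function(i) {
    paste(CONFETTI_FLUOROPHORES[i], collapse = "+")
  })
  c(singles, pairs)
}

#' Normalize color-state strings to canonical form
#'
#' Accepts `"unlabeled"`, single fluorophore names, and two-fluorophore
#' combinations joined by `"+"` in any order (`"RFP+YFP"` becomes
#' `"YFP+RFP"`). Invalid names, duplicated fluorophores or more than two
#' components are errors.
#'
#' @param state character vector of state strings.
#' @return Character vector of canonical state strings.
#' @export
normalize_state <- function(state) {
  vapply(as.character(state), function(s) {
    if (is.na(s)) stop("state string is NA", call. = FALSE)
    if (identical(s, "unlabeled")) return("unlabeled")
    parts <- strsplit(s, "+", fixed = TRUE)[[1]]
    if (length(parts) < 1L || length(parts) > 2L ||
        anyDuplicated(parts) || !all(parts %in% CONFETTI_FLUOROPHORES)) {
      stop("invalid state string: '", s, "'", call. = FALSE)
    }
    paste(parts[order(match(parts, CONFETTI_FLUOROPHORES))], collapse = "+")
  }, character(1), USE.NAMES = FALSE)
}

#' Cassette recombination model
#'
#' Parameterizes recombination at the tamoxifen pulse: each cassette copy
#' independently recombines with probability `rate`, and a recombined copy
#' commits to fluorophore `i` with probability `outcome_probs[i]`.
#'
#' @param rate per-copy recombination probability in \[0, 1\].
#' @param outcome_probs probability vector of length 4 over
#'   [CONFETTI_FLUOROPHORES] (conditional on recombination); defaults to
#'   uniform. Must sum to 1 within 1e-12 after no rescaling is applied.
#' @param cassette_copies 1 (hemizygous) or 2 (homozygous, the default).
#' @return An object of class `recombination_model`.
#' @export
recombination_model <- function(rate,
                                outcome_probs = rep(0.25, 4),
                                cassette_copies = 2) {
  if (!is_prob(rate)) {
    stop("`rate` must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(outcome_probs) || length(outcome_probs) != 4L ||
      any(is.na(outcome_probs)) || any(outcome_probs < 0)) {
    stop("`outcome_probs` must be 4 non-negative probabilities",
         call. = FALSE)
  }
  if (abs(sum(outcome_probs) - 1) > 1e-12) {
    stop("`outcome_probs` must sum to 1 (within 1e-12)", call. = FALSE)
  }
  if (!is_count(cassette_copies) || !cassette_copies %in% c(1, 2)) {
    stop("`cassette_copies` must be 1 or 2", call. = FALSE)
  }
  structure(
    list(
      rate = as.numeric(rate),
      outcome_probs = stats::setNames(as.numeric(outcome_probs),
                                      CONFETTI_FLUOROPHORES),
      cassette_copies = as.integer(cassette_copies)
    ),
    class = "recombination_model"
  )
}

#' @export
print.recombination_model <- function(x, ...) {
  cat("Confetti recombination model\n")
  cat("  per-copy recombination rate:", format(x$rate), "\n")
  cat("  cassette copies:", x$cassette_copies,
      if (x$cassette_copies == 2L) "(homozygous)" else "(hemizygous)", "\n")
  cat("  outcome probabilities:",
      paste(names(x$outcome_probs), format(x$outcome_probs), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Closed-form distribution over observable color states
#'
#' With independent cassette copies, write `r` for the per-copy
#' recombination rate and `p_a` for the outcome probability of fluorophore
#' `a`. For two copies:
#' `P(unlabeled) = (1 - r)^2`,
#' `P(single a) = 2 r (1 - r) p_a + r^2 p_a^2` (one copy recombined to
#' `a`, or both copies to `a`), and
#' `P(pair {a, b}) = 2 r^2 p_a p_b` for `a != b`.
#' For one copy: `P(unlabeled) = 1 - r`, `P(single a) = r p_a`.
#'
#' @param model a [recombination_model()].
#' @return Named numeric vector over `"unlabeled"` plus the labeled states
#'   of [confetti_states()] in canonical order; sums to 1.
#' @export
state_distribution <- function(model) {
  stopifnot(inherits(model, "recombination_model"))
  r <- model$rate
  p <- model$outcome_probs
  states <- confetti_states(model$cassette_copies)
  if (model$cassette_copies == 1L) {
    probs <- c(unlabeled = 1 - r, stats::setNames(r * p, states))
    return(probs)
  }
  singles <- 2 * r * (1 - r) * p + r^2 * p^2
  idx <- utils::combn(4L, 2L)
  pairs <- 2 * r^2 * p[idx[1L, ]] * p[idx[2L, ]]
  probs <- c(unlabeled = (1 - r)^2,
             stats::setNames(c(singles, pairs), states))
  probs
}

#' Overall labeling probability
#'
#' Probability that at least one cassette copy recombines:
#' `1 - (1 - rate)^copies`. This is the expected labeling density among
#' labelable cells.
#'
#' @param model a [recombination_model()].
#' @return Scalar probability.
#' @export
labeling_probability <- function(model) {
  stopifnot(inherits(model, "recombination_model"))
  1 - (1 - model$rate)^model$cassette_copies
}

#' Theoretical baseline color distribution
#'
#' The state distribution conditioned on being labeled, i.e. the expected
#' color-state frequencies among XFP+ cells. This is the default
#' reference ("random") distribution for the clonal divergence index.
#'
#' @param model a [recombination_model()].
#' @return Named probability vector over the labeled states in canonical
#'   order.
#' @export
labeled_baseline <- function(model) {
  d <- state_distribution(model)
  lab <- d[names(d) != "unlabeled"]
  tot <- sum(lab)
  if (tot <= 0) {
    stop("labeling probability is zero; no labeled baseline exists",
         call. = FALSE)
  }
  lab / tot
}

#' Empirical baseline from observed labeled-state counts
#'
#' Renormalizes observed counts of labeled color states onto the canonical
#' state order; states absent from the input get probability 0. Used to
#' build an empirical reference distribution (e.g. from pooled T-cell-zone
#' Tregs) instead of the theoretical one.
#'
#' @param counts named numeric vector or list mapping state strings
#'   (canonicalized via [normalize_state()]) to non-negative counts.
#' @param cassette_copies 1 or 2; fixes the state panel.
#' @return Named probability vector over the canonical labeled states.
#' @export
baseline_from_counts <- function(counts, cassette_copies = 2) {
  counts <- unlist(counts)
  if (length(counts) == 0L || is.null(names(counts))) {
    stop("`counts` must be a named vector of labeled-state counts",
         call. = FALSE)
  }
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  states <- confetti_states(cassette_copies)
  nm <- normalize_state(names(counts))
  if (any(nm == "unlabeled")) {
    stop("`counts` must contain labeled states only", call. = FALSE)
  }
  out <- stats::setNames(numeric(length(states)), states)
  for (i in seq_along(counts)) {
    out[nm[i]] <- out[nm[i]] + counts[i]
  }
  tot <- sum(out)
  if (tot == 0) {
    stop("total count is zero; cannot form a baseline", call. = FALSE)
  }
  out / tot
}

#' Estimate the per-copy recombination rate from a labeling density
#'
#' Inverts `density = 1 - (1 - r)^copies` and transforms an exact binomial
#' (Clopper-Pearson) confidence interval on the labeled fraction.
#'
#' @param n_labeled,n_total labeled and total gated cell counts.
#' @param cassette_copies 1 or 2.
#' @param conf_level confidence level, default 0.95.
#' @return List with `rate`, `conf_int` (length 2) and the input counts.
#' @export
estimate_labeling_rate <- function(n_labeled, n_total, cassette_copies = 2,
                                   conf_level = 0.95) {
  stopifnot(is_count(n_labeled), is_count(n_total), n_total >= 1,
            n_labeled <= n_total)
  bt <- stats::binom.test(n_labeled, n_total, conf.level = conf_level)
  inv <- function(d) 1 - (1 - d)^(1 / cassette_copies)
  list(
    rate = inv(n_labeled / n_total),
    conf_int = inv(as.numeric(bt$conf.int)),
    n_labeled = as.integer(n_labeled),
    n_total = as.integer(n_total)
  )
}
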