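---
title: "Confetti clonality: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confetti clonality: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfrtrace)
```

This vignette is the package's own account of its science: the
generative model of Confetti labeling, the clonality statistics and
their nulls, what the cohort simulator does and does not emulate, and
the choices made where the design was genuinely open.

## The cassette model

A Brainbow2.1/Confetti cassette copy, recombined by a tamoxifen-pulsed
Cre, commits the cell to one of four fluorophores (nGFP, YFP, RFP,
mCFP). We model the pulse as a single Bernoulli event per copy — the
labeling protocol is a single gavage, so continuous leaky labeling is
not modeled — with per-copy recombination probability $r$ and outcome
probabilities $p = (p_1,\dots,p_4)$ conditional on recombination.
Copies recombine independently with identical $(r, p)$; no inter-allele
interference is assumed, the simplest model consistent with the
cassette design.

Two copies recombined to the same fluorophore are indistinguishable
from one, so a homozygous carrier shows one of $4 + \binom{4}{2} = 10$
labeled states. Closed form (two copies):

$$P(\varnothing) = (1-r)^2,\qquad
  P(\{a\}) = 2r(1-r)p_a + r^2p_a^2,\qquad
  P(\{a,b\}) = 2r^2p_ap_b .$$

The tests verify this against brute-force enumeration of ordered
per-copy outcomes (exact) and an independent per-allele Monte-Carlo
sampler (within 3 binomial SE). The overall labeling probability is
$1-(1-r)^{\text{copies}}$, which `estimate_labeling_rate()` inverts
(with a Clopper–Pearson interval) to recover $r$ from an observed
labeling density.

**Outcome probabilities.** Published per-fluorophore recombination
frequencies for this cassette are not available and empirical Brainbow
outcomes are known to be non-uniform, so $p$ is configurable with a
uniform default, and an *empirical* baseline
(`baseline_from_counts()`) can replace the theoretical one wherever a
reference color distribution is needed. The scenario runner prefers the
pooled T-cell-zone labeled frequencies (at least 50 cells observed) as
that reference, because the T-zone Treg pool is the natural
non-clonally-selected compartment; otherwise it falls back to the
theoretical baseline.

**nGFP detectability.** Imaging channels for nGFP overlap those of mCFP
and YFP, and whether nGFP is reliably scored as a distinct color is an
open question of the readout. The model keeps all four fluorophores; a
channel-confusion experiment can be emulated with the optional
row-stochastic `misclassification` matrix, and exclusion of a
fluorophore is a configuration (set its outcome probability to zero)
rather than a model change.

## Clonality statistics and their nulls

All three statistics live in $[0,1]$ and are computed among labeled
(XFP+) cells, with unlabeled cells excluded and frequencies
renormalized:

* **labeling density** — labeled fraction of a gated population;
* **clonal dominance** — $\max_s f_s$, the share of the most abundant
  color state (ties reported as the canonically first state; the value
  is tie-invariant);
* **clonal divergence index** — distance of observed state frequencies
  $f$ from a reference $b$. No formula for this index is in general
  circulation, so the package defaults to total variation distance
  $\tfrac12\sum_s |f_s-b_s|$ — bounded, interpretable as the
  maximum probability discrepancy — with Euclidean distance as a
  configurable alternative. All calibration properties are stated for
  TVD.

With few cells both statistics are biased upward: at $n$ labeled cells
over 10 states the null mean of dominance runs from 1 at $n=1$ down
toward 0.1, and null TVD from 0.9 down toward 0. `bias_profile()`
quantifies this, and per-follicle results below `min_cells` (default 5)
labeled cells are reported missing rather than biased — a handful of
observed cells would otherwise masquerade as strong clonal skew.

Significance is assessed against the matched-$n$ multinomial null:
`null_statistics()` draws `reps` multinomial samples from the baseline
and `null_p_value()` applies the add-one upper-tail construction
$(\#\{t^\ast \ge t\}+1)/(R+1)$, which is super-uniform under the null
by the permutation-test argument. Upper tail only: both statistics
increase under clonal skew. Seeds are mandatory in scenario
configurations; reproducibility is treated as part of the result.

**What the absolute test measures.** The null colors every cell
independently — the limit of infinitely many small clones. A follicle
founded by a dozen clones sits far from that null even under perfectly
exchangeable growth, because clonal granularity alone concentrates
color mass. The absolute `classify_expansion()` call therefore detects
*clonal structure*; discriminating polyclonal from oligoclonal
*dynamics* is done comparatively (treated vs untreated, early vs late)
with the rank-sum test, which is how the ablation analysis is wired.
The `analysis/04` script prints both readouts side by side to keep this
distinction visible.

## The cohort simulator

`run_scenario()` executes one in-silico chimera experiment:

1. **Marrow mixing** — origin genotypes drawn multinomially from donor
   part ratios (e.g. 1:1:1, making one-third of Tregs
   Confetti-labelable) scaled by an optional radio-resistant host
   fraction. Host Tregs are a single configurable fraction; their size
   is not quantified in vivo, so the default is 0 and the packaged
   scenarios state their mixes explicitly.
2. **Labeling** — each labelable FoxP3+ cell draws a state from the
   cassette model.
3. **Founding** — clone founders are sampled without replacement from a
   shared per-mouse pool: `founders_per_follicle` per follicle plus one
   T-zone compartment. No inter-follicle migration is modeled; whether
   Tfr clones redistribute between neighboring follicles is unresolved
   in vivo, and a redistribution process would mask local clonal
   expansion in exactly the way it would in the real experiment. This
   no-migration assumption is therefore load-bearing and documented
   here rather than buried.
4. **Growth** — per follicle and day, clone proportions are redrawn
   from $\mathrm{Dirichlet}(\alpha\, m\, \pi_{\text{prev}})$ ($m$ =
   number of clones; symmetric $\mathrm{Dirichlet}(\alpha)$ at uniform
   proportions) and realized by a multinomial draw at the compartment
   size `homeostatic_target`. One knob $\alpha$ spans
   exchangeable/polyclonal growth ($\alpha$ large) to oligoclonal skew
   ($\alpha$ small) — exactly the contrast the statistics must detect.
   Compartments are treated as homeostatically sized from day 1;
   no growth law for follicle seeding is published, and observing
   before a compartment reaches steady state would confound
   count comparisons with growth.
   Note the daily multinomial realization injects variance
   $\sim p(1-p)/N$ per day even as $\alpha \to \infty$, so clone shares
   random-walk slowly; "stable polyclonal" scenarios use large
   compartments (N ≥ 2000) and large $\alpha$ so that drift over the
   observation window stays below sampling noise.
5. **Go dark** — each labeled clone is replaced by an unlabeled clone of
   equal size with per-day probability `go_dark_rate`: whole-clone
   replacement, the simplest mechanism by which pooled labeling density
   can decline while follicles that remain labeled keep their
   labeled-cell counts. Gradual dilution would instead fade every
   follicle uniformly — the two accounts are distinguishable, and the
   package implements the replacement one.
6. **Ablation** — each cell of DTR-marrow origin survives each DTX
   administration independently with probability
   $1-\text{efficiency}$; doses accumulate per the schedule (default
   every 3 days). Per-dose kill probability is not identifiable from
   published outcome ratios alone, so it is a free parameter (packaged
   scenarios use 0.5/dose, giving ~94% depletion after four doses).
   Surviving clones then expand back to the pre-ablation compartment
   size — proportionally to size (exchangeable: preserves expected
   relative color composition, the definition of polyclonal recovery)
   or Dirichlet-reweighted (oligoclonal counterfactual).
7. **Observation** — per follicle, `cells_sampled_per_follicle` cells
   are drawn without replacement (small follicles are censused),
   optional misclassification applied, rows sorted deterministically.

Tissue labels (spleen, IngLN, MesLN) are annotation only; observed
patterns are similar across tissues, and no tissue-specific dynamics
are modeled. Follicles are the statistical unit throughout, as in the
imaging readout; mouse-level clustering is noted in report metadata but
not modeled.

## Packaged scenarios and their parameters

The generator's defaults are the study conditions, not tuning knobs:

* `fig3_godark` — 1 part driver : 2 parts Confetti marrow (two-thirds
  labelable), $r=0.2$, 40 follicles, 4 founders each, compartment 300,
  `go_dark_rate` 0.06/day, observed days 4/18/32. The low founder count
  and rate put follicles in the observed regime of few labeled clones,
  where going dark is approximately all-or-none per follicle. Geometric
  clone survival implies a density ratio $0.94^{28}\approx0.18$ between
  days 4 and 32.
* `fig4_baseline` — same chimera, no waning, $\alpha=10^4$, compartment
  2000: dominance and divergence flat from day 4 to 32.
* `fig5_polyclonal` / `fig5_oligoclonal` — 1:1:1 three-part marrow
  (one-third labelable, two-thirds ablatable), $r=0.6$, DTX every
  3 days from day 4 at efficiency 0.5/dose, observed day 3 (pre) and
  day 15 (post); proportional vs Dirichlet-skewed ($\alpha=0.3$)
  recovery. Expected labeled-count fold change under full depletion of
  the unlabeled two-thirds is ~2.5–3×.

Cohort sizes (tens of follicles, hundreds to thousands of cells per
compartment, 2–3×10^4 Tregs per simulated mouse) are chosen to mirror
the scale of the imaging experiments while keeping every packaged
scenario under a second of runtime; the test suite and acceptance
script run the same sizes.

**Power analysis.** `power_analysis()` models the oligoclonal effect as
a Dirichlet perturbation of the baseline color distribution at
concentration $\alpha$ (state-level, not clone-level), so the
polyclonal limit coincides exactly with the multinomial null and power
equals the test level there — the property that makes the power curve
interpretable. The clone-level route would conflate granularity with
skew (see above). At realistic per-follicle counts (5–15 labeled
cells) only strong skew ($\alpha \le 0.3$) is reliably detectable:
absence of a divergence signal at such counts bounds only gross
oligoclonality.

## Group comparison

`compare_groups()` is the Wilcoxon–Mann–Whitney rank-sum test (the test
named in the source experiments' legends), delegated to
`stats::wilcox.test`: exact two-sided p by enumeration when both groups
have ≤ 12 tie-free observations, otherwise the normal approximation
with continuity and tie correction. Exact enumeration with midrank ties
has no standard definition, so ties always route to the corrected
approximation; fully tied groups return p = 1. The omnibus
ANOVA/post-test machinery used for routine phenotyping panels is out of
scope — only the rank-sum comparison bears on the clonality readouts.

## Numerical and degenerate-input conventions

* Canonical state order (nGFP, YFP, RFP, mCFP; singletons then pairs)
  fixes serialization, tie-breaks and vector layouts; `"RFP+YFP"`
  normalizes to `"YFP+RFP"` on input.
* Probability vectors must sum to 1 within 1e-12 (model inputs) or 1e-9
  (baselines, misclassification rows); violations are errors, not
  renormalizations.
* Zero gated cells, zero labeled cells, or counts below `min_cells`
  yield `below_threshold` results with missing values — never 0/0.
* Empty clone sets, zero-follicle scenarios and header-only cell files
  propagate as empty tables without error.
* Dirichlet draws use gamma variates; zero-size clones have zero
  concentration and stay extinct.
* All file output uses LF newlines, fixed column order and
  `toJSON(digits = 10)`, so identical configurations give
  byte-identical artifacts; every stochastic entry point takes a seed,
  and scenario configs refuse to load without one.

## What passing tests do and do not show

The simulator reproduces the *logical structure* of the chimera
experiments: mixing arithmetic, labeling combinatorics, clone-level
growth, ablation schedules, sampling granularity. It does not emulate
imaging segmentation error beyond the confusion matrix, spatial
follicle geometry, TCR-level clonal identity (color collisions between
distinct clones are real and present in the model, as in the
experiment), recirculation between follicles, or mouse-level random
effects. Green tests therefore validate the statistical machinery and
the internal consistency of the in-silico experiments — not the
biological parameter values, which are stated assumptions wherever the
source experiments do not pin them down.

## Session info

```{r}
sessionInfo()
```
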