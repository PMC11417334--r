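# tfrtrace

In-silico clonal lineage tracing of follicular regulatory T cells (Tfr)
with multicolor Confetti reporters.

Germinal centers (GCs) — the lymphoid microstructures where B cells
affinity-mature — are policed by FoxP3+ CXCR5+ Tfr. Whether Tfr
populations in chronic autoimmune GCs are clonally selected, and how
they respond to partial depletion, can be read out with Brainbow2.1
("Confetti") reporters: a tamoxifen pulse stochastically commits each
cassette copy of a FoxP3+ cell to one of four fluorophores, and a
homozygous carrier displays one of **ten** distinguishable color states.
Color is clonally heritable, so per-follicle color-state distributions
carry clonal information — but at the handful of labeled cells a
two-photon imaging readout yields per follicle, the statistics are
strongly biased and need matched-sample-size nulls.

`tfrtrace` provides, as tested R code:

* **Cassette model** — the closed-form distribution over observable
  color states for per-copy recombination probability *r* and outcome
  probabilities *p*: for a homozygous cassette
  P(unlabeled) = (1−r)², P(single *a*) = 2r(1−r)p<sub>a</sub> + r²p<sub>a</sub>²,
  P(pair {*a*,*b*}) = 2r²p<sub>a</sub>p<sub>b</sub>; overall labeling
  probability 1−(1−r)<sup>copies</sup>.
* **Cohort simulator** — seeded mixed bone-marrow chimeras (donor part
  ratios, host fraction), tamoxifen-pulse labeling, clonal founding of
  follicles and T-cell zones, Dirichlet-multinomial clone growth
  (exchangeable/polyclonal at large concentration, oligoclonal at
  small), labeled-clone replacement ("go dark"), diphtheria-toxin
  ablation of DTR-marrow-derived cells with homeostatic recovery, and
  per-follicle sampling with optional spectral misclassification.
* **Clonality statistics** — labeling density; clonal dominance
  (frequency of the most abundant color state, max<sub>s</sub> f<sub>s</sub>);
  clonal divergence index (total variation distance
  ½Σ|f<sub>s</sub> − b<sub>s</sub>| from a reference distribution *b*,
  Euclidean optional); multinomial resampling nulls at matched n with
  add-one upper-tail p-values; small-sample bias profiles; a
  polyclonal-vs-oligoclonal classifier.
* **Pipeline** — scenario runner over YAML/JSON configs,
  Wilcoxon–Mann–Whitney group comparison (exact for small tie-free
  groups), power analysis, reproducible JSON reports.

## Worked example

```r
library(tfrtrace)

model <- recombination_model(rate = 0.5)   # homozygous by default
round(state_distribution(model), 4)
#> unlabeled      nGFP       YFP       RFP      mCFP  nGFP+YFP  nGFP+RFP nGFP+mCFP
#>    0.2500    0.1406    0.1406    0.1406    0.1406    0.0312    0.0312    0.0312
#>   YFP+RFP  YFP+mCFP  RFP+mCFP
#>    0.0312    0.0312    0.0312
labeling_probability(model)
#> [1] 0.75
```

A quarter of labelable cells stay unlabeled at r = 0.5; each single
color carries 14.1% and each two-color combination 3.1% of the mass.

The packaged partial-ablation scenario mixes three marrows 1:1:1 (one
Confetti-labelable, two DTX-ablatable), pulses with tamoxifen, ablates
every 3 days from day 4, and recovers follicles proportionally:

```r
bundle <- run_scenario(example_scenarios(20240904)$fig5_polyclonal)
bundle
#> Scenario bundle: fig5_polyclonal
#>   cells sampled: 24600   baseline: empirical_t_zone
#>  day n_cells labeling_density n_follicles n_labeled_follicles
#>    3   12300            0.307          40                  40
#>   15   12300            0.761          40                  40
#>  mean_labeled_per_labeled_follicle mean_dominance mean_divergence
#>                               92.5          0.518           0.644
#>                              227.7          0.526           0.649
bundle$comparisons$n_labeled
#> Rank-sum: pre_ablation (n=40) vs post_ablation (n=40): U=35.5, p=1.953e-13 [normal_approximation]
bundle$comparisons$dominance
#> Rank-sum: pre_ablation (n=40) vs post_ablation (n=40): U=764, p=0.7322 [normal_approximation]
```

Labeled cells per follicle rise ~2.5-fold after depleting the
unlabeled two-thirds of the compartment (rank-sum p ≈ 2e-13), while
clonal dominance does not move (p = 0.73): the surviving labeled
population expanded polyclonally.

## Analysis workflow

The `analysis/` scripts run the full set of in-silico experiments and
write their tables under `results/`:

| script | experiment |
|---|---|
| `01_cassette_model.R` | state probabilities; null bias of both statistics vs n |
| `02_waning_scenario.R` | pulse-chase waning: pooled density falls, labeled follicles keep counts |
| `03_clonal_stability.R` | stable polyclonal follicular populations, days 4–32 |
| `04_ablation_expansion.R` | partial ablation: counts rise, clonality flat; oligoclonal counterfactual |
| `05_power.R` | power to detect oligoclonality vs effect size and cell count |

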