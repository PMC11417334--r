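Package: tfrtrace
Title: Clonal Lineage Tracing of Follicular Regulatory T Cells with
    Confetti Reporters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Generative model of Brainbow2.1/Confetti cassette
    recombination and a seeded simulator of mixed bone-marrow chimera
    experiments on FoxP3+ regulatory T cells, together with the clonality
    statistics used to read such experiments: labeling density, clonal
    dominance (frequency of the most abundant color state) and a clonal
    divergence index (distance of the observed color-state distribution
    from a reference), each with matched-sample-size multinomial
    resampling nulls, small-sample bias profiles, a polyclonal versus
    oligoclonal classifier, rank-sum group comparison and power analysis.
    Scenarios cover tamoxifen pulse-chase labeling with clone waning
    ("go dark"), stable polyclonal follicular populations, and diphtheria
    toxin ablation with homeostatic recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
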