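Package: airwaybiogeo
Title: Paired Multi-Site Airway Microbiome Biogeography Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for bacterial biogeography analysis of paired
    airway samples (protected bronchial brush, induced sputum, oral wash, and
    nasal brush) profiled by 16S rRNA gene sequencing. Implements
    rarefaction-ensemble alpha diversity (richness, Shannon, Faith
    phylogenetic diversity, Pielou evenness), unweighted and weighted UniFrac
    with principal coordinate ordination and linear mixed-effects testing,
    per-subject shared/exclusive taxon partitioning across body sites,
    dominant-genus classification with contingency analysis, clinical and
    inflammatory association scans with Benjamini-Hochberg correction, and a
    three-model (Poisson, negative binomial, zero-inflated negative binomial)
    differential-abundance framework. Includes a Dirichlet-multinomial
    synthetic paired-cohort generator with a ground-truth sidecar for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    MASS,
    lme4,
    biomformat,
    jsonlite,
    tibble,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    picante,
    withr
Config/testthat/edition: 3
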