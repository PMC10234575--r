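Package: elentomics
Title: Metabolic Niche Analysis for Anaerobic Gut Bacteria
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated toolkit for characterizing the metabolic niche of a
    cultured gut bacterium such as Eggerthella lenta. Provides untargeted
    metabolomics feature quality control and differential abundance analysis
    (blank filtering, coefficient-of-variation and outlier filters, pseudocount
    log transformation, cross-ionization-mode dereplication, Welch tests with
    Benjamini-Hochberg correction, permutation tests on smoothing-spline
    trajectories); cross-dataset feature linking by m/z, retention time, and
    MS2 cosine similarity with a null-calibrated cutoff; natural-abundance
    correction of mass-isotopologue distributions from stable-isotope tracing
    with non-negative least squares; constraint-based genome-scale metabolic
    modeling (FBA, parsimonious FBA, flux variability analysis, media
    conditioning, reaction knockouts, and concordance scoring against
    experimental growth, metabolomics, and expression data) on a built-in
    deterministic simplex solver; strain gene-presence/metabolite association
    with separability filtering and pathway enrichment; logistic growth-curve
    modeling; and seeded synthetic-data generators with ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
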