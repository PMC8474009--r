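Package: mrmassay
Title: Design and Quantitative Analysis of Targeted Phosphopeptide MRM Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for multiplexed phosphosite assays measured by
    multiple reaction monitoring (MRM) with stable-isotope-labeled internal
    standards. Builds a vetted phosphopeptide panel from a proteome and a
    phosphosite nomination list (in-silico tryptic digestion, length filters
    with missed-cleavage rescue, observation-evidence priority, peptide
    uniqueness and cross-species conservation checks), computes precursor and
    b/y fragment ion masses, ranks transitions from spectral libraries,
    generates collision-energy optimization schedules and retention-time
    scheduled method tables, assembles equimolar peptide mixtures, integrates
    MRM chromatograms into light/heavy peak-area ratios with detection-category
    rules, and runs downstream statistics: left-censored down-shifted normal
    imputation, empirical-Bayes moderated t-tests with Benjamini-Hochberg
    correction, one-way ANOVA with Tukey comparisons, robust median-MAD
    normalization and correlation-based sample clustering. A synthetic-data
    module generates proteomes, evidence tables, spectral libraries and
    chromatograms with known ground truth so the full pipeline can be
    exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
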