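Package: sidmeta
Title: Multilevel Phylogenetic Meta-Analysis of Sex Differences in Stable
    Isotope Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how sexual size dimorphism relates to sex
    differences in stable-isotope ratios (delta-15N, delta-13C) across
    vertebrates.  Builds raw mean difference, log variability ratio (lnVR)
    and log coefficient-of-variation ratio (lnCVR) effect sizes with
    sampling variances from per-sex summary statistics; fits multilevel
    random-effects meta-analytic and meta-regression models by REML or ML
    with study, species and phylogenetic random effects (Brownian-motion
    correlation from a Newick tree); decomposes heterogeneity (multilevel
    I-squared); compares moderator structures by AICc; and provides a
    publication-bias and sensitivity battery (funnel data, time-lag
    meta-regression, within-study-weight refits, leave-one-out Cook's
    distances) plus local Moran-type phylogenetic signal.  Includes a
    synthetic-data generator with a truth ledger for parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
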