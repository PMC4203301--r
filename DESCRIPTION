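Package: hfcsurv
Title: Heterozygosity-Fitness Correlations via Capture-Mark-Recapture Survival Models
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for testing heterozygosity-fitness correlations (HFCs) in
    wild populations monitored by annual capture-mark-recapture. Computes
    microsatellite-based multilocus heterozygosity measures (standardized
    heterozygosity, homozygosity by locus, internal relatedness), pedigree
    inbreeding coefficients with dataset-restriction rules, identity
    disequilibrium statistics (g2, heterozygosity-heterozygosity
    correlations, expected correlation between heterozygosity and
    inbreeding), and Cormack-Jolly-Seber survival models with bootstrap
    goodness of fit, QAICc model selection, and model averaging. Includes a
    seeded synthetic population generator (pedigree, genotypes with typing
    error, climate, capture histories) with known ground truth for
    validating every step, and an end-to-end pipeline mirroring a multistep
    reduced-model search followed by covariate HFC analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
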