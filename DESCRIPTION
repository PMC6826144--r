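Package: telomr
Title: Mendelian Randomization of Telomere Length Against Aging-Related Outcomes
Version: 0.1.0
Authors@R: person("telomr", "maintainers", email = "telomr@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization of genetically
    determined leukocyte telomere length against aging-related phenotypes in
    biobank-scale cohorts. Provides loading and validation of a telomere SNP
    instrument panel with its linkage-disequilibrium structure, unit
    conversions between standard deviations of telomere length, base pairs
    and years of attrition, a synthetic cohort simulator with LD-structured
    genotypes and calibrated outcome prevalences, derivation of aging
    phenotypes (parental lifespan contrasts, frailty indices, sarcopenia,
    Fried frailty, cognitive transforms), covariate-adjusted per-SNP
    association scans, correlated-instrument causal estimators
    (inverse-variance weighted, maximum likelihood, MR-Egger with intercept
    pleiotropy test), Benjamini-Hochberg false discovery rate control, and
    analytic power calculations for binary and continuous outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
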