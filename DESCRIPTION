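Package: radhet
Title: Reliability of Radiogenomic Heterogeneity Features in NSCLC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes genomic intratumor-heterogeneity features (tumor
    mutational burden, mutant-allele tumor heterogeneity and Shannon entropy
    of the variant-allele-fraction distribution) under alternative
    population-allele-frequency cutoffs for tumor-only somatic calling, and
    first-order glycolytic PET features (SUVmax, metabolic tumor volume,
    total lesion glycolysis, intensity entropy) under standard and reduced
    image matrix sizes. Quantifies feature reliability with the two-way
    random consistency intraclass correlation coefficient and relates
    features to clinical covariates via Pearson correlation, two-group
    tests and univariate Cox regression. Includes a seeded synthetic cohort
    generator (clonal VAF mixtures with germline contamination, textured
    SUV phantoms, linked survival outcomes) so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
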