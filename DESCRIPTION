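Package: selfscape
Title: Population Structure, Selfing and Isolation by Distance from Sparse SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for spatially referenced SNP genotype
    collections from highly selfing plants. Provides genotype quality
    control, haplogroup assignment by a modified QT clustering with a
    binomial mismatch-probability distance, per-field-site inbreeding
    coefficients (F_IS) with conversion to selfing rates and locus
    bootstrap confidence intervals, field-site haplogroup diversity,
    panmixia resampling of the pairwise mismatch distribution, and
    multi-scale isolation-by-distance analyses (same-haplogroup
    probability and mismatch quantiles per distance bin, linear and
    exponential curve fits, pairwise Weir-Cockerham F_ST against log
    distance with sliding-window slopes). Includes synthetic genotype
    and landscape generators at mixed-mating inbreeding equilibrium so
    that every estimator can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    minpack.lm,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
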