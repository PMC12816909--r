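Package: varscape
Title: Structural Feature Landscapes of Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Annotates missense variants with interpretable structural and
    biophysical binary features derived from AlphaFold-style monomeric protein
    models (pLDDT-based order/disorder, solvent accessibility and burial class,
    intramolecular contact density, secondary structure, catalytic-site
    overlap) together with substitution-chemistry and thresholded auxiliary
    features (conservation, folding-energy change, steric clashes). Feature
    landscapes of two variant datasets (e.g. clinically pathogenic versus
    high-frequency population variants) are compared feature-by-feature with
    two-tailed Fisher exact tests, odds ratios with Woolf 95% confidence
    intervals, Bonferroni correction, stratified analyses by protein class or
    disease category, and a z-scored log odds-ratio meta-analysis across
    dataset comparisons. Includes generators for synthetic protein backbones
    and variant cohorts with planted feature prevalences so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
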