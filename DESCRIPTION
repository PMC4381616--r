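Package: metspread
Title: Metastatic Progression Patterns Across Major Cancer Types
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for autopsy-registry studies of metastatic
    organotropism. Provides a patient-level registry data model with an
    inclusion-filter cascade, a seedable synthetic-registry generator built
    on a latent-Gaussian (copula) co-occurrence model, fractional and
    relative-risk association matrices with Fisher exact screening and
    Benjamini-Hochberg FDR control, stratified subgroup comparisons,
    primary-site prediction from metastasis profiles (per-primary logistic
    odds-ratio profiles and multinomial top-k cross-validation), Cox
    proportional-hazards analysis of total lifetime, and hierarchical
    clustering plus GraphML export of progression networks.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    survival,
    nnet,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
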