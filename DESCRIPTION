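Package: sourveyor
Title: Citizen-Science Sourdough Survey Harmonisation and Analysis
Version: 0.1.0
Authors@R:
    person("HealthFerm", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Harmonises multi-table citizen-science sourdough survey data
    (registration, at-home experiment results, laboratory measurements) into
    one analysis-ready table, then provides the statistical layer used to
    characterise pan-European sourdough baking practice: fold-enrichment
    scoring of categorical and numeric features across sample clusters with
    Benjamini-Hochberg FDR control and directional flagging, pairwise
    effect-size testing (Cramer's V, rank-biserial correlation, Cohen's d),
    mixed-type collinearity screening with representative-variable selection,
    check-all-that-apply (CATA) sensory ordination (Jaccard distances, PCoA,
    PERMANOVA, Mantel tests), and PCA of the numeric feature space with group
    confidence ellipses. A synthetic survey generator with a planted-effect
    registry makes every stage testable without access to the deposited data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    vegan,
    yaml
Config/testthat/edition: 3
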