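Package: herbnet
Title: Network Pharmacology of Multi-Ingredient Herbal Formulae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An integrative network-pharmacology pipeline for herbal
    formulae. Predicts per-ingredient target profiles by concordance
    between chemical-similarity vectors (drug space) and
    protein-interaction network closeness vectors (target space), clusters
    ingredients by principal component analysis of their target profiles,
    expands disease seed genes into a disease-specific interaction
    network, maps per-herb candidate targets into it, performs gene-set
    over-representation analysis with Benjamini-Hochberg control, and
    detects synergistic ingredient pairs through pathway feedback and
    compensation mechanisms on a curated directed signaling model. Ships
    a transcribed rheumatoid-arthritis worked example (the four-herb
    Qing-Luo-Yin formula) and synthetic-data generators for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    methods,
    tools,
    jsonlite,
    yaml,
    stats,
    utils,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
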