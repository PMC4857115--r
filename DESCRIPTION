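Package: herbscreen
Title: Ligand-Based Anti-Cancer Screening of Plant Compound Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An in-silico screening pipeline for plant-derived compound
    libraries. Scores compounds for anti-cancer activity with a
    frequency-weighted MACCS fingerprint similarity model and an empirical
    P-value, identifies plants enriched in predicted actives with a
    hypergeometric test under Bonferroni control, profiles predicted actives
    against staged anti-cancer drug panels at a Tanimoto threshold, computes
    Lipinski-style property and fragment-frequency summaries, and builds a
    bipartite plant-drug similarity network exportable to Cytoscape formats.
    Ships a scaffold-decoration generator that emits plant-annotated
    synthetic libraries with known ground truth so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
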