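Package: rel2graph
Title: Relational-to-Graph Schema Transformation and Cohort Analytics for
    Clinical Diagnostics Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms a relational database schema into a labeled property
    graph model via an intermediate attribute-level schema graph (sink, source
    and hub rewriting), applies use-case refinements (entity absorption with
    subtype labels, hierarchy merges, key-value field promotion into shared
    nodes), migrates relational instance data into the derived graph, and
    exports it as GraphML, Cypher MERGE scripts or bulk-import CSV. On top of
    the migrated graph it implements the cohort analytics behind a pediatric
    acute lymphoblastic leukemia dashboard: grouped distributions, gene-fusion
    subgroup selection with alias resolution, per-patient neighborhood
    subgraphs, and Jaccard patient similarity. A seeded synthetic cohort
    generator emulates the source database so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
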