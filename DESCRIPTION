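Package: beltway
Title: Harmonize KEGG, Reactome and WikiPathways Pathways into Unified BEL-Style Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts pathway descriptions from KEGG (KGML), WikiPathways
    (GPML) and Reactome (BioPAX Level 3, RDF/XML) into a single unified
    directed multigraph model in the style of the Biological Expression
    Language (BEL), with identifier normalization through a configurable
    namespace priority cascade and cross-reference mapping tables.
    Provides comparative analytics over the harmonized graphs: the
    Szymkiewicz-Simpson overlap coefficient, a three-way pathway
    similarity index, per-modality shared/partial/exclusive overlap
    ratios, provenance-aware merging, group-node flattening,
    gene-level collapsing, and consensus/contradiction detection
    between databases. Graphs are exported to BEL script, GraphML and
    node-link JSON, and a synthetic fixture generator emits KGML, GPML
    and BioPAX file trios with controlled entity overlap for offline
    testing. A command-line interface mirrors the library functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    igraph,
    stats,
    tibble,
    tools,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
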