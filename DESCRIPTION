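Package: flowContrast
Title: Phenotype-Contrast Information-Flow Analysis of Protein-Protein
    Interaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds phenotype-specific capacitated flow networks by overlaying
    co-expression weights on a protein-protein interactome, routes information
    flow from differentially expressed source genes with an exact integer
    minimum-cost maximum-flow solver, and contrasts the two phenotypes to
    classify genes as sources, routers or targets, score network rewiring
    impact, and flag key edges. Includes exact hypergeometric
    over-representation analysis with Benjamini-Hochberg correction, CRISPR/
    RNAi gene-dependency integration, multi-network gene-set intersection and
    average-linkage clustering of flow profiles, and a seeded synthetic-data
    generator with planted differential structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    ape,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
biocViews: Network, GraphAndNetwork, GeneExpression, NetworkInference,
    Pathways
RoxygenNote: 7.3.3
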