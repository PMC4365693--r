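Package: cyanopan
Title: Pan-Genome, Phenotype and Outer-Membrane Proteome Analysis of
    Cyanobacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ortholog-cluster (CLOG) based core/pan-genome analysis for
    cyanobacterial genome collections: CLOG classification into core,
    dispensable and unique gene clusters; core- and pan-genome rarefaction by
    repeated random genome subsampling with Heaps-law (open pan-genome)
    exponent estimation; a Tanimoto-like phenotype similarity index over
    subcategory bit strings with explicit unknown handling; neighbor-joining
    trees from CLOG, feature, amino-acid-identity and alignment p-distances
    with patristic-distance tree correlation; feature-specific signature-gene
    mining with an outgroup homology specificity filter; consensus
    categorization of beta-barrel outer-membrane proteins from predictor,
    profile-HMM and Pfam-coverage evidence; and COG-category profiling of
    nested clade core-genomes. Includes synthetic-data generators with known
    ground truth for every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
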