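Package: OrthoCensus
Title: Orthogroup Identification and Gene-Duplication Census on a Species Tree
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A semiautomated orthology-identification pipeline for
    multi-species gene families: screening of precomputed similarity hits,
    protein-guided codon alignment preparation with gap-based column
    trimming and a relative-length filter, neighbor-joining gene trees
    under the TN93 nucleotide substitution model with nonparametric
    bootstrap, duplication-loss parsimony rooting and rearrangement of
    weakly supported nodes against a reference species tree, bootstrap
    acceptance of orthogroups at a key node, and a lineage-resolved census
    of orthologs and gene-duplication events. Includes a birth-death
    gene-family simulator with codon-structured sequence evolution so the
    whole pipeline can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape (>= 5.0),
    phangorn,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Phylogenetics, Alignment, ComparativeGenomics, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'OrthoCensus-package.R'
    'alignment-prep.R'
    'phylo-core.R'
    'reconciler.R'
    'census.R'
    'homology-screen.R'
    'nj-engine.R'
    'pipeline.R'
    'simulate.R'
    'tree-utils.R'
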