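Package: gvtax
Title: Taxonomic Classification of Giant Virus Genomes from Protein
    Family Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns metagenome-assembled genomes of giant viruses
    (phylum Nucleocytoviricota) to taxonomic order and family with
    random-forest classifiers trained on binary presence/absence
    profiles of giant virus orthologous groups (GVOGs) plus GC
    content. Provides the full training workflow (HMMER tblout
    featurization, order-prevalence feature screening, recursive
    feature elimination, permutation and impurity importance under
    collinearity clustering, randomized-then-grid hyperparameter
    search with stratified nested cross-validation), a genome
    fragmentation simulator for augmenting training sets with
    incomplete genome variants, evaluation reports (per-class
    precision/recall/F1, normalized confusion matrices), a one-way
    average amino acid identity (AAI) best-match module, and a
    synthetic-fixture generator for end-to-end testing without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    ranger,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
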