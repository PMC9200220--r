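Package: dfscreen
Title: Structure-Free Virtual Screening with a Densely Connected
    Protein-Ligand Binding Classifier
Version: 0.1.0
Authors@R:
    person("dfscreen", "maintainers", email = "dfscreen@example.org",
           role = c("aut", "cre"))
Description: A structure-free virtual-screening toolkit. Molecules and
    binding pockets are encoded as Morgan-substructure sentences and
    embedded into fixed 300-dimensional vectors with a word2vec-style
    skip-gram model; a densely connected feed-forward classifier (with a
    1-D convolutional alternative) scores concatenated pocket-ligand
    vectors as binding probabilities; a streaming engine ranks compound
    libraries, applies score cutoffs, top-fraction selection and Lipinski
    drug-likeness filtering; evaluation utilities compute rank AUC,
    confusion-matrix metrics, recall at top-k% and prediction-random
    enrichment ratios; high-scoring hits are grouped by hierarchical
    Tanimoto clustering of circular fingerprints. Includes synthetic-data
    generators (planted-signal binding worlds, toy PDB complexes,
    fragment-grammar SMILES libraries) that provide ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
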