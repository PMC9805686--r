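Package: phenoverlap
Title: Phenotype and Disease Enrichment with Overlap Scores for Gene Set
    Comparison
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Phenotype-level and disease-level annotation of gene sets
    against flat gene-term association databases (Human Phenotype Ontology
    style, Mammalian Phenotype style, curated gene-disease tables, CRISPR
    screen hit tables). Implements exact hypergeometric enrichment with
    Bonferroni and Benjamini-Hochberg correction, the Phenotypic Overlap
    Ratio (POR) between two gene sets under the Jaccard index or the
    Forbes-Alroy similarity coefficient, randomization-based empirical
    significance of the POR in overlapping and conditional modes, a relaxed
    variant over all annotated terms (RPOR), differential-phenotype
    detection, and a relevance regression over shared terms. Ships a
    seed-deterministic synthetic annotation-database generator and the two
    calibration experiments built on it: a type-I-error grid over random
    gene sets and a POR sensitivity study on artificial gene-set mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
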