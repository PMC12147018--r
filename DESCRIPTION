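Package: dynlca
Title: Sample-Tailored Minimizer-LCA Metagenomic Read Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A minimizer-based lowest-common-ancestor (LCA) taxonomic read
    classifier for shotgun metagenomes, in the style of Kraken 2 but storing
    unhashed minimizer keys, together with a two-step classification mode
    that tailors the reference library to the sample: a first pass against a
    large static library detects the species present (by a pooled read-count
    cutoff, or a gold-standard taxon set), a smaller dynamic library is
    rebuilt from only those species' genomes, and all reads are classified
    again against it. Includes an NCBI-dialect taxonomy parser with LCA and
    rank arithmetic, canonical spaced-seed minimizer extraction, Kraken-
    compatible per-read output and report writers, per-read and sample-level
    evaluation metrics (TP/VP/FP/FN categories, read index and soft index,
    taxon-set precision/recall, read-profile distances), and a synthetic
    community generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    Biostrings,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
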