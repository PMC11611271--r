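Package: foldscan
Title: Sort-Seq Foldability Analysis and Design of Constrained-Peptide
    Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of shotgun alanine-scan sort-seq experiments on
    disulfide-constrained peptide scaffolds. Turns UMI-tagged amplicon
    reads into deduplicated protein count tables, computes per-residue
    Enrichment Scores from pre- and post-sort frequencies, labels
    sequences by foldability from normalized count ratios, trains a
    compact self-attention classifier under leave-one-scaffold-out
    cross-validation, attributes per-residue importance with Integrated
    Gradients, calls non-touchable residues, and audits or designs
    degenerate-codon combinatorial libraries. Ships a fully seeded
    synthetic sort-seq simulator with planted ground truth so the whole
    pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
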