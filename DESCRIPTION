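Package: nifscan
Title: In-Silico Prediction of Diazotrophy from Prokaryotic Genomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens annotated prokaryotic genomes for nitrogen-fixation (nif)
    gene families by protein homology and predicts diazotrophy with a
    six-gene minimum-gene-set criterion (nifH, nifD, nifK, nifE, nifN, nifB)
    supported by gene-neighbourhood (synteny) evidence. Maps D-subunit
    sequences onto Azotobacter vinelandii NifD numbering to profile FeMo-cofactor
    and P-cluster ligands, classifies NifD subfamilies (conventional, group C,
    alternative-nitrogenase V group), distinguishes Mo-, V- and Fe-dependent
    systems via the extra G subunit, and triages divergent nitrogenase-like
    sequences (DPOR homolog removal, NifH-NifD/E fusion detection, single-subunit
    NflD, adjacent alpha/beta pairs with ligand classes). Includes a seeded
    synthetic-genome simulator that provides ground-truth fixtures for every
    analysis step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    withr,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
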