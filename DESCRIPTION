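Package: pubtcr
Title: Public T Cell Receptor Clonotype Discovery from Immune Repertoire Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for T cell receptor (TCR) beta-chain repertoire analysis aimed
    at discovering public, condition-specific clonotypes: CDR3 junction extraction
    from nucleotide reads using the conserved Y[YFLI]C and [FW]GXGT anchor motifs,
    clonotype tabulation with AIRR-style input/output, V-J gene usage and pairing
    statistics with cohort normalization and PCA, cross-sample public-clonotype
    detection with configurable case/control thresholds, single-residue CDR3
    clustering, single-cell alpha/beta chain pairing summaries with a phenotypic
    gene panel, and a seedable cohort simulator with planted spike-in clonotypes
    providing ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
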