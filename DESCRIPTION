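Package: epibeam
Title: Epitope-Constrained Beam-Search Protein Sequence Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constrained beam-search decoding for autoregressive protein
    sequence models that guarantees every k-mer (up to length 10) of a
    designed sequence is either present in a reference proteome ("self")
    or predicted not to be presented by a patient's MHC class I alleles
    ("hidden"). Includes an exact proteome k-mer membership index, a fast
    position-weight-matrix (PWM) surrogate classifier for MHC-I peptide
    presentation with quantile-calibrated thresholds, permissibility rules
    and the lookahead beam-search decoder itself, sequence-level
    immunogenicity metrics (self-kmer fractions, presented non-self
    fraction, ungapped BLOSUM62 dissimilarity to the proteome), allele
    presentation-profile distances with max-min alternative genotype
    selection, and seeded generators for synthetic proteomes, anchored
    alleles and toy sequence models so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rlang,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
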