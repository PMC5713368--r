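Package: seqvec
Title: Fixed-Length Numeric Descriptors for Biological Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts variable-length DNA, RNA, protein, or user-defined
    alphabet sequences into fixed-length numeric descriptor vectors for
    machine learning: k-mer compositions, pseudo-amino-acid and pseudo
    k-tuple nucleotide compositions (Type-1 parallel and Type-2 series
    correlation), autocorrelation and cross-covariance descriptors (AC, CC,
    ACC, Moran, Geary, normalized Moreau-Broto), distance-pair frequencies,
    and one-hot encodings. Includes a multi-line FASTA parser with automatic
    header-dialect recognition for UniProt, GenBank, EMBL, DDBJ and RefSeq,
    a configurable skip-or-abort data-fault policy, physicochemical property
    tables with pre-computed pairwise correlation matrices, a runtime
    extension system for registering new sequence types, properties and
    modes, and libSVM/TSV/CSV result writers with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools
Suggests: testthat (>= 3.0.0), withr, Biostrings, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
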