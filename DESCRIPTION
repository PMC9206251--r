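Package: privgst
Title: Privacy-Preserving String Queries on Genomic Data via Generalized Suffix Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds generalized suffix trees (GSTs) over haplotype or nucleotide
    datasets, in serial or in parallel under horizontal, vertical and
    bi-directional data partitioning with path-graph extension and duplicate-free
    merging. The GST is outsourced to an untrusted server under a top-down
    (reverse-Merkle) salted hash of every node, deterministic AES-CBC encryption
    of the digests, and a fixed-depth bitwise hash index over the ciphertexts.
    Four string queries (exact match, exact substring match, set-maximal match
    and its thresholded variant) run against the encrypted index in a two-role
    researcher/server protocol, optionally through a bitwise XNOR
    garbled-circuit walk that hides the researcher's query bits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    openssl,
    jsonlite,
    parallel,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
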