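# privgst

Privacy-preserving string queries on genomic data via generalized suffix
trees.

## The problem

A data owner holds an *n* × *m* haplotype matrix **D** — one row per
participant sequence *s<sub>i</sub>* ∈ {0,1}<sup>m</sup> (bi-allelic SNP
values; nucleotide alphabets are also supported) — and wants a cloud server
to answer researchers' string queries *q* (1 ≤ |q| ≤ m) without the server
ever learning the sequences. Four query kinds are supported:

* **EM** (exact match): records equal to *q* over the full width;
* **ESM** (exact substring match): records containing *q* contiguously,
  with every occurrence span (j₁, j₂);
* **SMM** (set-maximal match): per record, its longest non-extensible
  substring shared with *q*, subject to a minimum-length floor
  (default ⌈(|q|+1)/2⌉);
* **TSMM**: SMM with an explicit length threshold *t*.

## How it works

1. **Generalized suffix tree.** The owner indexes every suffix of every
   record in a GST, built serially (per-suffix trie insertion, or Ukkonen's
   amortized-linear algorithm) or in parallel: the matrix is partitioned
   horizontally, vertically, or both ways; blocks are built concurrently;
   column-truncated blocks are completed with per-sequence *path graphs*
   (linear chains spelling the column tail); and block trees are merged
   duplicate-free, exchanging serialized tree files exactly as distributed
   workers would.
2. **Reverse-Merkle hashing.** Digests flow top-down: the root holds a
   secret SALT, and each node's digest is
   *h*(parent ∥ *h*(symbol)) — so for a query string
   *Q<sub>h</sub>* = *h*(… *h*(*h*(SALT ∥ *h*(q₁)) ∥ *h*(q₂)) …), any party
   holding the salt can recompute the digest of any path without the tree.
   MD5 (k = 128 bits) by default; SHA-256 selectable.
3. **Deterministic encryption + hash index.** Every digest is AES-CBC
   encrypted under a fixed key/IV (deterministic, size-preserving), and the
   server builds a binary index of logical depth k over the ciphertext
   bits. Queries become single ciphertext lookups; the server sees tokens,
   never symbols. Matched leaves return opaque (sequence, start) reference
   tokens only the researcher can decrypt.
4. **Oblivious walk (optional).** The researcher's token bits can be
   matched one per round through an XNOR garbled circuit so the server
   never sees the query bits either; a hit takes exactly k rounds.

## Worked example

The 5 × 6 example matrix (rows `100010`, `111010`, `110001`, `010110`,
`010101`) ships with the package:

```r
library(privgst)
d <- example_dataset()
keys <- make_keys(seed = 1)                 # salt + AES key/IV (owner & researcher)
server <- outsource(build_trie(d), keys)    # what the cloud server holds
server
#> server_bundle: encrypted tree (62 nodes), index (61 entries, k=128)

execute_query(server, make_query_tokens("1011", "tsmm", t = 3, keys = keys))
#> query_result (TSMM): hit, 4 match span(s)
#>  seq j1 j2 length match
#>    2  3  5      3   101
#>    4  2  5      4  1011
#>    5  2  4      3   101
#>    5  4  6      3   101
```

Read: records 2, 4 and 5 share a substring of length ≥ 3 with query
`1011`; record 2's maximal match (`101`) starts at position 3, record 4
contains the whole query from position 2, and record 5 matches `101`
twice. Every answer equals a plaintext scan of the definitions
(`plaintext_oracle()`), but is computed entirely on the encrypted index.

The same flows run from a shell via `inst/cli/privgst.R`
(`generate`, `build`, `keygen`, `outsource`, `query`, `selftest`
subcommands), with secrets passed by keyfile, never on the command line.

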