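---
title: "Secure suffix-tree queries: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Secure suffix-tree queries: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privgst)
```

## The model

Three parties with asymmetric trust. The **data owner** holds an
$n \times m$ record matrix $D$ over a small alphabet $\Sigma$ (bi-allelic
haplotypes $\{0,1\}$ or nucleotides $\{A,C,G,T\}$) and performs a one-time
preprocessing. The **cloud server** stores the result and answers queries
but is only *semi-honest*: it follows the protocol yet may inspect
everything it receives, and a breach of its storage must not reveal the
sequences. The **researcher** shares secrets with the owner (never with the
server) and issues string queries $q$, $1 \le |q| \le m$.

The owner's preprocessing chains four steps, each of which is an exported
function so every trust boundary is testable in isolation:

1. **Indexing.** A generalized suffix tree over all suffixes of all
   records. The uncompressed trie (one symbol per edge) is the canonical
   logical form, because the hashing step assigns one digest per
   single-symbol node; the Ukkonen builder produces the compressed form and
   exposes a per-symbol expansion (`expand_to_trie()`) that must be
   node-for-node equal to the trie builder. Suffix ends carry a reserved
   terminal class `"$"` whose node stores the `(sequence, start)`
   references; the bare terminal (the empty suffix) is not stored, so a
   record of length $m$ contributes exactly $m$ terminal-marked leaves.
2. **Reverse-Merkle hashing** (`hash_tree()`). Top-down digest chaining:
   the root digest is the secret salt; each child is
   $H(\text{parent} \,\|\, H(\text{symbol}))$. A node's digest therefore
   depends only on the salt and its root path — two trees sharing a path
   share that digest — which is precisely what lets the researcher rebuild
   any path digest from the query string alone.
3. **Deterministic encryption** (`encrypt_tree()`). AES-CBC under a fixed
   key and IV. Determinism is a *requirement* here (searchability), and a
   deliberate leak: equal digests yield equal ciphertexts, an ECB-like
   property the design accepts because digests are already salted and the
   server never holds key, IV, or salt. Ciphertext length equals digest
   length (whole-block CBC; the PKCS#7 pad block is dropped), so
   encryption adds no storage.
4. **Bitwise hash index** (`build_hash_index()`). A binary tree of fixed
   logical depth $k$ over ciphertext bits, one entry per tree node
   (internal nodes included — substring queries terminate mid-tree), each
   entry referencing the suffix positions reachable through that node as
   opaque researcher-decryptable tokens.

Queries reduce to digest lookups. Exact match folds the terminal class
into the digest, so only complete suffixes (and for $|q| = m$, only whole
records) can answer it; substring-style queries use the bare path digest
and may land on internal entries. The set-maximal kinds enumerate the
substrings of $q$ longest-first down to a floor and keep each record's
first (longest) hit; the researcher-side aggregation decrypts the
reference tokens and assembles per-record maximal spans.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `hash_fn` | `"md5"` (k = 128 bits) | digest and index depth; `"sha256"` switches k to 256 everywhere |
| salt / key / IV | random (k/8, 16, 16 bytes) | shared owner↔researcher; fixed per deployment |
| SMM floor (`min_match`) | ⌈(\|q\|+1)/2⌉ | smallest reportable match; the default is the smallest rule that keeps a record whose best share is barely over half the query while excluding sub-half noise matches |
| `t` (TSMM) | — | explicit floor, 1 ≤ t ≤ \|q\|; interpreted as match *length* |
| `scheme`, `workers` | `horizontal`, 1 | partitioning geometry and block-build concurrency |
| `gc_backend`, `gc_seed` | `simulated` | oblivious-walk gate realization and transcript reproducibility |

## Parallel construction choices

Blocks are contiguous and balanced (sizes differ by at most one row or
column). The bi-directional scheme needs $p \ge 4$ factorable into a
$p_r \times p_c$ grid with both factors $\ge 2$; the factorization closest
to a square is chosen deterministically. Workers exchange *serialized tree
files* through a spool directory even when running in one process — the
point is to preserve the distributed-memory architecture's contract, not
to win wall-clock time on one box. Column-truncated blocks mark their
suffix ends *pending* and are completed by path graphs spanning all
remaining columns; with more than two vertical blocks this is equivalent
to the right-to-left chaining of already-extended tails, and is how the
merge order for many vertical blocks (which the architecture leaves open)
is fixed here. Merging is a structural union with references unioned and
sibling symbols kept unique; it is associative and commutative up to
canonical form, so the binary-reduction schedule over adjacent worker
pairs is just one valid order. Merges run sequentially in-process; the
root-branch split that would let separate cores take the `0` and `1`
subtrees is a correctness-neutral scheduling detail and is not exposed as
a knob.

Canonical equality (`gst_equal()`) — children ordered by symbol, nodes
renumbered in preorder, reference rows sorted — is the equality surface
for all of this: the parallel ≡ serial property is asserted over random
datasets with $n, m \in [8, 32]$ for every scheme × $p \in \{1,2,4,8\}$
(30 datasets; bi-directional skips $p < 4$ by precondition).

## Numerical and encoding choices

The hashing scheme fixes shapes, not byte encodings, so these are pinned
for bit-exact reproducibility: $H(x \| y)$ hashes the raw concatenation of
the two byte strings; a symbol hashes as its one-byte ASCII encoding; the
terminal folds as the single byte `"$"`. The `(sequence, start)` positions
ride as node metadata rather than inside the digest — folding them in
would make leaf digests impossible for a researcher to reconstruct (the
researcher knows the query symbols, not where they live in the dataset).
Digest bits are big-endian within bytes, stable across platforms. The
salt's length equals the digest length. Degenerate inputs are contracts,
not surprises: empty row sets, ragged rows, mixed alphabets, out-of-range
plants, `"$"` in queries, and wrong-length keys or tokens all raise typed
errors; a keyfile from the wrong lineage simply misses everywhere, which
is indistinguishable from absence by design.

## The oblivious walk

The plain lookup reveals the query token to the server. With
`oblivious = TRUE` the index walk runs as a fixed-round two-party
protocol: per round the server picks one of the current node's children at
random (a lone child is functionally forced and tried first — the
protocol leaves this case open and this is the only choice that costs no
extra round), a single XNOR gate compares the child's bit with the
researcher's query bit, and only the equality bit reaches the server,
which then advances, takes the sibling, or stops. A hit takes exactly $k$
rounds; transcripts contain fixed-size wire labels and never a plaintext
bit. Two backends share the interface: the default `simulated` broker is
functionally faithful but *not* cryptographically secure — it exists so
protocol-flow properties (round counts, outcomes, functional equivalence
with `hi_lookup()`) can be tested cheaply — while `garbled` actually
garbles the gate (four hash-encrypted rows under random wire labels, an
oblivious-transfer abstraction for the evaluator's label, exactly one row
decrypting). A whole-query, non-iterative circuit variant is deliberately
absent: matching all $k$ bits inside one circuit removes the per-round
leakage but is not computationally practical, and the iterative protocol
is the one specified round structure.

## What the synthetic generator does and does not emulate

`generate_synthetic()` draws uniform i.i.d. symbols (the distribution of
the randomized benchmark datasets is not stated anywhere authoritative;
uniform is assumed and documented), with optional verbatim planted
substrings to guarantee query hits. Real haplotype panels are *not*
i.i.d. — linkage disequilibrium correlates nearby columns and allele
frequencies are skewed — so passing tests demonstrate correctness of the
algorithms and protocols, not statistical realism of match lengths: on
real data set-maximal matches run longer than on uniform noise, which
affects performance profiles, never answers.

## Problem sizes used by the test suite

Sizes are chosen so the full suite exercises every code path at
exhaustively checkable scale: parallel ≡ serial on 30 random datasets up
to 32 × 32 across all schemes and worker counts; secure ≡ plaintext on
500 random (dataset, query, kind) triples over 25 datasets of 10–20 rows
and columns, plus 50 triples through the oblivious path on 6–10-sized
datasets; per-node digest verification against an independently written
fold oracle on a 4 × 8 dataset (every node); and the worked 5 × 6 example
throughout. The example matrix pipeline produces a 62-node tree and a
61-entry index in milliseconds.

## Known limitations

* The index walk is $O(k)$ bit steps, not $O(\log k)$: a fixed-depth
  bit-walk must touch every bit. The per-query cost is still independent
  of $n$, $m$ and $|q|$ once tokens are built, which is the property that
  matters.
* Deterministic encryption leaks digest equality between server-side
  entries and across queries; per-depth keys or randomized encryption
  would remove it at the cost of searchability or size.
* The researcher is trusted with salt, key and IV; malicious-researcher
  defenses (output perturbation, differential privacy) are out of scope.
* Result privacy is not attempted: the server learns which entries hit,
  except under the oblivious walk, which still reveals hit/miss timing.
* Single-machine emulation only: worker processes and spool files stand in
  for a real cluster; no network transport, no fault tolerance beyond
  aborting on a failed block.
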