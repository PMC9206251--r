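#' Reverse-Merkle (top-down) hashing of suffix trees
#'
#' Classic Merkle trees hash bottom-up; here digests flow top-down. The root
#' holds a secret random SALT (never shipped to the server). Every child's
#' digest is `H(parent_digest || H(child_symbol))`, so a node's digest
#' depends only on the salt and the root-to-node symbol path — which is what
#' makes a researcher able to recompute the digest of any query string
#' without seeing the tree. MD5 (k = 128 bits) is the default; SHA-256
#' (k = 256) is selectable and changes `k` everywhere consistently.
#'
#' Byte-level pinning (the scheme fixes shapes, not encodings, so these are
#' frozen here for bit-exact reproducibility): `H(x || y)` hashes the raw
#' concatenation of the two byte strings; a single symbol hashes as its
#' one-byte ASCII encoding; the terminal class folds as the byte `"$"`. The
#' `(sequence, start)` positions of suffixes ride as node metadata, not
#' inside the digest, so queries need only the symbols.
#'
#' @name rmt
NULL

HASH_FNS <- list(md5 = list(fn = function(x) openssl::md5(x), k = 128L),
                 sha256 = list(fn = function(x) openssl::sha256(x), k = 256L))

hash_spec <- function(hash_fn) {
  if (!hash_fn %in% names(HASH_FNS)) {
    stop(sprintf("unsupported hash function '%s' (use md5 or sha256)", hash_fn))
  }
  HASH_FNS[[hash_fn]]
}

#' Generate a random salt
#'
#' Cryptographically random byte array of the digest length (k/8 bytes),
#' seeding the RMT root. Shared owner-to-researcher, withheld from the
#' server.
#'
#' @param hash_fn `"md5"` or `"sha256"`.
#' @return raw vector of k/8 bytes.
#' @export
rmt_salt <- function(hash_fn = "md5") {
  openssl::rand_bytes(hash_spec(hash_fn)$k %/% 8L)
}

# one chaining step: H(parent_digest || H(symbol))
rmt_step <- function(d, sym_raw, H) {
  as.raw(H(c(d, as.raw(H(sym_raw)))))
}

#' Reverse-Merkle digest of a string
#'
#' Folds the symbols left to right: `d0 = salt`,
#' `d_i = H(d_{i-1} || H(s_i))`; returns `d_|s|`. With `terminal = TRUE`
#' the terminal class byte `"$"` is folded after the last symbol (the form
#' stored on suffix-ending leaves and used by exact-match query tokens).
#'
#' @param s character string over the data alphabet (or character vector of
#'   single symbols).
#' @param salt raw vector of k/8 bytes.
#' @param hash_fn `"md5"` or `"sha256"`.
#' @param terminal fold the terminal marker after the symbols?
#' @return raw digest of k/8 bytes.
#' @export
rmt_hash_string <- function(s, salt, hash_fn = "md5", terminal = FALSE) {
  spec <- hash_spec(hash_fn)
  stopifnot(is.raw(salt), length(salt) == spec$k %/% 8L)
  syms <- if (length(s) == 1L && nchar(s) != 1L) strsplit(s, "")[[1L]] else s
  if (length(syms) < 1L || (length(syms) == 1L && !nzchar(syms))) {
    stop("string to hash must have at least one symbol")
  }
  if (any(syms == TERM)) stop("alphabet error: '$' is reserved for the terminal marker")
  if (any(nchar(syms) != 1L)) stop("symbols must be single characters")
  d <- salt
  for (sym in syms) d <- rmt_step(d, charToRaw(sym), spec$fn)
  if (terminal) d <- rmt_step(d, charToRaw(TERM), spec$fn)
  d
}

#' Hash a whole GST top-down into a reverse-Merkle tree
#'
#' Mirrors the trie: the root digest is the salt itself; each child's digest
#' chains one symbol. Terminal (`"$"`) nodes additionally carry their
#' `(sequence, start)` references. Leaf digests are also exported as a flat
#' table for query-time matching.
#'
#' @param gst a `gst` in trie form (compressed trees are expanded).
#' @param salt raw salt from [rmt_salt()].
#' @param hash_fn `"md5"` or `"sha256"`.
#' @return an `rmtree`: the gst topology plus `digest` (list of raw
#'   vectors), `hash_fn`, `k`, and `leaves` (data.frame `node`, `seq`,
#'   `start`, `digest` hex).
#' @export
hash_tree <- function(gst, salt, hash_fn = "md5") {
  g <- as_trie(gst)
  spec <- hash_spec(hash_fn)
  stopifnot(is.raw(salt), length(salt) == spec$k %/% 8L)
  n <- g$n_nodes
  digest <- vector("list", n)
  digest[[1L]] <- salt
  # parents precede children in creation order? not guaranteed after merge —
  # walk in BFS order from the root instead
  ord <- integer(n); ord[1L] <- 1L; head <- 1L; cnt <- 1L
  while (head <= cnt) {
    node <- ord[head]; head <- head + 1L
    for (ch in g$children[[node]]) { cnt <- cnt + 1L; ord[cnt] <- ch }
  }
  sym_raw <- lapply(g$symbol, function(s) if (is.na(s)) NULL else charToRaw(s))
  for (i in ord[-1L]) {
    digest[[i]] <- rmt_step(digest[[g$parent[i]]], sym_raw[[i]], spec$fn)
  }
  leaf_nodes <- which(!vapply(g$refs, is.null, logical(1)))
  leaves <- do.call(rbind, lapply(leaf_nodes, function(i) {
    data.frame(node = i, seq = g$refs[[i]][, 1L], start = g$refs[[i]][, 2L],
               digest = paste(digest[[i]], collapse = ""), stringsAsFactors = FALSE)
  }))
  structure(
    list(symbol = g$symbol, parent = g$parent, children = g$children,
         refs = g$refs, digest = digest, n_nodes = n,
         hash_fn = hash_fn, k = spec$k,
         leaves = if (is.null(leaves)) data.frame() else leaves,
         n_seq = g$n_seq, m = g$m, alphabet = g$alphabet, span = g$span),
    class = "rmtree"
  )
}

#' @export
print.rmtree <- function(x, ...) {
  cat(sprintf("rmtree: %d nodes hashed with %s (k=%d bits), %d suffix leaves\n",
              x$n_nodes, x$hash_fn, x$k, nrow(x$leaves)))
  invisible(x)
}

#' Digest bits in stable big-endian order
#'
#' Most-significant bit of the first byte first; stable across platforms,
#' round-trips through [bits_to_raw()].
#'
#' @param digest raw vector.
#' @return integer vector of 0/1 of length `8 * length(digest)`.
#' @export
digest_bits <- function(digest) {
  stopifnot(is.raw(digest))
  bits <- matrix(as.integer(rawToBits(digest)), nrow = 8L)  # little-endian per byte
  as.integer(bits[8:1, ])
}

#' @rdname digest_bits
#' @param bits integer 0/1 vector, length a multiple of 8.
#' @export
bits_to_raw <- function(bits) {
  stopifnot(length(bits) %% 8L == 0L)
  m <- matrix(as.integer(bits), nrow = 8L)
  as.raw(colSums(m * 2L^(7:0)))
}
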