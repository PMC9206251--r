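#' Encryption context for searchable determinism
#'
#' AES-CBC with a 128-bit key and a FIXED initialization vector per
#' deployment. Fixing the IV is what makes equal digests encrypt to equal
#' ciphertexts, so the researcher can reproduce server-side ciphertexts —
#' and it is also a deliberate, ECB-like determinism leak: anyone holding
#' two ciphertexts learns whether the underlying digests were equal. The
#' scheme accepts this by design (the digests are already salted); see the
#' package vignette's security notes. Key and IV are shared
#' owner-to-researcher and withheld from the server.
#'
#' @param key raw 16-byte AES-128 key.
#' @param iv raw 16-byte initialization vector.
#' @return an `encryption_context`.
#' @export
encryption_context <- function(key, iv) {
  if (!is.raw(key) || length(key) != 16L) stop("key must be 16 raw bytes (AES-128)")
  if (!is.raw(iv) || length(iv) != 16L) stop("iv must be 16 raw bytes")
  structure(list(key = key, iv = iv, cipher = "aes-128-cbc"),
            class = "encryption_context")
}

# CBC of whole blocks without padding expansion: PKCS#7 always appends a
# full pad block for block-aligned input, so dropping the trailing block
# leaves exactly the unpadded CBC ciphertext. Digests are block-aligned
# (16B for MD5, 32B for SHA-256), hence ciphertext length == digest length.
encrypt_digest <- function(d, ctx) {
  stopifnot(is.raw(d), length(d) %% 16L == 0L)
  ct <- openssl::aes_cbc_encrypt(d, key = ctx$key, iv = ctx$iv)
  ct[seq_along(d)]
}

# suffix references travel as opaque AES tokens ("seq:start", padded CBC);
# the server stores and returns them but cannot read them
encrypt_ref <- function(seq, start, ctx) {
  raw_to_hex(openssl::aes_cbc_encrypt(charToRaw(sprintf("%d:%d", seq, start)),
                                      key = ctx$key, iv = ctx$iv))
}

decrypt_ref <- function(token_hex, ctx) {
  pt <- openssl::aes_cbc_decrypt(hex_to_raw(token_hex), key = ctx$key, iv = ctx$iv)
  as.integer(strsplit(rawToChar(pt), ":", fixed = TRUE)[[1L]])
}

raw_to_hex <- function(r) paste(r, collapse = "")
hex_to_raw <- function(h) {
  n <- nchar(h) %/% 2L
  as.raw(strtoi(substring(h, 2L * seq_len(n) - 1L, 2L * seq_len(n)), 16L))
}

#' Encrypt a reverse-Merkle tree for outsourcing
#'
#' Produces the server-side tree: same topology, every node value replaced
#' by the deterministic AES ciphertext of its digest, all plaintext symbols
#' and the salt removed. The root (whose digest IS the salt) carries no
#' value at all. Suffix references become opaque researcher-decryptable
#' tokens.
#'
#' @param rmtree an `rmtree` from [hash_tree()].
#' @param ctx an [encryption_context()].
#' @return an `encrypted_gst`: `parent`, `value` (hex, `NA` for root),
#'   `ref_tokens` (per-node list), `n_nodes`, `k`, `cipher`.
#' @export
encrypt_tree <- function(rmtree, ctx) {
  stopifnot(inherits(rmtree, "rmtree"), inherits(ctx, "encryption_context"))
  n <- rmtree$n_nodes
  value <- rep(NA_character_, n)
  for (i in seq_len(n)[-1L]) {
    value[i] <- raw_to_hex(encrypt_digest(rmtree$digest[[i]], ctx))
  }
  ref_tokens <- vector("list", n)
  for (i in which(!vapply(rmtree$refs, is.null, logical(1)))) {
    mat <- rmtree$refs[[i]]
    ref_tokens[[i]] <- vapply(seq_len(nrow(mat)),
                              function(j) encrypt_ref(mat[j, 1L], mat[j, 2L], ctx),
                              character(1))
  }
  structure(list(parent = rmtree$parent, value = value, ref_tokens = ref_tokens,
                 n_nodes = n, k = rmtree$k, cipher = ctx$cipher,
                 hash_fn = rmtree$hash_fn),
            class = "encrypted_gst")
}

#' @export
print.encrypted_gst <- function(x, ...) {
  cat(sprintf("encrypted_gst: %d nodes, %s over %s digests (k=%d)\n",
              x$n_nodes, x$cipher, x$hash_fn, x$k))
  invisible(x)
}

#' Build the server-side hash index over ciphertext bits
#'
#' A binary tree of fixed logical depth k whose root-to-leaf paths are the
#' bits of the encrypted node values; every RMT node's ciphertext (internal
#' nodes included — substring queries terminate mid-tree) is present
#' exactly once, its entry referencing the suffix tokens reachable through
#' that node. Physically realized as a sorted radix table with the depth-k
#' bit-walk as the logical contract, so no 128-level pointer chain is
#' materialized.
#'
#' @param egst an `encrypted_gst`.
#' @return a `hash_index`: `entries` (environment, ciphertext hex -> entry),
#'   `bits` (sorted bit-strings), `k`, `n_entries`.
#' @export
build_hash_index <- function(egst) {
  stopifnot(inherits(egst, "encrypted_gst"))
  n <- egst$n_nodes
  # subtree reference accumulation (children after parents in reverse id
  # order is not guaranteed; accumulate bottom-up over a BFS ordering)
  depth <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)[-1L]) {
    p <- egst$parent[i]
    kids[[p]] <- c(kids[[p]], i)
    depth[i] <- 0L
  }
  ord <- integer(n); ord[1L] <- 1L; head <- 1L; cnt <- 1L
  while (head <= cnt) {
    node <- ord[head]; head <- head + 1L
    for (ch in kids[[node]]) {
      cnt <- cnt + 1L; ord[cnt] <- ch
      depth[ch] <- depth[node] + 1L
    }
  }
  subrefs <- egst$ref_tokens
  for (i in rev(ord)) {
    for (ch in kids[[i]]) subrefs[[i]] <- c(subrefs[[i]], subrefs[[ch]])
  }
  entries <- new.env(parent = emptyenv(), hash = TRUE)
  bits <- character(0)
  for (i in seq_len(n)[-1L]) {
    ct <- egst$value[i]
    cur <- get0(ct, envir = entries, inherits = FALSE)
    if (is.null(cur)) {
      assign(ct, list(node = i, depth = depth[i], refs = subrefs[[i]]), envir = entries)
      bits <- c(bits, paste(digest_bits(hex_to_raw(ct)), collapse = ""))
    } else {
      # identical path-strings legitimately share a digest: merge references
      cur$refs <- unique(c(cur$refs, subrefs[[i]]))
      assign(ct, cur, envir = entries)
    }
  }
  structure(list(entries = entries, bits = sort(bits), k = egst$k,
                 n_entries = length(bits)),
            class = "hash_index")
}

#' @export
print.hash_index <- function(x, ...) {
  cat(sprintf("hash_index: %d entries, logical depth k=%d\n", x$n_entries, x$k))
  invisible(x)
}

bitstring <- function(ct_raw) paste(digest_bits(ct_raw), collapse = "")

# binary search in a sorted character vector: index of last element <= x
bsearch_le <- function(v, x) {
  lo <- 1L; hi <- length(v); ans <- 0L
  while (lo <= hi) {
    mid <- (lo + hi) %/% 2L
    if (v[mid] <= x) { ans <- mid; lo <- mid + 1L } else hi <- mid - 1L
  }
  ans
}

# longest common prefix length of two equal-length bit strings
lcp_len <- function(a, b) {
  ra <- utf8ToInt(a); rb <- utf8ToInt(b)
  eq <- ra == rb
  if (all(eq)) length(ra) else which.min(eq) - 1L
}

#' Look up a ciphertext in the hash index
#'
#' Logical bit-walk from the root: a hit requires all k bits to traverse
#' existing children and land on an entry. On a miss the depth of the first
#' failing bit is reported (consumed by the oblivious protocol); the GST is
#' never touched on a miss.
#'
#' @param hi a `hash_index`.
#' @param ciphertext raw vector or hex string of k bits.
#' @return list with `hit`; on hit also `node`, `depth`, `refs`; on miss
#'   `fail_depth`.
#' @export
hi_lookup <- function(hi, ciphertext) {
  stopifnot(inherits(hi, "hash_index"))
  ct_hex <- if (is.raw(ciphertext)) raw_to_hex(ciphertext) else tolower(ciphertext)
  if (nchar(ct_hex) * 4L != hi$k) {
    stop(sprintf("ciphertext has %d bits, index depth is k=%d", nchar(ct_hex) * 4L, hi$k))
  }
  entry <- get0(ct_hex, envir = hi$entries, inherits = FALSE)
  if (!is.null(entry)) {
    return(list(hit = TRUE, node = entry$node, depth = entry$depth, refs = entry$refs))
  }
  bs <- bitstring(hex_to_raw(ct_hex))
  if (length(hi$bits) == 0L) return(list(hit = FALSE, fail_depth = 1L))
  pos <- bsearch_le(hi$bits, bs)  # index of last entry <= bs (0 if none)
  best <- 0L
  if (pos >= 1L) best <- max(best, lcp_len(bs, hi$bits[pos]))
  if (pos < length(hi$bits)) best <- max(best, lcp_len(bs, hi$bits[pos + 1L]))
  list(hit = FALSE, fail_depth = best + 1L)
}
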