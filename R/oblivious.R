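#' Two-party oblivious bit matching
#'
#' Hides the researcher's query bits from the server during the index walk.
#' Each round compares one researcher bit against one index bit through an
#' XNOR gate (1 iff equal) whose output is revealed to the server only; the
#' server advances to the matching child, takes the sibling when present,
#' or declares a mismatch. Two backends share the interface:
#' * `simulated` (default) — a trusted in-process broker computes the gate;
#'   functionally faithful, round-for-round, but not cryptographically
#'   secure. Inputs are never logged or stored in the transcript.
#' * `garbled` — the single XNOR gate is garbled: four hash-encrypted table
#'   rows under random 16-byte wire labels, the evaluator obtaining its
#'   input label through an oblivious-transfer abstraction, and exactly one
#'   row decrypting.
#'
#' @name gc_protocol
NULL

rand_label <- function() as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)

xor_raw <- function(a, b) as.raw(bitwAnd(bitwXor(as.integer(a), as.integer(b)), 255L))

#' Garbled XNOR of two private bits
#'
#' @param server_bit,client_bit bits in `{0, 1}`; `server_bit` is the index
#'   child's label bit, `client_bit` the researcher's query bit.
#' @param backend `"simulated"` or `"garbled"`.
#' @return list: `out` (1 iff bits equal — revealed to the server role),
#'   `blobs` (the opaque wire messages exchanged this round), and for the
#'   garbled backend `table` (the four rows) for auditing.
#' @export
garbled_xnor <- function(server_bit, client_bit, backend = c("simulated", "garbled")) {
  backend <- match.arg(backend)
  stopifnot(server_bit %in% c(0L, 1L), client_bit %in% c(0L, 1L))
  if (backend == "simulated") {
    # trusted broker: computes the gate in-process, emits dummy fixed-size
    # wire blobs so the transcript shape matches the garbled backend
    out <- as.integer(server_bit == client_bit)
    return(list(out = out, blobs = list(rand_label(), rand_label())))
  }
  # client garbles: labels for the server wire (S0/S1) and its own (C0/C1)
  S <- list(rand_label(), rand_label())
  C <- list(rand_label(), rand_label())
  rows <- list()
  for (a in 0:1) for (b in 0:1) {
    keyc <- c(S[[a + 1L]], C[[b + 1L]])
    tag <- as.raw(openssl::md5(keyc))
    pad <- as.raw(openssl::md5(c(keyc, as.raw(1L))))[1L]
    out_bit <- as.integer(a == b)  # XNOR
    rows[[length(rows) + 1L]] <- list(tag = tag, pay = xor_raw(as.raw(out_bit), pad))
  }
  rows <- rows[sample.int(4L)]
  # OT abstraction: the server learns S[server_bit] and nothing else; the
  # broker closure never exposes the other label
  ot <- function(choice) S[[choice + 1L]]
  s_label <- ot(server_bit)
  c_label <- C[[client_bit + 1L]]
  # server evaluates: exactly one row's tag matches
  out <- NA_integer_
  keyc <- c(s_label, c_label)
  tag <- as.raw(openssl::md5(keyc))
  pad <- as.raw(openssl::md5(c(keyc, as.raw(1L))))[1L]
  n_dec <- 0L
  for (row in rows) {
    if (identical(row$tag, tag)) {
      out <- as.integer(xor_raw(row$pay, pad))
      n_dec <- n_dec + 1L
    }
  }
  if (is.na(out) || n_dec != 1L) stop("garbled table evaluation failed (malformed label)")
  list(out = out, blobs = list(s_label, c_label), table = rows)
}

#' Oblivious index lookup via per-bit XNOR rounds
#'
#' Functionally identical to [hi_lookup()] — same hits, same references,
#' same first-failure depth — but the walk runs as a fixed-round two-party
#' protocol. Per round the server randomly picks one of the current node's
#' children (when two exist; a lone child is functionally forced and tried
#' first), the gate compares its bit with the researcher's, and only the
#' equality bit reaches the server. A hit takes exactly k rounds; the
#' transcript ends at the first mismatch.
#'
#' @param ciphertext raw or hex query token of k bits.
#' @param hi a `hash_index`.
#' @param backend gate backend, see [garbled_xnor()].
#' @param seed optional seed for the server's random child picks
#'   (reproducible transcripts).
#' @return list: `result` (as [hi_lookup()]) and `transcript` (list of
#'   rounds: `blobs`, `outcome` in continue/mismatch/leaf-hit).
#' @export
run_oblivious_lookup <- function(ciphertext, hi, backend = "simulated", seed = NULL) {
  stopifnot(inherits(hi, "hash_index"))
  ct_hex <- if (is.raw(ciphertext)) raw_to_hex(ciphertext) else tolower(ciphertext)
  if (nchar(ct_hex) * 4L != hi$k) stop(sprintf("token has %d bits, index depth k=%d",
                                               nchar(ct_hex) * 4L, hi$k))
  qbits <- digest_bits(hex_to_raw(ct_hex))
  body <- function() {
    transcript <- list()
    lo <- 1L; up <- length(hi$bits)
    if (up == 0L) {
      return(list(result = list(hit = FALSE, fail_depth = 1L), transcript = transcript))
    }
    for (d in seq_len(hi$k)) {
      # entries in [lo, up] share the first d-1 bits; the range splits into
      # a 0-part then a 1-part on bit d
      split <- bsearch_first_one(hi$bits, lo, up, d)
      have0 <- split > lo
      have1 <- split <= up
      present <- c(if (have0) 0L, if (have1) 1L)
      pick <- if (length(present) == 2L) present[sample.int(2L, 1L)] else present[1L]
      g <- garbled_xnor(pick, qbits[d], backend = backend)
      eq <- g$out
      branch <- if (eq == 1L) pick else if (length(present) == 2L) 1L - pick else NA_integer_
      outcome <- if (is.na(branch)) "mismatch" else if (d == hi$k) "leaf-hit" else "continue"
      transcript[[length(transcript) + 1L]] <- list(blobs = g$blobs, outcome = outcome)
      if (is.na(branch)) {
        return(list(result = list(hit = FALSE, fail_depth = d), transcript = transcript))
      }
      if (branch == 0L) up <- split - 1L else lo <- split
    }
    # depth k reached: the surviving entry is the token itself
    entry <- get0(ct_hex, envir = hi$entries, inherits = FALSE)
    list(result = list(hit = TRUE, node = entry$node, depth = entry$depth,
                       refs = entry$refs),
         transcript = transcript)
  }
  if (is.null(seed)) body() else withr_seed(seed, body)
}

# first index in [lo, up] whose bit at position d is "1" (up + 1 if none);
# valid because the range is sorted and shares bits 1..d-1
bsearch_first_one <- function(bits, lo, up, d) {
  l <- lo; u <- up; ans <- up + 1L
  while (l <= u) {
    mid <- (l + u) %/% 2L
    if (substr(bits[mid], d, d) == "1") { ans <- mid; u <- mid - 1L } else l <- mid + 1L
  }
  ans
}
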