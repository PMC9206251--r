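#' String queries over haplotype datasets
#'
#' Four query kinds, all reducible to digest lookups on the hash index:
#' * `em` — exact match: records equal to `q` over the full width.
#' * `esm` — exact substring match: records containing `q` contiguously;
#'   every occurrence `(j1, j2)` is returned.
#' * `smm` — set-maximal match: per record, the longest substring shared
#'   with `q` (non-extensible), subject to a minimum-length floor
#'   (default `ceiling((|q|+1)/2)`); records below the floor are omitted.
#' * `tsmm` — thresholded set-maximal match: as `smm` with floor `t`.
#'
#' Match spans are 1-based inclusive positions in the record; ties
#' (multiple equal-length maximal matches in one record) are all reported,
#' ordered by `j1`.
#'
#' @name queries
NULL

QUERY_KINDS <- c("em", "esm", "smm", "tsmm")

smm_floor <- function(qlen) as.integer(ceiling((qlen + 1) / 2))

#' Build researcher-side query tokens
#'
#' From the query string and the shared secrets only: each candidate
#' (sub)string is reverse-Merkle hashed under the salt and deterministically
#' encrypted. Exact match folds the terminal class (full suffixes only);
#' substring-style lookups use the bare digest so they can land on internal
#' index entries. Set-maximal kinds enumerate every substring of `q` down
#' to the floor, longest first, each tagged with its offset in `q`. The
#' wire form ([wire_tokens()]) carries ciphertexts and lengths only — no
#' plaintext symbols.
#'
#' @param q query string (1 <= nchar(q) <= m).
#' @param kind one of `"em"`, `"esm"`, `"smm"`, `"tsmm"`.
#' @param t threshold for `tsmm` (1 <= t <= nchar(q)).
#' @param keys a keyfile object from [make_keys()].
#' @param min_match optional floor override for `smm`.
#' @return an `encrypted_query`.
#' @export
make_query_tokens <- function(q, kind = QUERY_KINDS, t = NULL, keys, min_match = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(keys, "privgst_keys"))
  qlen <- nchar(q)
  if (qlen < 1L) stop("query must have at least one symbol (1 <= |q| <= m)")
  syms <- strsplit(q, "")[[1L]]
  if (any(syms == TERM)) stop("alphabet error: '$' is reserved")
  ctx <- encryption_context(keys$key, keys$iv)
  tok <- function(s, terminal) {
    raw_to_hex(encrypt_digest(rmt_hash_string(s, keys$salt, keys$hash_fn,
                                              terminal = terminal), ctx))
  }
  if (kind %in% c("em", "esm")) {
    tokens <- data.frame(length = qlen, offset = 1L, sub = q,
                         ct = tok(q, terminal = (kind == "em")),
                         stringsAsFactors = FALSE)
    floor_len <- qlen
  } else {
    floor_len <- if (kind == "tsmm") {
      if (is.null(t)) stop("tsmm requires a threshold t")
      t <- as.integer(t)
      if (t < 1L || t > qlen) stop(sprintf("threshold t=%d outside 1..|q|=%d", t, qlen))
      t
    } else {
      if (is.null(min_match)) smm_floor(qlen) else as.integer(min_match)
    }
    rows <- do.call(rbind, lapply(seq(qlen, floor_len), function(L) {
      data.frame(length = L, offset = seq_len(qlen - L + 1L), stringsAsFactors = FALSE)
    }))
    rows <- rows[order(-rows$length, rows$offset), ]
    rows$sub <- substring(q, rows$offset, rows$offset + rows$length - 1L)
    uniq <- !duplicated(rows$sub)
    rows <- rows[uniq, , drop = FALSE]
    cts <- vapply(rows$sub, tok, character(1), terminal = FALSE)
    rows$ct <- unname(cts)
    tokens <- rows
  }
  structure(list(kind = kind, qlen = qlen, t = t, floor = floor_len,
                 tokens = tokens, k = hash_spec(keys$hash_fn)$k, keys = keys),
            class = "encrypted_query")
}

#' Server-visible form of a query: ciphertexts and lengths only
#' @param eq an `encrypted_query`.
#' @return data.frame with columns `ct`, `length`.
#' @export
wire_tokens <- function(eq) {
  data.frame(ct = eq$tokens$ct, length = eq$tokens$length, stringsAsFactors = FALSE)
}

#' @export
print.encrypted_query <- function(x, ...) {
  cat(sprintf("encrypted_query: kind=%s, |q|=%d, %d token(s), floor=%d\n",
              x$kind, x$qlen, nrow(x$tokens), x$floor))
  invisible(x)
}

query_result <- function(kind, matches) {
  if (is.null(matches) || nrow(matches) == 0L) {
    matches <- data.frame(seq = integer(0), j1 = integer(0), j2 = integer(0),
                          length = integer(0), match = character(0),
                          stringsAsFactors = FALSE)
  }
  matches <- matches[order(matches$seq, matches$j1), , drop = FALSE]
  rownames(matches) <- NULL
  structure(list(kind = kind, status = if (nrow(matches) > 0L) "hit" else "miss",
                 matches = matches),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  cat(sprintf("query_result (%s): %s, %d match span(s)\n",
              toupper(x$kind), x$status, nrow(x$matches)))
  if (nrow(x$matches) > 0L) print(x$matches, row.names = FALSE)
  invisible(x)
}

#' Execute an encrypted query against a server bundle
#'
#' The server resolves each token on the hash index (plain bit-walk, or the
#' oblivious XNOR protocol when `oblivious = TRUE`) and returns the opaque
#' suffix tokens it references; the researcher decrypts those into
#' `(sequence, start)` spans and, for the set-maximal kinds, keeps each
#' record's longest match. Results are identical to [plaintext_oracle()] on
#' the underlying dataset by construction; a key/salt lineage mismatch
#' manifests as a universal miss (by design indistinguishable from absence).
#'
#' @param server a `server_bundle` (or a `hash_index`).
#' @param eq an `encrypted_query` from [make_query_tokens()].
#' @param oblivious use the garbled-circuit bit-matching walk.
#' @param gc_backend `"simulated"` or `"garbled"` (see [garbled_xnor()]).
#' @param gc_seed seed for the server's random child picks (reproducible
#'   transcripts).
#' @return a `query_result`.
#' @export
execute_query <- function(server, eq, oblivious = FALSE,
                          gc_backend = "simulated", gc_seed = NULL) {
  stopifnot(inherits(eq, "encrypted_query"))
  hi <- if (inherits(server, "server_bundle")) server$hi else server
  stopifnot(inherits(hi, "hash_index"))
  ctx <- encryption_context(eq$keys$key, eq$keys$iv)
  do_lookup <- function(ct) {
    if (oblivious) run_oblivious_lookup(ct, hi, backend = gc_backend, seed = gc_seed)$result
    else hi_lookup(hi, ct)
  }
  spans_of <- function(res, L) {
    refs <- do.call(rbind, lapply(res$refs, decrypt_ref, ctx = ctx))
    data.frame(seq = refs[, 1L], j1 = refs[, 2L], j2 = refs[, 2L] + L - 1L,
               length = L, stringsAsFactors = FALSE)
  }
  if (eq$kind == "em") {
    res <- do_lookup(eq$tokens$ct[1L])
    if (!res$hit) return(query_result("em", NULL))
    sp <- spans_of(res, eq$qlen)
    sp <- sp[sp$j1 == 1L, , drop = FALSE]  # full-width suffixes start at 1
    sp$match <- rep(eq$tokens$sub[1L], nrow(sp))
    return(query_result("em", sp))
  }
  if (eq$kind == "esm") {
    res <- do_lookup(eq$tokens$ct[1L])
    if (!res$hit) return(query_result("esm", NULL))
    sp <- spans_of(res, eq$qlen)
    sp$match <- rep(eq$tokens$sub[1L], nrow(sp))
    return(query_result("esm", sp))
  }
  # smm / tsmm: longest-first iteration; a record's first (longest) hit wins
  best <- new.env(parent = emptyenv())
  acc <- list()
  for (i in seq_len(nrow(eq$tokens))) {
    L <- eq$tokens$length[i]
    res <- do_lookup(eq$tokens$ct[i])
    if (!res$hit) next
    sp <- spans_of(res, L)
    sp$match <- rep(eq$tokens$sub[i], nrow(sp))
    keep <- vapply(sp$seq, function(s) {
      b <- get0(as.character(s), envir = best, inherits = FALSE)
      is.null(b) || b == L
    }, logical(1))
    sp <- sp[keep, , drop = FALSE]
    for (s in unique(sp$seq)) assign(as.character(s), L, envir = best)
    if (nrow(sp) > 0L) acc[[length(acc) + 1L]] <- sp
  }
  m <- if (length(acc) > 0L) unique(do.call(rbind, acc)) else NULL
  query_result(eq$kind, m)
}

#' Ground-truth query evaluation by plaintext scan
#'
#' Direct transcription of the four query definitions as a naive
#' O(n m |q|) scan over the records. This is the reference every secure
#' execution path is checked against.
#'
#' @param dataset a [haplotype_dataset()].
#' @param q query string.
#' @param kind query kind.
#' @param t threshold for `tsmm`.
#' @param min_match optional floor override for `smm`.
#' @return a `query_result`.
#' @export
plaintext_oracle <- function(dataset, q, kind = QUERY_KINDS, t = NULL, min_match = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(dataset, "haplotype_dataset"))
  qlen <- nchar(q)
  stopifnot(qlen >= 1L)
  occurrences <- function(sub, rec) {
    hits <- gregexpr(sub, rec, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) integer(0) else {
      # gregexpr skips overlapping occurrences; rescan from each position
      out <- integer(0); from <- 1L
      while (from + nchar(sub) - 1L <= nchar(rec)) {
        if (substring(rec, from, from + nchar(sub) - 1L) == sub) out <- c(out, from)
        from <- from + 1L
      }
      out
    }
  }
  if (kind == "em") {
    hits <- if (qlen == dataset$m) which(dataset$records == q) else integer(0)
    m <- if (length(hits) > 0L)
      data.frame(seq = hits, j1 = 1L, j2 = dataset$m, length = dataset$m,
                 match = q, stringsAsFactors = FALSE) else NULL
    return(query_result("em", m))
  }
  if (kind == "esm") {
    acc <- list()
    for (r in seq_len(dataset$n)) {
      occ <- occurrences(q, dataset$records[r])
      if (length(occ) > 0L) {
        acc[[length(acc) + 1L]] <- data.frame(seq = r, j1 = occ, j2 = occ + qlen - 1L,
                                              length = qlen, match = q,
                                              stringsAsFactors = FALSE)
      }
    }
    return(query_result("esm", if (length(acc)) do.call(rbind, acc) else NULL))
  }
  floor_len <- if (kind == "tsmm") {
    if (is.null(t)) stop("tsmm requires a threshold t")
    as.integer(t)
  } else if (is.null(min_match)) smm_floor(qlen) else as.integer(min_match)
  acc <- list()
  for (r in seq_len(dataset$n)) {
    rec <- dataset$records[r]
    for (L in rev(seq(min(floor_len, qlen), qlen))) {
      subs <- unique(substring(q, seq_len(qlen - L + 1L), seq_len(qlen - L + 1L) + L - 1L))
      found <- list()
      for (s in subs) {
        occ <- occurrences(s, rec)
        if (length(occ) > 0L) {
          found[[length(found) + 1L]] <- data.frame(seq = r, j1 = occ, j2 = occ + L - 1L,
                                                    length = L, match = s,
                                                    stringsAsFactors = FALSE)
        }
      }
      if (length(found) > 0L) {
        acc[[length(acc) + 1L]] <- unique(do.call(rbind, found))
        break
      }
    }
  }
  query_result(kind, if (length(acc)) do.call(rbind, acc) else NULL)
}
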