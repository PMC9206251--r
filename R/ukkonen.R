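#' Generalized suffix tree via Ukkonen's algorithm
#'
#' Online, amortized-linear construction of a compressed (edge-labelled)
#' suffix tree, extended to multiple sequences: each record is streamed
#' through the classic active-point / suffix-link machinery against the
#' shared tree, with a terminal marker closing its suffixes. Edge labels are
#' `(sequence, start, end)` references into the records, so the tree stores
#' no copied substrings. The per-symbol logical expansion
#' ([expand_to_trie()]) is node-for-node equal to [build_trie()]'s output
#' under canonicalization; that equivalence is the correctness contract.
#'
#' @param dataset a [haplotype_dataset()].
#' @param rows subset of row indices (default all).
#' @param span `c(c1, c2)` column span (default full width).
#' @return an object of class `gst_compressed`.
#' @export
build_ukkonen <- function(dataset, rows = NULL, span = NULL) {
  stopifnot(inherits(dataset, "haplotype_dataset"))
  if (is.null(rows)) rows <- seq_len(dataset$n)
  rows <- as.integer(rows)
  if (length(rows) == 0L) stop("empty row set")
  if (is.null(span)) span <- c(1L, dataset$m)
  c1 <- as.integer(span[1L]); c2 <- as.integer(span[2L])
  stopifnot(1L <= c1, c1 <= c2, c2 <= dataset$m)

  cap <- 64L
  eseq <- integer(cap); estart <- integer(cap); eend <- integer(cap)
  parent <- integer(cap); slink <- integer(cap)
  n <- 1L  # node 1 = root, no incoming edge
  eseq[1L] <- NA_integer_
  kids <- new.env(parent = emptyenv(), hash = TRUE)
  leafref <- new.env(parent = emptyenv(), hash = TRUE)
  OPEN <- -1L

  grow <- function() {
    cap2 <- length(eseq) * 2L
    eseq <<- c(eseq, integer(cap2 - length(eseq)))
    estart <<- c(estart, integer(cap2 - length(estart)))
    eend <<- c(eend, integer(cap2 - length(eend)))
    parent <<- c(parent, integer(cap2 - length(parent)))
    slink <<- c(slink, integer(cap2 - length(slink)))
  }
  new_node <- function(sq, st, en, par) {
    n <<- n + 1L
    if (n > length(eseq)) grow()
    eseq[n] <<- sq; estart[n] <<- st; eend[n] <<- en; parent[n] <<- par
    slink[n] <<- 0L
    n
  }
  kid <- function(node, sym) get0(paste0(node, KSEP, sym), envir = kids, inherits = FALSE)
  set_kid <- function(node, sym, child) assign(paste0(node, KSEP, sym), child, envir = kids)
  add_ref <- function(leaf, r, j) {
    key <- as.character(leaf)
    cur <- get0(key, envir = leafref, inherits = FALSE)
    assign(key, c(cur, list(c(r, c1 + j - 1L))), envir = leafref)
  }

  texts <- list()  # restricted chars + terminal, keyed by row index
  sym_at <- function(sq, pos) texts[[sq]][pos]

  for (r in rows) {
    x <- c(strsplit(substring(dataset$records[r], c1, c2), "")[[1L]], TERM)
    texts[[r]] <- x
    L <- length(x)
    an <- 1L; ae <- 0L; al <- 0L; remainder <- 0L

    for (i in seq_len(L)) {
      remainder <- remainder + 1L
      last_new <- 0L
      while (remainder > 0L) {
        if (i == L && remainder == 1L) {  # bare terminal = empty suffix; not stored
          remainder <- 0L
          break
        }
        if (al == 0L) ae <- i
        nxt <- kid(an, x[ae])
        if (is.null(nxt)) {
          leaf <- new_node(r, i, OPEN, an)
          set_kid(an, x[i], leaf)
          add_ref(leaf, r, i - remainder + 1L)
          if (last_new != 0L) { slink[last_new] <- an; last_new <- 0L }
        } else {
          en <- if (eend[nxt] == OPEN) i else eend[nxt]
          elen <- en - estart[nxt] + 1L
          if (al >= elen) {  # canonicalize: walk down the edge
            an <- nxt; ae <- ae + elen; al <- al - elen
            next
          }
          nc <- sym_at(eseq[nxt], estart[nxt] + al)
          if (identical(nc, x[i])) {
            if (identical(x[i], TERM)) {
              # suffix already present and closed by an earlier sequence's
              # terminal: record the reference on the existing leaf
              add_ref(nxt, r, i - remainder + 1L)
              if (last_new != 0L) { slink[last_new] <- an; last_new <- 0L }
              # fall through to consume this suffix and advance
            } else {
              if (last_new != 0L) { slink[last_new] <- an; last_new <- 0L }
              al <- al + 1L
              break
            }
          } else {
            # split the edge, hang the old child and a fresh leaf off it
            sq <- eseq[nxt]; st <- estart[nxt]
            mid <- new_node(sq, st, st + al - 1L, an)
            set_kid(an, x[ae], mid)
            estart[nxt] <- st + al
            parent[nxt] <- mid
            set_kid(mid, sym_at(sq, st + al), nxt)
            leaf <- new_node(r, i, OPEN, mid)
            set_kid(mid, x[i], leaf)
            add_ref(leaf, r, i - remainder + 1L)
            if (last_new != 0L) slink[last_new] <- mid
            last_new <- mid
          }
        }
        remainder <- remainder - 1L
        if (an == 1L && al > 0L) {
          al <- al - 1L
          ae <- i - remainder + 1L
        } else if (an != 1L) {
          an <- if (slink[an] != 0L) slink[an] else 1L
        }
      }
    }
    # freeze this sequence's open leaves at its terminal position
    open <- which(eend[seq_len(n)] == OPEN)
    eend[open] <- L
  }

  idx <- seq_len(n)
  children <- vector("list", n)
  if (n > 1L) {
    first_sym <- c(NA_character_, vapply(2:n, function(i) sym_at(eseq[i], estart[i]), character(1)))
    for (grp in split(2:n, parent[2:n])) {
      v <- grp
      names(v) <- first_sym[grp]
      children[[parent[grp[1L]]]] <- v[order(names(v))]
    }
  }
  refs <- vector("list", n)
  for (key in ls(leafref, sorted = FALSE)) {
    v <- get(key, envir = leafref)
    mat <- unique(do.call(rbind, v))
    mat <- mat[order(mat[, 1L], mat[, 2L]), , drop = FALSE]
    colnames(mat) <- c("seq", "start")
    refs[[as.integer(key)]] <- mat
  }
  structure(
    list(eseq = eseq[idx], estart = estart[idx], eend = eend[idx],
         parent = parent[idx], children = children, refs = refs,
         texts = texts, n_nodes = n, representation = "compressed",
         n_seq = dataset$n, m = dataset$m, alphabet = dataset$alphabet,
         span = c(c1, c2)),
    class = "gst_compressed"
  )
}

#' @export
print.gst_compressed <- function(x, ...) {
  nref <- sum(vapply(x$refs, function(r) if (is.null(r)) 0L else nrow(r), integer(1)))
  cat(sprintf("gst (compressed): %d nodes, %d leaf refs, span [%d,%d]\n",
              x$n_nodes, nref, x$span[1L], x$span[2L]))
  invisible(x)
}

#' Edge label of a compressed-GST node, spelled out
#' @keywords internal
edge_label <- function(gc, node) {
  if (node == 1L) return(character(0))
  gc$texts[[gc$eseq[node]]][gc$estart[node]:gc$eend[node]]
}

#' Expand a compressed GST to the per-symbol trie view
#'
#' Materializes every edge label one symbol per node; terminal-final edges
#' become a trie terminal carrying the leaf references. The result compares
#' with [build_trie()] output via [gst_equal()].
#'
#' @param gc a `gst_compressed`.
#' @return a `gst` (trie form).
#' @export
expand_to_trie <- function(gc) {
  stopifnot(inherits(gc, "gst_compressed"))
  e <- new_trie_env()
  walk2 <- function(node, at) {
    lab <- edge_label(gc, node)
    if (length(lab) > 0L) {
      has_term <- lab[length(lab)] == TERM
      body <- if (has_term) lab[-length(lab)] else lab
      at <- trie_insert_path(e, body, from = at)
      if (has_term) {
        r <- gc$refs[[node]]
        for (j in seq_len(nrow(r))) trie_mark(e, at, r[j, 1L], r[j, 2L])
      }
    }
    for (ch in gc$children[[node]]) walk2(ch, at)
  }
  walk2(1L, 1L)
  trie_finalize(e, list(n_seq = gc$n_seq, m = gc$m, alphabet = gc$alphabet,
                        span = gc$span))
}
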