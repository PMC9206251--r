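#' @title Generalized suffix trees (uncompressed trie form)
#'
#' @description
#' The trie (one symbol per edge) is the canonical logical representation of
#' a GST here: the reverse-Merkle hashing assigns one digest per single-symbol
#' node, so everything downstream (hashing, encryption, indexing) consumes
#' this form. Suffix ends are marked by a reserved terminal symbol `"$"`
#' (rejected from data alphabets) whose node carries the `(sequence, start)`
#' references of the suffixes ending there.
#'
#' @name gst
NULL

TERM <- "$"
KSEP <- "\x1f"

# -- mutable trie builder -----------------------------------------------------

new_trie_env <- function(cap = 256L) {
  e <- new.env(parent = emptyenv())
  e$symbol <- character(cap)
  e$parent <- integer(cap)
  e$n <- 1L
  e$symbol[1L] <- NA_character_
  e$parent[1L] <- 0L
  e$kids <- new.env(parent = emptyenv(), hash = TRUE)
  e$refs <- new.env(parent = emptyenv(), hash = TRUE)     # node id -> list of c(seq, start)
  e$pending <- new.env(parent = emptyenv(), hash = TRUE)  # node id -> list of c(seq, start)
  e
}

trie_grow <- function(e) {
  cap <- length(e$symbol) * 2L
  e$symbol <- c(e$symbol, character(length(e$symbol)))
  e$parent <- c(e$parent, integer(cap - length(e$parent)))
  invisible(e)
}

trie_child <- function(e, node, sym, create = TRUE) {
  key <- paste0(node, KSEP, sym)
  id <- get0(key, envir = e$kids, inherits = FALSE)
  if (!is.null(id)) return(id)
  if (!create) return(NULL)
  id <- e$n + 1L
  if (id > length(e$symbol)) trie_grow(e)
  e$n <- id
  e$symbol[id] <- sym
  e$parent[id] <- node
  assign(key, id, envir = e$kids)
  id
}

trie_insert_path <- function(e, syms, from = 1L) {
  node <- from
  for (s in syms) node <- trie_child(e, node, s)
  node
}

trie_mark <- function(e, node, seq, start, slot = "refs") {
  term <- if (slot == "refs") trie_child(e, node, TERM) else node
  key <- as.character(term)
  env <- e[[slot]]
  cur <- get0(key, envir = env, inherits = FALSE)
  assign(key, c(cur, list(c(seq, start))), envir = env)
  invisible(term)
}

refs_env_to_list <- function(env, n) {
  out <- vector("list", n)
  for (key in ls(env, sorted = FALSE)) {
    v <- get(key, envir = env)
    mat <- do.call(rbind, v)
    mat <- unique(mat)
    mat <- mat[order(mat[, 1L], mat[, 2L]), , drop = FALSE]
    colnames(mat) <- c("seq", "start")
    out[[as.integer(key)]] <- mat
  }
  out
}

trie_finalize <- function(e, meta) {
  n <- e$n
  symbol <- e$symbol[seq_len(n)]
  parent <- e$parent[seq_len(n)]
  children <- vector("list", n)
  if (n > 1L) {
    idx <- 2:n
    for (grp in split(idx, parent[idx])) {
      p <- parent[grp[1L]]
      v <- grp
      names(v) <- symbol[grp]
      children[[p]] <- v
    }
  }
  structure(
    c(list(symbol = symbol, parent = parent, children = children,
           refs = refs_env_to_list(e$refs, n),
           pending = refs_env_to_list(e$pending, n),
           n_nodes = n, representation = "trie"),
      meta),
    class = "gst"
  )
}

gst_meta <- function(dataset, span) {
  list(n_seq = dataset$n, m = dataset$m, alphabet = dataset$alphabet, span = span)
}

# -- builders -----------------------------------------------------------------

#' Build a GST by per-suffix trie insertion
#'
#' Inserts every suffix of every selected record (restricted to the column
#' span) symbol-by-symbol. Quadratic per record, but simple enough to serve
#' as the reference builder that all other construction paths are checked
#' against.
#'
#' @param dataset a [haplotype_dataset()].
#' @param rows subset of row indices (default all).
#' @param span `c(c1, c2)` column span, 1-based inclusive (default full width).
#' @param pending if `TRUE`, suffix ends are recorded as pending
#'   continuations (to be extended by path graphs) rather than terminals;
#'   used by vertical/bi-directional partitioning for blocks with `c2 < m`.
#' @return an object of class `gst`.
#' @export
build_trie <- function(dataset, rows = NULL, span = NULL, pending = FALSE) {
  stopifnot(inherits(dataset, "haplotype_dataset"))
  if (is.null(rows)) rows <- seq_len(dataset$n)
  rows <- as.integer(rows)
  if (length(rows) == 0L) stop("empty row set")
  stopifnot(all(rows >= 1L & rows <= dataset$n))
  if (is.null(span)) span <- c(1L, dataset$m)
  c1 <- as.integer(span[1L]); c2 <- as.integer(span[2L])
  stopifnot(1L <= c1, c1 <= c2, c2 <= dataset$m)
  e <- new_trie_env()
  for (r in rows) {
    chars <- strsplit(dataset$records[r], "")[[1L]]
    for (start in c1:c2) {
      node <- trie_insert_path(e, chars[start:c2])
      trie_mark(e, node, r, start, slot = if (pending) "pending" else "refs")
    }
  }
  trie_finalize(e, gst_meta(dataset, c(c1, c2)))
}

# rebuild a mutable env from a finalized gst (for merging / extension)
trie_to_env <- function(g) {
  e <- new_trie_env(cap = max(256L, g$n_nodes))
  e$n <- g$n_nodes
  e$symbol[seq_len(g$n_nodes)] <- g$symbol
  e$parent[seq_len(g$n_nodes)] <- g$parent
  for (i in seq_len(g$n_nodes)[-1L]) {
    assign(paste0(g$parent[i], KSEP, g$symbol[i]), i, envir = e$kids)
  }
  copy_marks <- function(src, slot) {
    for (i in seq_along(src)) {
      if (!is.null(src[[i]])) {
        assign(as.character(i),
               lapply(seq_len(nrow(src[[i]])), function(j) unname(src[[i]][j, ])),
               envir = e[[slot]])
      }
    }
  }
  copy_marks(g$refs, "refs")
  copy_marks(g$pending, "pending")
  e
}

# -- canonical form and equality ----------------------------------------------

#' Canonicalize a GST
#'
#' Renumbers nodes in preorder with children visited in symbol order, so two
#' trees indexing the same suffix sets become structurally `identical()`.
#' Idempotent.
#'
#' @param g a `gst`.
#' @return a `gst` in canonical node order.
#' @export
gst_canonical <- function(g) {
  stopifnot(inherits(g, "gst"))
  n <- g$n_nodes
  order_new <- integer(n)   # old id -> new id
  seq_old <- integer(n)     # preorder sequence of old ids
  stack <- 1L
  k <- 0L
  while (length(stack) > 0L) {
    node <- stack[length(stack)]
    stack <- stack[-length(stack)]
    k <- k + 1L
    order_new[node] <- k
    seq_old[k] <- node
    ch <- g$children[[node]]
    if (!is.null(ch)) {
      ch <- ch[order(names(ch))]
      stack <- c(stack, rev(unname(ch)))
    }
  }
  symbol <- g$symbol[seq_old]
  po <- g$parent[seq_old]
  parent <- integer(n)
  nz <- po != 0L
  parent[nz] <- order_new[po[nz]]
  remap <- function(lst) {
    out <- vector("list", n)
    for (i in seq_len(n)) if (!is.null(lst[[i]])) out[[order_new[i]]] <- lst[[i]]
    out
  }
  children <- vector("list", n)
  if (n > 1L) {
    idx <- 2:n
    for (grp in split(idx, parent[idx])) {
      v <- grp
      names(v) <- symbol[grp]
      children[[parent[grp[1L]]]] <- v
    }
  }
  structure(
    list(symbol = symbol, parent = parent, children = children,
         refs = remap(g$refs), pending = remap(g$pending),
         n_nodes = n, representation = "trie",
         n_seq = g$n_seq, m = g$m, alphabet = g$alphabet, span = g$span),
    class = "gst"
  )
}

#' Test two GSTs for canonical equality
#' @param a,b `gst` objects (trie form).
#' @return `TRUE` iff the canonical forms have identical structure,
#'   terminal references and pending marks.
#' @export
gst_equal <- function(a, b) {
  ca <- gst_canonical(as_trie(a))
  cb <- gst_canonical(as_trie(b))
  identical(ca$symbol, cb$symbol) &&
    identical(ca$parent, cb$parent) &&
    identical(ca$refs, cb$refs) &&
    identical(ca$pending, cb$pending)
}

as_trie <- function(g) {
  if (inherits(g, "gst_compressed")) expand_to_trie(g) else g
}

#' @export
print.gst <- function(x, ...) {
  nref <- sum(vapply(x$refs, function(r) if (is.null(r)) 0L else nrow(r), integer(1)))
  cat(sprintf("gst (%s): %d nodes, %d leaf refs, %d sequences x m=%d, span [%d,%d]\n",
              x$representation, x$n_nodes, nref, x$n_seq, x$m, x$span[1L], x$span[2L]))
  invisible(x)
}

# -- suffix enumeration (canonical equality surface) --------------------------

#' Enumerate all suffixes stored in a GST
#'
#' Walks root-to-terminal paths and emits one row per `(sequence, start)`
#' reference with the spelled-out suffix string. This is the canonical
#' equality surface for trees: two GSTs index the same data iff their
#' enumerations agree.
#'
#' @param gst a `gst` (trie) or `gst_compressed`.
#' @return a data.frame with columns `seq`, `start`, `suffix`, sorted.
#' @export
enumerate_suffixes <- function(gst) {
  g <- as_trie(gst)
  out_seq <- integer(0); out_start <- integer(0); out_suf <- character(0)
  walk <- function(node, path) {
    r <- g$refs[[node]]
    if (!is.null(r)) {
      out_seq <<- c(out_seq, r[, 1L])
      out_start <<- c(out_start, r[, 2L])
      out_suf <<- c(out_suf, rep(path, nrow(r)))
    }
    ch <- g$children[[node]]
    for (i in seq_along(ch)) {
      sym <- names(ch)[i]
      if (sym == TERM) walk(ch[[i]], path)
      else walk(ch[[i]], paste0(path, sym))
    }
  }
  walk(1L, "")
  df <- data.frame(seq = out_seq, start = out_start, suffix = out_suf,
                   stringsAsFactors = FALSE)
  df <- df[order(df$seq, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# brute-force suffix listing straight from the records (test oracle)
#' Enumerate suffixes directly from the dataset (reference listing)
#' @param dataset a [haplotype_dataset()].
#' @param rows,span as in [build_trie()].
#' @return data.frame with `seq`, `start`, `suffix` — what any correct GST
#'   over the same selection must enumerate.
#' @export
suffixes_from_records <- function(dataset, rows = NULL, span = NULL) {
  if (is.null(rows)) rows <- seq_len(dataset$n)
  if (is.null(span)) span <- c(1L, dataset$m)
  res <- do.call(rbind, lapply(rows, function(r) {
    starts <- span[1L]:span[2L]
    data.frame(seq = r, start = starts,
               suffix = substring(dataset$records[r], starts, span[2L]),
               stringsAsFactors = FALSE)
  }))
  res <- res[order(res$seq, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# -- serialization ------------------------------------------------------------

GST_FORMAT <- "privgst-gst"
GST_VERSION <- 1L

#' Serialize / deserialize a GST
#'
#' Self-describing versioned JSON: a header (`format`, `version`, metadata)
#' followed by node and reference tables. Round-trips the canonical form
#' bit-exactly. Compressed trees are expanded to the trie view first.
#'
#' @param gst a `gst`.
#' @param path file path.
#' @return `serialize_gst` returns `path` invisibly; `deserialize_gst`
#'   returns the `gst`.
#' @export
serialize_gst <- function(gst, path) {
  g <- gst_canonical(as_trie(gst))
  marks <- function(lst) {
    keep <- which(!vapply(lst, is.null, logical(1)))
    list(node = as.integer(keep),
         rows = lapply(unname(keep), function(i) {
           m <- lst[[i]]
           lapply(seq_len(nrow(m)), function(j) as.integer(m[j, ]))
         }))
  }
  obj <- list(
    format = GST_FORMAT, version = GST_VERSION,
    n_seq = g$n_seq, m = g$m, alphabet = g$alphabet, span = as.integer(g$span),
    n_nodes = g$n_nodes,
    symbol = c("", g$symbol[-1L]),   # root symbol is NA; JSON-safe placeholder
    parent = g$parent,
    refs = marks(g$refs),
    pending = marks(g$pending)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname serialize_gst
#' @export
deserialize_gst <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop(sprintf("cannot parse GST file %s: %s",
                                                   path, conditionMessage(e))))
  if (!identical(obj$format, GST_FORMAT)) {
    stop(sprintf("not a GST file (format header '%s')", as.character(obj$format)[1L]))
  }
  if (!identical(as.integer(obj$version), GST_VERSION)) {
    stop(sprintf("unsupported GST format version %s", as.character(obj$version)[1L]))
  }
  n <- as.integer(obj$n_nodes)
  symbol <- vapply(obj$symbol, as.character, character(1))
  symbol[1L] <- NA_character_
  parent <- vapply(obj$parent, as.integer, integer(1))
  if (length(symbol) != n || length(parent) != n) stop("truncated GST file: node table length mismatch")
  unmarks <- function(m) {
    out <- vector("list", n)
    nodes <- vapply(m$node, as.integer, integer(1))
    for (i in seq_along(nodes)) {
      mat <- do.call(rbind, lapply(m$rows[[i]], function(r) as.integer(unlist(r))))
      colnames(mat) <- c("seq", "start")
      out[[nodes[i]]] <- mat
    }
    out
  }
  children <- vector("list", n)
  if (n > 1L) {
    idx <- 2:n
    for (grp in split(idx, parent[idx])) {
      v <- grp
      names(v) <- symbol[grp]
      children[[parent[grp[1L]]]] <- v
    }
  }
  structure(
    list(symbol = symbol, parent = parent, children = children,
         refs = unmarks(obj$refs), pending = unmarks(obj$pending),
         n_nodes = n, representation = "trie",
         n_seq = as.integer(obj$n_seq), m = as.integer(obj$m),
         alphabet = vapply(obj$alphabet, as.character, character(1)),
         span = vapply(obj$span, as.integer, integer(1))),
    class = "gst"
  )
}

#' Node depth vector of a GST
#' @param g a `gst`.
#' @return integer vector: root has depth 0, each child one more.
#' @keywords internal
gst_depths <- function(g) {
  d <- integer(g$n_nodes)
  for (i in seq_len(g$n_nodes)[-1L]) d[i] <- d[g$parent[i]] + 1L
  d
}
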