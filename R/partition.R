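#' Plan a data partition for parallel GST construction
#'
#' Splits the n x m record matrix into contiguous, balanced blocks, one per
#' worker, under one of three schemes:
#' * `horizontal` — row groups; each worker indexes a subset of records over
#'   the full width. No extension step is needed.
#' * `vertical` — column groups; blocks left of the last one hold truncated
#'   suffixes that are later extended by per-sequence path graphs.
#' * `bidirectional` — rows and columns both split (requires `p >= 4`,
#'   factorable into two factors >= 2).
#'
#' The merge schedule pairs workers by proximity rank (adjacent ids) in a
#' binary reduction; with one worker it is empty.
#'
#' @param n,m dataset dimensions.
#' @param p worker count.
#' @param scheme `"horizontal"`, `"vertical"` or `"bidirectional"`.
#' @return a `partition_plan`: `scheme`, `p`, `blocks` (data.frame with
#'   `worker`, `row1`, `row2`, `col1`, `col2`), `grid` (c(row groups, column
#'   groups)), and `schedule` (list of merge rounds, each a matrix of worker
#'   pairs).
#' @export
plan_partition <- function(n, m, p, scheme = c("horizontal", "vertical", "bidirectional")) {
  scheme <- match.arg(scheme)
  n <- as.integer(n); m <- as.integer(m); p <- as.integer(p)
  stopifnot(n >= 1L, m >= 1L, p >= 1L)
  if (scheme == "bidirectional" && p < 4L) {
    stop("bidirectional partitioning requires four or more workers (p >= 4)")
  }
  chunk <- function(len, k) {
    # balanced contiguous ranges, sizes differing by <= 1
    sizes <- rep(len %/% k, k) + c(rep(1L, len %% k), rep(0L, k - len %% k))
    hi <- cumsum(sizes)
    cbind(lo = hi - sizes + 1L, hi = hi)
  }
  if (scheme == "horizontal") {
    if (p > n) stop(sprintf("p=%d workers exceed n=%d rows", p, n))
    rr <- chunk(n, p)
    blocks <- data.frame(worker = seq_len(p), row1 = rr[, 1L], row2 = rr[, 2L],
                         col1 = 1L, col2 = m)
    grid <- c(p, 1L)
  } else if (scheme == "vertical") {
    if (p > m) stop(sprintf("p=%d workers exceed m=%d columns", p, m))
    cc <- chunk(m, p)
    blocks <- data.frame(worker = seq_len(p), row1 = 1L, row2 = n,
                         col1 = cc[, 1L], col2 = cc[, 2L])
    grid <- c(1L, p)
  } else {
    f <- bidi_factors(p)
    if (is.null(f)) stop(sprintf("bidirectional requires p to factor into two parts >= 2; p=%d does not", p))
    pr <- f[1L]; pc <- f[2L]
    if (pr > n || pc > m) stop(sprintf("grid %dx%d exceeds dataset %dx%d", pr, pc, n, m))
    rr <- chunk(n, pr); cc <- chunk(m, pc)
    blocks <- expand.grid(gr = seq_len(pr), gc = seq_len(pc))
    blocks <- blocks[order(blocks$gr, blocks$gc), ]
    blocks <- data.frame(worker = seq_len(p),
                         row1 = rr[blocks$gr, 1L], row2 = rr[blocks$gr, 2L],
                         col1 = cc[blocks$gc, 1L], col2 = cc[blocks$gc, 2L])
    grid <- c(pr, pc)
  }
  structure(list(scheme = scheme, p = p, n = n, m = m, grid = grid,
                 blocks = blocks, schedule = merge_schedule(grid[1L])),
            class = "partition_plan")
}

# largest factorization pr x pc with pr <= pc, both >= 2; pr closest to sqrt(p)
bidi_factors <- function(p) {
  for (f in rev(seq_len(floor(sqrt(p)))[-1L])) if (p %% f == 0L) return(c(f, p %/% f))
  NULL
}

# adjacent-pair binary reduction over g row groups: round r merges group
# (i + 2^(r-1)) into group i. Proximity rank = |worker id difference|.
merge_schedule <- function(g) {
  rounds <- list()
  step <- 1L
  while (step < g) {
    src <- seq(1L, g, by = 2L * step)
    pairs <- cbind(into = src, from = src + step)
    pairs <- pairs[pairs[, 2L] <= g, , drop = FALSE]
    if (nrow(pairs) > 0L) rounds[[length(rounds) + 1L]] <- pairs
    step <- 2L * step
  }
  rounds
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf("partition_plan: %s, p=%d over %dx%d (grid %dx%d)\n",
              x$scheme, x$p, x$n, x$m, x$grid[1L], x$grid[2L]))
  print(x$blocks, row.names = FALSE)
  invisible(x)
}

#' Per-sequence path graphs for a column tail
#'
#' A path graph is a linear chain of nodes (one child each) spelling the
#' tail `(c2, m]` of one sequence; truncated blocks append these chains to
#' close their pending suffixes.
#'
#' @param dataset a [haplotype_dataset()].
#' @param c2 last column covered by the block; tails span `(c2, m]`.
#' @param rows rows to build tails for (default all).
#' @return named list (by row index) of `path_graph` objects with fields
#'   `label`, `seq`, `start_col`, `symbols`.
#' @export
path_graphs <- function(dataset, c2, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(dataset$n)
  c2 <- as.integer(c2)
  stopifnot(c2 >= 0L, c2 <= dataset$m)
  out <- lapply(seq_along(rows), function(i) {
    r <- as.integer(rows[i])
    structure(list(label = paste0("%", i), seq = r, start_col = c2 + 1L,
                   symbols = if (c2 < dataset$m)
                     strsplit(substring(dataset$records[r], c2 + 1L, dataset$m), "")[[1L]]
                   else character(0)),
              class = "path_graph")
  })
  names(out) <- as.character(rows)
  out
}

#' Extend a truncated block GST with path graphs
#'
#' Every pending suffix of a block over columns `[c1, c2]`, `c2 < m`, is
#' extended down the tree by its sequence's tail chain so it ends at column
#' `m`, then terminated. Shared prefixes merge (no duplicate siblings); a
#' zero-length tail (`c2 = m`) just converts pending marks to terminals.
#'
#' @param gst_block a `gst` with pending continuation marks.
#' @param tails named list from [path_graphs()], keyed by row index.
#' @return a `gst` with no pending marks.
#' @export
extend_with_path_graphs <- function(gst_block, tails) {
  g <- gst_block
  stopifnot(inherits(g, "gst"))
  e <- trie_to_env(g)
  c2 <- g$span[2L]
  pend <- g$pending
  for (node in which(!vapply(pend, is.null, logical(1)))) {
    mat <- pend[[node]]
    for (j in seq_len(nrow(mat))) {
      r <- mat[j, 1L]; start <- mat[j, 2L]
      tail <- tails[[as.character(r)]]
      if (is.null(tail)) stop(sprintf("missing path graph for sequence %d", r))
      if (length(tail$symbols) > 0L && tail$start_col != c2 + 1L) {
        stop(sprintf("path graph for sequence %d starts at column %d, block ends at %d",
                     r, tail$start_col, c2))
      }
      end <- trie_insert_path(e, tail$symbols, from = node)
      trie_mark(e, end, r, start)
    }
  }
  e$pending <- new.env(parent = emptyenv(), hash = TRUE)
  out <- trie_finalize(e, list(n_seq = g$n_seq, m = g$m, alphabet = g$alphabet,
                               span = c(g$span[1L], g$m)))
  out
}

#' Merge two GSTs into one duplicate-free tree
#'
#' Structural union: the suffix set of the result is the union of the
#' inputs' suffix sets with `(sequence, start)` references unioned; no node
#' ends up with two sibling edges on the same symbol. Inputs are not
#' modified. Associative and commutative up to canonical form.
#'
#' @param a,b `gst` objects over the same alphabet (trie form; compressed
#'   inputs are expanded).
#' @return the merged `gst`.
#' @export
merge_gst <- function(a, b) {
  a <- as_trie(a); b <- as_trie(b)
  if (!identical(sort(a$alphabet), sort(b$alphabet))) {
    stop(sprintf("alphabet mismatch: {%s} vs {%s}",
                 paste(a$alphabet, collapse = ","), paste(b$alphabet, collapse = ",")))
  }
  e <- trie_to_env(a)
  graft(e, b, b_node = 1L, at = 1L)
  trie_finalize(e, list(n_seq = max(a$n_seq, b$n_seq), m = a$m,
                        alphabet = a$alphabet,
                        span = c(min(a$span[1L], b$span[1L]),
                                 max(a$span[2L], b$span[2L]))))
}

# walk b's edges, creating/sharing nodes in the mutable env
graft <- function(e, b, b_node, at) {
  marks <- function(slot) {
    mat <- b[[slot]][[b_node]]
    if (!is.null(mat)) {
      for (j in seq_len(nrow(mat))) {
        if (slot == "refs") {
          # `at` is already the terminal node when grafting a "$" edge
          key <- as.character(at)
          cur <- get0(key, envir = e$refs, inherits = FALSE)
          assign(key, c(cur, list(unname(mat[j, ]))), envir = e$refs)
        } else {
          trie_mark(e, at, mat[j, 1L], mat[j, 2L], slot = "pending")
        }
      }
    }
  }
  marks("refs")
  marks("pending")
  ch <- b$children[[b_node]]
  for (i in seq_along(ch)) {
    sym <- names(ch)[i]
    graft(e, b, ch[[i]], trie_child(e, at, sym))
  }
}

#' Build a GST in parallel over a partition plan
#'
#' Owner-side driver reproducing the distributed-memory architecture on one
#' machine: each block is built independently (optionally in forked worker
#' processes), written to a spool directory as a serialized tree file, read
#' back, extended with path graphs where the block is column-truncated, and
#' merged per the plan's binary-reduction schedule. Merging across the
#' root's distinct first-symbol branches is independent work
#' (branch-splittable); merges within one branch are sequential.
#'
#' The result is canonically equal to `build_trie(dataset)`.
#'
#' @param dataset a [haplotype_dataset()].
#' @param plan a [plan_partition()] plan (or `NULL` for a single block).
#' @param workers number of concurrent worker processes for the block-build
#'   stage (`1` runs blocks sequentially in-process; forked workers need a
#'   unix-alike OS).
#' @param spool directory for exchanged tree files (default a tempdir).
#' @return the merged `gst`.
#' @export
build_parallel <- function(dataset, plan = NULL, workers = 1L, spool = NULL) {
  stopifnot(inherits(dataset, "haplotype_dataset"))
  if (is.null(plan)) plan <- plan_partition(dataset$n, dataset$m, 1L, "horizontal")
  stopifnot(inherits(plan, "partition_plan"))
  if (plan$n != dataset$n || plan$m != dataset$m) {
    stop("partition plan shape does not match dataset")
  }
  if (is.null(spool)) spool <- tempfile("spool")
  dir.create(spool, showWarnings = FALSE, recursive = TRUE)
  blocks <- plan$blocks

  build_one <- function(i) {
    bl <- blocks[i, ]
    g <- build_trie(dataset, rows = bl$row1:bl$row2, span = c(bl$col1, bl$col2),
                    pending = bl$col2 < dataset$m)
    f <- file.path(spool, sprintf("block-%03d.json", bl$worker))
    serialize_gst(g, f)
    f
  }
  files <- if (workers > 1L && .Platform$OS.type == "unix") {
    res <- parallel::mclapply(seq_len(nrow(blocks)), build_one, mc.cores = workers)
    bad <- vapply(res, inherits, logical(1), what = "try-error")
    if (any(bad)) stop(sprintf("worker failed on block %d", which(bad)[1L]))
    res
  } else {
    lapply(seq_len(nrow(blocks)), build_one)
  }
  trees <- lapply(files, deserialize_gst)

  # column-truncated blocks: close pending suffixes with path-graph tails
  # (chained right-to-left: each tail spans all remaining columns)
  for (i in seq_along(trees)) {
    if (blocks$col2[i] < dataset$m) {
      tails <- path_graphs(dataset, blocks$col2[i], rows = blocks$row1[i]:blocks$row2[i])
      trees[[i]] <- extend_with_path_graphs(trees[[i]], tails)
    }
  }

  # merge within each row group (vertical direction), then reduce row groups
  rowkey <- paste(blocks$row1, blocks$row2)
  groups <- lapply(split(seq_along(trees), factor(rowkey, levels = unique(rowkey))),
                   function(ix) Reduce(merge_gst, trees[ix]))
  for (round in plan$schedule) {
    for (j in seq_len(nrow(round))) {
      into <- round[j, 1L]; from <- round[j, 2L]
      if (from <= length(groups) && !is.null(groups[[from]])) {
        groups[[into]] <- merge_gst(groups[[into]], groups[[from]])
        groups[from] <- list(NULL)
      }
    }
  }
  out <- groups[[1L]]
  out$n_seq <- dataset$n
  gst_canonical(out)
}
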