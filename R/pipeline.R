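#' Owner / server / researcher pipeline
#'
#' Single-machine simulation of the three-entity architecture: the data
#' owner builds the GST (in parallel) and derives the secrets, the cloud
#' server receives only the encrypted tree and its hash index, and the
#' researcher holds the keyfile and issues queries. Role directories
#' (`owner/`, `server/`, `researcher/`) enforce by construction which files
#' each role may read.
#'
#' @name pipeline
NULL

#' Create the shared secrets (salt, AES key, IV)
#'
#' The salt seeds the reverse-Merkle root; key and IV drive the
#' deterministic AES-CBC layer. All three are shared owner-to-researcher
#' and withheld from the server. With `seed` the bytes are derived
#' reproducibly (for tests and demos); otherwise they come from the OS
#' cryptographic source.
#'
#' @param hash_fn `"md5"` (k = 128) or `"sha256"` (k = 256).
#' @param seed optional integer for reproducible secrets.
#' @return a `privgst_keys` object: `hash_fn`, `salt`, `key`, `iv`.
#' @export
make_keys <- function(hash_fn = "md5", seed = NULL) {
  spec <- hash_spec(hash_fn)
  nb <- spec$k %/% 8L
  draw <- function(n) as.raw(sample.int(256L, n, replace = TRUE) - 1L)
  bytes <- if (is.null(seed)) {
    list(salt = openssl::rand_bytes(nb), key = openssl::rand_bytes(16L),
         iv = openssl::rand_bytes(16L))
  } else {
    withr_seed(seed, function() list(salt = draw(nb), key = draw(16L), iv = draw(16L)))
  }
  structure(c(list(hash_fn = hash_fn), bytes), class = "privgst_keys")
}

#' @export
print.privgst_keys <- function(x, ...) {
  cat(sprintf("privgst_keys: %s (k=%d), salt/key/iv held (not printed)\n",
              x$hash_fn, hash_spec(x$hash_fn)$k))
  invisible(x)
}

#' Write / read a keyfile
#'
#' JSON with hex-encoded secrets; owner- and researcher-side only (never
#' into the server directory). Pass secrets by file, not by command line,
#' so they stay out of shell history.
#'
#' @param keys a `privgst_keys`.
#' @param path keyfile path.
#' @return `write_keyfile` returns `path` invisibly; `read_keyfile` the keys.
#' @export
write_keyfile <- function(keys, path) {
  stopifnot(inherits(keys, "privgst_keys"))
  jsonlite::write_json(list(hash_fn = keys$hash_fn, salt = raw_to_hex(keys$salt),
                            key = raw_to_hex(keys$key), iv = raw_to_hex(keys$iv)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_keyfile
#' @export
read_keyfile <- function(path) {
  o <- jsonlite::read_json(path)
  structure(list(hash_fn = o$hash_fn, salt = hex_to_raw(o$salt),
                 key = hex_to_raw(o$key), iv = hex_to_raw(o$iv)),
            class = "privgst_keys")
}

#' Outsource a GST: hash, encrypt, index
#'
#' The owner-side one-time preprocessing: reverse-Merkle hash the tree
#' under the salt, encrypt every digest, build the server's bitwise hash
#' index. The returned bundle is everything the server holds — it contains
#' neither the salt, the key, nor any plaintext symbol.
#'
#' @param gst a `gst` (or `gst_compressed`).
#' @param keys a `privgst_keys`.
#' @return a `server_bundle`: `egst` (encrypted tree) and `hi` (hash index).
#' @export
outsource <- function(gst, keys) {
  stopifnot(inherits(keys, "privgst_keys"))
  rt <- hash_tree(gst, keys$salt, keys$hash_fn)
  egst <- encrypt_tree(rt, encryption_context(keys$key, keys$iv))
  list_bundle(egst, build_hash_index(egst))
}

list_bundle <- function(egst, hi) {
  structure(list(egst = egst, hi = hi), class = "server_bundle")
}

#' @export
print.server_bundle <- function(x, ...) {
  cat(sprintf("server_bundle: encrypted tree (%d nodes), index (%d entries, k=%d)\n",
              x$egst$n_nodes, x$hi$n_entries, x$hi$k))
  invisible(x)
}

#' Serialize / load a server bundle
#'
#' Versioned JSON holding the encrypted tree (parent vector + ciphertext
#' values + opaque reference tokens) and the index entries. Contains no
#' secrets; safe to hand to the server role.
#'
#' @param bundle a `server_bundle`.
#' @param path file path.
#' @export
write_server_bundle <- function(bundle, path) {
  e <- bundle$egst
  ents <- ls(bundle$hi$entries, sorted = TRUE)
  obj <- list(
    format = "privgst-bundle", version = 1L,
    k = e$k, cipher = e$cipher, hash_fn = e$hash_fn,
    n_nodes = e$n_nodes, parent = e$parent, value = e$value,
    ref_nodes = which(!vapply(e$ref_tokens, is.null, logical(1))),
    ref_tokens = Filter(Negate(is.null), e$ref_tokens),
    index = lapply(ents, function(ct) {
      en <- get(ct, envir = bundle$hi$entries)
      list(ct = ct, node = en$node, depth = en$depth, refs = en$refs)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_server_bundle
#' @export
read_server_bundle <- function(path) {
  o <- jsonlite::read_json(path)
  if (!identical(o$format, "privgst-bundle")) stop("not a server bundle file")
  n <- as.integer(o$n_nodes)
  ref_tokens <- vector("list", n)
  nodes <- vapply(o$ref_nodes, as.integer, integer(1))
  for (i in seq_along(nodes)) {
    ref_tokens[[nodes[i]]] <- vapply(o$ref_tokens[[i]], as.character, character(1))
  }
  egst <- structure(list(parent = vapply(o$parent, as.integer, integer(1)),
                         value = vapply(o$value, function(v) if (is.null(v)) NA_character_ else v, character(1)),
                         ref_tokens = ref_tokens, n_nodes = n,
                         k = as.integer(o$k), cipher = o$cipher, hash_fn = o$hash_fn),
                    class = "encrypted_gst")
  entries <- new.env(parent = emptyenv(), hash = TRUE)
  bits <- character(length(o$index))
  for (i in seq_along(o$index)) {
    en <- o$index[[i]]
    assign(en$ct, list(node = as.integer(en$node), depth = as.integer(en$depth),
                       refs = vapply(en$refs, as.character, character(1))),
           envir = entries)
    bits[i] <- bitstring(hex_to_raw(en$ct))
  }
  hi <- structure(list(entries = entries, bits = sort(bits), k = as.integer(o$k),
                       n_entries = length(bits)),
                  class = "hash_index")
  list_bundle(egst, hi)
}

#' End-to-end three-role demo over role directories
#'
#' Creates `owner/`, `server/`, `researcher/` under `base_dir`; the owner
#' builds and outsources, the server directory receives only the bundle,
#' the researcher only the keyfile. Returns the paths.
#'
#' @param dataset a [haplotype_dataset()].
#' @param base_dir target directory.
#' @param keys optional `privgst_keys` (fresh random ones by default).
#' @param scheme,workers passed to [plan_partition()] / [build_parallel()].
#' @return list of role paths (`owner`, `server`, `researcher`) and file
#'   locations.
#' @export
setup_roles <- function(dataset, base_dir, keys = NULL,
                        scheme = "horizontal", workers = 1L) {
  dirs <- file.path(base_dir, c("owner", "server", "researcher"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  if (is.null(keys)) keys <- make_keys()
  plan <- plan_partition(dataset$n, dataset$m, workers, scheme)
  g <- build_parallel(dataset, plan, workers = workers,
                      spool = file.path(dirs[1L], "spool"))
  write_dataset(dataset, file.path(dirs[1L], "dataset.txt"))
  serialize_gst(g, file.path(dirs[1L], "gst.json"))
  write_keyfile(keys, file.path(dirs[1L], "keyfile.json"))
  write_keyfile(keys, file.path(dirs[3L], "keyfile.json"))
  write_server_bundle(outsource(g, keys), file.path(dirs[2L], "bundle.json"))
  list(owner = dirs[1L], server = dirs[2L], researcher = dirs[3L],
       bundle = file.path(dirs[2L], "bundle.json"),
       keyfile = file.path(dirs[3L], "keyfile.json"))
}

#' Researcher-side query against a bundle on disk
#'
#' @param q query string; `kind` one of em/esm/smm/tsmm; `t` threshold.
#' @param keyfile path to the researcher keyfile.
#' @param bundle path to the server bundle (or a `server_bundle`).
#' @param oblivious,gc_backend,gc_seed see [execute_query()].
#' @param min_match optional smm floor override.
#' @return a `query_result`.
#' @export
run_query <- function(q, kind, keyfile, bundle, t = NULL, min_match = NULL,
                      oblivious = FALSE, gc_backend = "simulated", gc_seed = NULL) {
  keys <- if (inherits(keyfile, "privgst_keys")) keyfile else read_keyfile(keyfile)
  srv <- if (inherits(bundle, "server_bundle")) bundle else read_server_bundle(bundle)
  eq <- make_query_tokens(q, kind, t = t, keys = keys, min_match = min_match)
  execute_query(srv, eq, oblivious = oblivious, gc_backend = gc_backend,
                gc_seed = gc_seed)
}

#' Package self-test on the worked example
#'
#' Runs the full secure pipeline on the 5x6 example matrix and checks the
#' four canonical queries (exact 100010 -> record 1; substring 111 ->
#' record 2; set-maximal 1101 -> records 2,3,4,5; thresholded 1011, t=3 ->
#' records 2,4,5).
#'
#' @param verbose print per-check results.
#' @return `TRUE` (invisibly) if all checks pass; stops otherwise.
#' @export
selftest <- function(verbose = TRUE) {
  d <- example_dataset()
  keys <- make_keys(seed = 1L)
  srv <- outsource(build_trie(d), keys)
  check <- function(label, got, want) {
    ok <- identical(sort(unique(got)), sort(unique(want)))
    if (verbose) cat(sprintf("  [%s] %s: records {%s}\n",
                             if (ok) "ok" else "FAIL", label,
                             paste(sort(unique(got)), collapse = ",")))
    if (!ok) stop(sprintf("selftest failed at %s", label))
  }
  q1 <- execute_query(srv, make_query_tokens("100010", "em", keys = keys))
  check("EM 100010", q1$matches$seq, 1L)
  q2 <- execute_query(srv, make_query_tokens("111", "esm", keys = keys))
  check("ESM 111", q2$matches$seq, 2L)
  q3 <- execute_query(srv, make_query_tokens("1101", "smm", keys = keys))
  check("SMM 1101", q3$matches$seq, c(2L, 3L, 4L, 5L))
  q4 <- execute_query(srv, make_query_tokens("1011", "tsmm", t = 3L, keys = keys))
  check("TSMM 1011 t=3", q4$matches$seq, c(2L, 4L, 5L))
  invisible(TRUE)
}
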