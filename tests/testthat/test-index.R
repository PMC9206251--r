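test_that("encryption is deterministic, size-preserving, and iv-sensitive", {
  keys <- fixed_keys()
  d <- table_dataset()
  rt <- hash_tree(build_trie(d), keys$salt)
  ctx <- encryption_context(keys$key, keys$iv)
  e1 <- encrypt_tree(rt, ctx)
  e2 <- encrypt_tree(rt, ctx)
  expect_identical(e1, e2)
  expect_equal(e1$n_nodes, rt$n_nodes)
  # ciphertext length equals digest length: 16 bytes = 32 hex chars for MD5
  expect_true(all(nchar(e1$value[-1L]) == 32L))
  expect_true(is.na(e1$value[1L]))  # the root (salt) is never exported
  # a different iv changes every node ciphertext
  ctx2 <- encryption_context(keys$key, as.raw(rev(as.integer(keys$iv))))
  e3 <- encrypt_tree(rt, ctx2)
  expect_true(all(e1$value[-1L] != e3$value[-1L]))
  expect_error(encryption_context(as.raw(1:8), keys$iv), "16 raw bytes")
})

test_that("every node ciphertext is findable in the index, exactly once", {
  keys <- fixed_keys()
  d <- table_dataset()
  rt <- hash_tree(build_trie(d), keys$salt)
  egst <- encrypt_tree(rt, encryption_context(keys$key, keys$iv))
  hi <- build_hash_index(egst)
  # entry count = distinct node digests (root excluded)
  expect_equal(hi$n_entries, length(unique(egst$value[-1L])))
  for (i in seq_len(egst$n_nodes)[-1L]) {
    res <- hi_lookup(hi, egst$value[i])
    expect_true(res$hit)
  }
  # random unseen token misses; flipped last bit misses at depth >= 1
  miss <- hi_lookup(hi, paste(rep("00", 16L), collapse = ""))
  expect_false(miss$hit)
  expect_gte(miss$fail_depth, 1L)
  stored <- egst$value[2L]
  flipped_raw <- privgst:::hex_to_raw(stored)
  flipped_raw[16L] <- xor(flipped_raw[16L], as.raw(1L))
  fl <- hi_lookup(hi, flipped_raw)
  expect_false(fl$hit)
  expect_gte(fl$fail_depth, 1L)
  expect_lte(fl$fail_depth, hi$k)
  expect_error(hi_lookup(hi, as.raw(1:4)), "bits")
})

test_that("index depth is k regardless of dataset size", {
  keys <- fixed_keys()
  for (n in c(2L, 8L)) {
    srv <- secure_pipeline(generate_synthetic(n, 6, seed = n), keys)
    expect_equal(srv$hi$k, 128L)
    expect_true(all(nchar(srv$hi$bits) == 128L))
  }
})

test_that("index entries reference all suffixes passing through their node", {
  keys <- fixed_keys()
  d <- table_dataset()
  srv <- secure_pipeline(d, keys)
  ctx <- encryption_context(keys$key, keys$iv)
  # every one of the 30 suffixes: its full-path + terminal token must hit
  # with exactly its own (seq, start) reference
  ref <- suffixes_from_records(d)
  for (i in seq_len(nrow(ref))) {
    tokd <- rmt_hash_string(ref$suffix[i], keys$salt, terminal = TRUE)
    res <- hi_lookup(srv$hi, privgst:::encrypt_digest(tokd, ctx))
    expect_true(res$hit)
    decoded <- do.call(rbind, lapply(res$refs, privgst:::decrypt_ref, ctx = ctx))
    expect_true(any(decoded[, 1L] == ref$seq[i] & decoded[, 2L] == ref$start[i]))
  }
})

test_that("server bundle leaks neither secrets nor record substrings", {
  keys <- fixed_keys()
  d <- generate_synthetic(5, 12, seed = 9)
  srv <- secure_pipeline(d, keys)
  f <- withr::local_tempfile(fileext = ".json")
  write_server_bundle(srv, f)
  blob <- paste(readLines(f), collapse = "")
  for (secret in list(keys$salt, keys$key, keys$iv)) {
    expect_false(grepl(paste(secret, collapse = ""), blob, fixed = TRUE))
  }
  # no raw record symbol run of length >= 8 anywhere in the bundle
  for (rec in d$records) {
    for (s in unique(substring(rec, 1:(nchar(rec) - 7), 8:nchar(rec)))) {
      expect_false(grepl(s, blob, fixed = TRUE))
    }
  }
  # round trip reproduces query behaviour
  srv2 <- read_server_bundle(f)
  d <- table_dataset()
  srv <- secure_pipeline(d, keys)
  srv2 <- read_server_bundle(write_server_bundle(srv, f))
  r1 <- execute_query(srv, make_query_tokens("1101", "smm", keys = keys))
  r2 <- execute_query(srv2, make_query_tokens("1101", "smm", keys = keys))
  expect_same_result(r1, r2)
})
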