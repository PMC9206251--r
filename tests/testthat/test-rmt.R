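test_that("string folding matches an independent fold oracle", {
  salt <- as.raw(1:16)
  # the canonical 0110 expansion: H(H(H(H(salt||H(0))||H(1))||H(1))||H(0))
  expect_identical(rmt_hash_string("0110", salt),
                   fold_oracle(c("0", "1", "1", "0"), salt))
  # base case: one fold step
  expect_identical(rmt_hash_string("0", salt), fold_oracle("0", salt))
  # terminal class folds one extra step
  expect_identical(rmt_hash_string("01", salt, terminal = TRUE),
                   fold_oracle(c("0", "1"), salt, terminal = TRUE))
  expect_error(rmt_hash_string("01$", salt), "reserved")
  expect_error(rmt_hash_string("", salt), "at least one symbol")
  expect_error(rmt_hash_string("01", as.raw(1:8)), "length")
})

test_that("digests chain over prefixes", {
  salt <- rmt_salt()
  d_prefix <- rmt_hash_string("01", salt)
  # continuing the fold from the prefix digest equals hashing the whole string
  continued <- fold_oracle(c("0", "1"), d_prefix)
  expect_identical(continued, rmt_hash_string("0101", salt))
})

test_that("every tree node's digest equals the fold of its root path", {
  salt <- fixed_keys()$salt
  d <- generate_synthetic(4, 8, seed = 17)
  g <- build_trie(d)
  rt <- hash_tree(g, salt)
  for (i in seq_len(g$n_nodes)[-1L]) {
    path <- character(0); node <- i
    while (node != 1L) { path <- c(g$symbol[node], path); node <- g$parent[node] }
    term <- path[length(path)] == "$"
    if (term) path <- path[-length(path)]
    expect_identical(rt$digest[[i]], fold_oracle(path, salt, terminal = term))
  }
  # leaf table exports one row per (seq, start) with the leaf digest
  expect_equal(nrow(rt$leaves), 4L * 8L)
})

test_that("leaf digests follow the documented suffix example", {
  d <- haplotype_dataset("010101")
  salt <- fixed_keys()$salt
  rt <- hash_tree(build_trie(d), salt)
  # the longest path carries the digest of the full suffix 010101
  full <- rt$leaves[rt$leaves$start == 1L, ]
  expect_equal(full$digest,
               paste(rmt_hash_string("010101", salt, terminal = TRUE), collapse = ""))
  # sibling leaves under distinct symbols carry distinct digests
  expect_false(anyDuplicated(rt$leaves$digest) > 0)
})

test_that("digests depend only on path and salt; salts separate", {
  salt <- as.raw(1:16)
  d1 <- generate_synthetic(3, 6, seed = 1)
  d2 <- generate_synthetic(3, 6, seed = 2)
  rt1 <- hash_tree(build_trie(d1), salt)
  rt2 <- hash_tree(build_trie(d2), salt)
  # shared root path "common prefix" -> shared digest across different trees
  path_digest <- function(rt, sym) {
    ch <- rt$children[[1L]]
    if (!sym %in% names(ch)) return(NULL)
    paste(rt$digest[[ch[[sym]]]], collapse = "")
  }
  for (s in c("0", "1")) {
    p1 <- path_digest(rt1, s); p2 <- path_digest(rt2, s)
    if (!is.null(p1) && !is.null(p2)) expect_identical(p1, p2)
  }
  # different salts change every digest
  rt3 <- hash_tree(build_trie(d1), as.raw(16:1))
  for (i in 2:rt1$n_nodes) expect_false(identical(rt1$digest[[i]], rt3$digest[[i]]))
})

test_that("bit order is stable, big-endian, and round-trips", {
  d <- rmt_hash_string("0101", as.raw(1:16))
  bits <- digest_bits(d)
  expect_length(bits, 128L)
  expect_identical(bits_to_raw(bits), d)
  expect_identical(digest_bits(as.raw(c(0, 0))), rep(0L, 16L))
  expect_identical(digest_bits(as.raw(0x80))[1L], 1L)
})

test_that("sha256 swaps k to 256 everywhere consistently", {
  keys <- fixed_keys("sha256")
  expect_length(keys$salt, 32L)
  dgst <- rmt_hash_string("0110", keys$salt, "sha256")
  expect_length(dgst, 32L)
  sha <- function(x) as.raw(openssl::sha256(x))
  expect_identical(dgst, fold_oracle(c("0", "1", "1", "0"), keys$salt, hash = sha))
  d <- table_dataset()
  srv <- outsource(build_trie(d), keys)
  expect_equal(srv$hi$k, 256L)
  res <- execute_query(srv, make_query_tokens("100010", "em", keys = keys))
  expect_equal(res$matches$seq, 1L)
})
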