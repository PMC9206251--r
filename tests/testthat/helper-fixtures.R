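# shared fixtures: all built in code, nothing loaded from disk

# the 5x6 worked-example matrix (rows 100010/111010/110001/010110/010101)
table_dataset <- function() example_dataset()

# fixed secrets so every test run is reproducible
fixed_keys <- function(hash_fn = "md5") make_keys(hash_fn, seed = 424242L)

# full owner-side pipeline: dataset -> gst -> hashed -> encrypted -> indexed
secure_pipeline <- function(dataset, keys = fixed_keys()) {
  outsource(build_trie(dataset), keys)
}

random_binary_query <- function(m, max_len = m) {
  len <- sample.int(max_len, 1L)
  paste(sample(c("0", "1"), len, replace = TRUE), collapse = "")
}

# independent reverse-Merkle fold, written against the definition only
# (never calls rmt_hash_string)
fold_oracle <- function(syms, salt, hash = function(x) as.raw(openssl::md5(x)),
                        terminal = FALSE) {
  d <- salt
  for (s in syms) d <- hash(c(d, hash(charToRaw(s))))
  if (terminal) d <- hash(c(d, hash(charToRaw("$"))))
  d
}

expect_same_result <- function(a, b) {
  expect_identical(a$status, b$status)
  expect_equal(a$matches, b$matches)
}
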