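test_that("the four worked-example queries return the printed answers", {
  keys <- fixed_keys()
  d <- table_dataset()
  srv <- secure_pipeline(d, keys)

  em <- execute_query(srv, make_query_tokens("100010", "em", keys = keys))
  expect_equal(em$matches$seq, 1L)
  expect_equal(em$matches$j1, 1L)

  esm <- execute_query(srv, make_query_tokens("111", "esm", keys = keys))
  expect_equal(unique(esm$matches$seq), 2L)

  smm <- execute_query(srv, make_query_tokens("1101", "smm", keys = keys))
  expect_setequal(unique(smm$matches$seq), c(2L, 3L, 4L, 5L))
  by_rec <- split(smm$matches$match, smm$matches$seq)
  expect_true("1101" %in% by_rec[["2"]])
  expect_true("110" %in% by_rec[["3"]])
  expect_true("101" %in% by_rec[["5"]])

  tsmm <- execute_query(srv, make_query_tokens("1011", "tsmm", t = 3, keys = keys))
  expect_setequal(unique(tsmm$matches$seq), c(2L, 4L, 5L))
  expect_equal(tsmm$matches$j1[tsmm$matches$seq == 2L], 3L)   # 101 from position 3
  expect_equal(tsmm$matches$j1[tsmm$matches$seq == 4L], 2L)   # whole query from position 2
  expect_equal(tsmm$matches$length[tsmm$matches$seq == 4L], 4L)
})

test_that("token enumeration walks substrings by decreasing length with offsets", {
  keys <- fixed_keys()
  eq <- make_query_tokens("1101", "smm", keys = keys)
  expect_equal(eq$floor, 3L)  # ceiling((4+1)/2)
  expect_equal(eq$tokens$sub, c("1101", "110", "101"))
  expect_equal(eq$tokens$length, c(4L, 3L, 3L))
  expect_equal(eq$tokens$offset, c(1L, 1L, 2L))

  one <- make_query_tokens("1", "esm", keys = keys)
  expect_equal(nrow(one$tokens), 1L)

  tk <- make_query_tokens("1011", "tsmm", t = 2, keys = keys)
  expect_true(all(tk$tokens$length >= 2L))
  expect_error(make_query_tokens("1011", "tsmm", keys = keys), "threshold")
  expect_error(make_query_tokens("1011", "tsmm", t = 9, keys = keys), "outside")
  expect_error(make_query_tokens("", "em", keys = keys), "at least one symbol")

  # wire form carries ciphertext and length only — no plaintext symbols
  w <- wire_tokens(eq)
  expect_named(w, c("ct", "length"))
  expect_false(any(grepl("^[01]+$", w$ct)))
})

test_that("secure execution equals the plaintext oracle on random instances", {
  keys <- fixed_keys()
  set.seed(202)
  for (rep in 1:8) {
    d <- generate_synthetic(sample(5:12, 1), sample(5:12, 1), seed = 3000 + rep)
    srv <- secure_pipeline(d, keys)
    for (j in 1:6) {
      q <- random_binary_query(d$m)
      kind <- sample(c("em", "esm", "smm", "tsmm"), 1)
      t <- if (kind == "tsmm") sample.int(nchar(q), 1) else NULL
      sec <- execute_query(srv, make_query_tokens(q, kind, t = t, keys = keys))
      ora <- plaintext_oracle(d, q, kind, t = t)
      expect_same_result(sec, ora)
    }
  }
})

test_that("oracle reproduces definition edge cases", {
  d <- table_dataset()
  # EM on a shorter query cannot match a full record
  expect_equal(plaintext_oracle(d, "111", "em")$status, "miss")
  # absent substring everywhere at floor length -> miss
  expect_equal(plaintext_oracle(d, "0000", "tsmm", t = 4)$status, "miss")
  # all occurrences are reported per record, ordered by j1
  r <- plaintext_oracle(d, "01", "esm")
  expect_true(all(diff(r$matches$j1[r$matches$seq == 5L]) > 0))
  expect_equal(sum(r$matches$seq == 5L), 3L)  # 010101 contains 01 at 1,3,5
})

test_that("query-kind relations hold", {
  keys <- fixed_keys()
  d <- table_dataset()
  srv <- secure_pipeline(d, keys)
  # EM hit implies ESM hit for the same full-width query
  em <- execute_query(srv, make_query_tokens("010101", "em", keys = keys))
  esm <- execute_query(srv, make_query_tokens("010101", "esm", keys = keys))
  expect_equal(em$status, "hit")
  expect_true(all(em$matches$seq %in% esm$matches$seq))
  # TSMM result set non-increasing in t
  prev <- NULL
  for (t in 1:4) {
    got <- unique(execute_query(srv, make_query_tokens("1011", "tsmm", t = t,
                                                       keys = keys))$matches$seq)
    if (!is.null(prev)) expect_true(all(got %in% prev))
    prev <- got
  }
  # TSMM at t=|q| keeps only full-length matches, i.e. ESM hits
  full <- execute_query(srv, make_query_tokens("1011", "tsmm", t = 4, keys = keys))
  esm2 <- execute_query(srv, make_query_tokens("1011", "esm", keys = keys))
  expect_equal(full$matches[, c("seq", "j1", "j2")], esm2$matches[, c("seq", "j1", "j2")])
})

test_that("a foreign keyfile manifests as a universal miss", {
  d <- table_dataset()
  srv <- secure_pipeline(d, fixed_keys())
  other <- make_keys(seed = 777L)
  for (kind in c("em", "esm", "smm")) {
    res <- execute_query(srv, make_query_tokens("100010", kind, keys = other))
    expect_equal(res$status, "miss")
  }
})

test_that("smm floor is adjustable and defaults per query length", {
  keys <- fixed_keys()
  d <- table_dataset()
  srv <- secure_pipeline(d, keys)
  # with floor 2, record 1 (best shared substring '10' or '01') joins the set
  res <- execute_query(srv, make_query_tokens("1101", "smm", keys = keys, min_match = 2))
  expect_true(1L %in% res$matches$seq)
  ora <- plaintext_oracle(d, "1101", "smm", min_match = 2)
  expect_same_result(res, ora)
})
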