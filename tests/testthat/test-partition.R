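test_that("partition plans tile the matrix exactly and balance block sizes", {
  pl <- plan_partition(100, 100, 4, "bidirectional")
  expect_equal(nrow(pl$blocks), 4L)
  expect_true(all(pl$blocks$row2 - pl$blocks$row1 + 1L == 50L))
  expect_true(all(pl$blocks$col2 - pl$blocks$col1 + 1L == 50L))

  ph <- plan_partition(1000, 1000, 4, "horizontal")
  expect_true(all(ph$blocks$row2 - ph$blocks$row1 + 1L == 250L))
  expect_true(all(ph$blocks$col1 == 1L & ph$blocks$col2 == 1000L))

  p1 <- plan_partition(5, 6, 1, "horizontal")
  expect_equal(nrow(p1$blocks), 1L)
  expect_length(p1$schedule, 0L)

  expect_error(plan_partition(10, 10, 2, "bidirectional"), "p >= 4")
  expect_error(plan_partition(10, 10, 5, "bidirectional"), "factor")

  # exact tiling, no overlap, no gap, for uneven splits
  for (args in list(list(7, 9, 3, "horizontal"), list(9, 7, 3, "vertical"),
                    list(9, 9, 6, "bidirectional"))) {
    pl <- do.call(plan_partition, args)
    cells <- unlist(lapply(seq_len(nrow(pl$blocks)), function(i) {
      b <- pl$blocks[i, ]
      outer((b$row1:b$row2 - 1L) * args[[2]], b$col1:b$col2, "+")
    }))
    expect_setequal(cells, unlist(outer((seq_len(args[[1]]) - 1L) * args[[2]],
                                        seq_len(args[[2]]), "+")))
    expect_equal(length(cells), args[[1]] * args[[2]])
  }
})

test_that("path-graph extension closes truncated suffixes without duplication", {
  # one sequence 010101 split 010|101: block suffixes extended by tail 101
  d <- haplotype_dataset("010101")
  blk <- build_trie(d, span = c(1, 3), pending = TRUE)
  expect_equal(nrow(enumerate_suffixes(blk)), 0L)  # nothing terminal yet
  ext <- extend_with_path_graphs(blk, path_graphs(d, 3))
  expect_setequal(enumerate_suffixes(ext)$suffix, c("010101", "10101", "0101"))
  # the tail-side tree contributes the remaining suffixes; merged = serial
  tail_tree <- build_trie(d, span = c(4, 6))
  expect_true(gst_equal(merge_gst(ext, tail_tree), build_trie(d)))

  # zero-length tail is the identity on terminal marks
  full <- build_trie(d)
  expect_true(gst_equal(extend_with_path_graphs(full, path_graphs(d, 6)), full))

  # missing tail is a consistency error
  expect_error(extend_with_path_graphs(blk, list()), "missing path graph")
})

test_that("extension + merge reproduces the serial suffix set on random data", {
  d <- generate_synthetic(4, 8, seed = 77)
  left <- extend_with_path_graphs(build_trie(d, span = c(1, 4), pending = TRUE),
                                  path_graphs(d, 4))
  right <- build_trie(d, span = c(5, 8))
  merged <- merge_gst(left, right)
  expect_equal(enumerate_suffixes(merged), enumerate_suffixes(build_trie(d)))
})

test_that("merge is commutative, associative, duplicate-free, ref-conserving", {
  d <- table_dataset()
  t1 <- build_trie(d, rows = 1:2)
  t2 <- build_trie(d, rows = 3:4)
  t3 <- build_trie(d, rows = 5)
  expect_true(gst_equal(merge_gst(t1, t2), merge_gst(t2, t1)))
  expect_true(gst_equal(merge_gst(merge_gst(t1, t2), t3),
                        merge_gst(t1, merge_gst(t2, t3))))
  m <- merge_gst(merge_gst(t1, t2), t3)
  expect_true(gst_equal(m, build_trie(d)))
  for (ch in m$children) if (!is.null(ch)) expect_false(anyDuplicated(names(ch)) > 0)
  # leaf-ref multiset conserved
  nref <- function(g) sum(vapply(g$refs, function(r) if (is.null(r)) 0L else nrow(r), integer(1)))
  expect_equal(nref(m), nref(t1) + nref(t2) + nref(t3))
  # inputs unmodified
  expect_equal(nrow(enumerate_suffixes(t1)), 12L)
  expect_error(merge_gst(t1, build_trie(generate_synthetic(2, 6, "nucleotide", 1))),
               "alphabet mismatch")
})

test_that("parallel build equals serial build for the documented examples", {
  d <- table_dataset()
  serial <- build_trie(d)
  expect_true(gst_equal(build_parallel(d, plan_partition(5, 6, 2, "horizontal")), serial))

  d2 <- haplotype_dataset(c("010101", "101010"))
  expect_true(gst_equal(build_parallel(d2, plan_partition(2, 6, 2, "vertical")),
                        build_trie(d2)))

  d16 <- generate_synthetic(16, 16, seed = 20)
  expect_true(gst_equal(build_parallel(d16, plan_partition(16, 16, 4, "bidirectional")),
                        build_trie(d16)))
})

test_that("forked block builds through the spool agree with in-process builds", {
  skip_on_os("windows")
  d <- generate_synthetic(8, 8, seed = 4)
  pl <- plan_partition(8, 8, 2, "horizontal")
  spool <- withr::local_tempdir()
  g <- build_parallel(d, pl, workers = 2L, spool = spool)
  expect_true(gst_equal(g, build_trie(d)))
  # the communication contract: one serialized tree file per block
  expect_length(list.files(spool, pattern = "^block-"), 2L)
})
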