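test_that("abundance tables parse in both orientations and agree", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "samples.tsv")
  writeLines(c("sample_id\ttaxA\ttaxB", "s1\t5\t0", "s2\t2\t1", "s3\t0\t7"), f1)
  tbl <- read_abundance(f1)
  expect_equal(nrow(tbl), 3)
  expect_equal(taxon_names <- setdiff(names(tbl), "sample_id"), c("taxA", "taxB"))
  expect_equal(tbl$taxA, c(5, 2, 0))

  f2 <- file.path(dir, "taxa.tsv")
  writeLines(c("taxon_id\ts1\ts2\ts3", "taxA\t5\t2\t0", "taxB\t0\t1\t7"), f2)
  tbl2 <- read_abundance(f2, orientation = "taxa_as_rows")
  expect_equal(tbl2, tbl)

  f3 <- file.path(dir, "samples.csv")
  writeLines(c("sample_id,taxA,taxB", "s1,5,0", "s2,2,1", "s3,0,7"), f3)
  expect_equal(read_abundance(f3), tbl)
})

test_that("invalid tables are rejected with informative errors", {
  dir <- withr::local_tempdir()
  dup <- file.path(dir, "dup.tsv")
  writeLines(c("sample_id\ttaxA\ttaxA", "s1\t1\t2", "s2\t3\t4"), dup)
  expect_error(read_abundance(dup), "taxA")

  neg <- file.path(dir, "neg.tsv")
  writeLines(c("sample_id\ttaxA\ttaxB", "s1\t1\t-2", "s2\t3\t4"), neg)
  expect_error(read_abundance(neg), "s1.*taxB")

  chr <- file.path(dir, "chr.tsv")
  writeLines(c("sample_id\ttaxA\ttaxB", "s1\t1\tx", "s2\t3\t4"), chr)
  expect_error(read_abundance(chr), "taxB")

  dup_s <- file.path(dir, "dups.tsv")
  writeLines(c("sample_id\ttaxA", "s1\t1", "s1\t2"), dup_s)
  expect_error(read_abundance(dup_s), "s1")
})

test_that("prevalence filter keeps exactly the taxa observed often enough", {
  # 10 samples; t1 nonzero in 7 samples, t2 in 10, t3 in 0
  tbl <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:10),
    t1 = c(rep(2, 7), 0, 0, 0),
    t2 = rep(1, 10),
    t3 = rep(0, 10)
  )
  expect_equal(setdiff(names(filter_prevalence(tbl, 7)), "sample_id"), c("t1", "t2"))
  expect_equal(setdiff(names(filter_prevalence(tbl, 8)), "sample_id"), "t2")
  expect_equal(setdiff(names(filter_prevalence(tbl, 1)), "sample_id"), c("t1", "t2"))
  expect_error(filter_prevalence(tbl, 11), "lower")
  # default threshold targets prevalence in >= 15 samples
  expect_equal(formals(filter_prevalence)$min_samples, 15)
})

test_that("prevalence filtering is idempotent and monotone in the threshold", {
  tbl <- random_count_table(20, 12, seed = 42, mu = 2, size = 0.3)
  for (ms in c(1, 5, 10)) {
    once <- filter_prevalence(tbl, ms)
    expect_identical(filter_prevalence(once, ms), once)
  }
  kept <- vapply(1:12, function(ms) {
    res <- tryCatch(filter_prevalence(tbl, ms), error = function(e) NULL)
    if (is.null(res)) 0L else length(setdiff(names(res), "sample_id"))
  }, integer(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("networks round-trip through both on-disk formats", {
  dir <- withr::local_tempdir()
  # path a-b-c as adjacency: symmetric with exactly 4 off-diagonal ones
  path3 <- mb_network(c("a", "b", "c"),
                      tibble::tibble(from = c("a", "b"), to = c("b", "c")))
  fa <- file.path(dir, "adj.tsv")
  write_network(path3, fa, format = "adjacency_matrix")
  mat <- as.matrix(readr::read_tsv(fa, show_col_types = FALSE)[, -1])
  expect_equal(sum(mat), 4)
  expect_equal(mat, t(mat), ignore_attr = TRUE)
  expect_equal(edge_keys(read_adjacency(fa)), edge_keys(path3))

  # empty network: edge list with header only
  empty <- mb_network(c("a", "b"))
  fe <- file.path(dir, "empty.tsv")
  write_network(empty, fe, format = "edge_list")
  expect_equal(length(readLines(fe)), 1)
  expect_equal(n_edges(read_edge_list(fe, node_ids = c("a", "b"))), 0)

  for (seed in 1:5) {
    net <- random_network(sprintf("n%02d", 1:8), prob = 0.4, seed = seed)
    f1 <- file.path(dir, "el.tsv"); f2 <- file.path(dir, "am.tsv")
    write_network(net, f1, "edge_list")
    write_network(net, f2, "adjacency_matrix")
    expect_equal(edge_keys(read_edge_list(f1, node_ids = net$nodes)), edge_keys(net))
    expect_equal(edge_keys(read_adjacency(f2)), edge_keys(net))
  }
})

test_that("adjacency input is symmetrized by OR with a warning", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "asym.tsv")
  writeLines(c("id\ta\tb\tc", "a\t0\t1\t0", "b\t0\t0\t0", "c\t0\t0\t0"), f)
  expect_warning(net <- read_adjacency(f), "symmetriz")
  expect_equal(edge_keys(net), "a|b")

  # identity matrix: diagonal ignored, no edges
  fi <- file.path(dir, "id.tsv")
  writeLines(c("id\ta\tb", "a\t1\t0", "b\t0\t1"), fi)
  expect_equal(n_edges(read_adjacency(fi)), 0)

  # dense off-diagonal on 4 nodes: choose(4, 2) edges
  fd <- file.path(dir, "dense.tsv")
  m <- matrix(1, 4, 4); diag(m) <- 0
  writeLines(c(paste(c("id", letters[1:4]), collapse = "\t"),
               vapply(1:4, function(i) paste(c(letters[i], m[i, ]), collapse = "\t"),
                      character(1))), fd)
  expect_equal(n_edges(read_adjacency(fd)), choose(4, 2))

  # non-square or mislabeled matrices are rejected
  fb <- file.path(dir, "bad.tsv")
  writeLines(c("id\ta\tb\tc", "a\t0\t1\t0", "b\t1\t0\t0"), fb)
  expect_error(read_adjacency(fb), "square")
})

test_that("edges are stored canonically regardless of input order", {
  n1 <- mb_network(c("b", "a", "c"), tibble::tibble(from = "c", to = "a"))
  n2 <- mb_network(c("b", "a", "c"), tibble::tibble(from = "a", to = "c"))
  expect_identical(n1$edges, n2$edges)
  expect_error(mb_network(c("a", "b"), tibble::tibble(from = "a", to = "a")),
               "self-loop")
  expect_error(mb_network(c("a", "a")), "duplicate")
})
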