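test_that("GMT files parse with member deduplication and validation", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc one\tG1\tG2\tG2",
               "T2\tdesc two\tG3\tG4"), path)
  coll <- read_gmt(path, axis = "gene")
  expect_equal(length(coll), 2L)
  expect_identical(coll$terms$T1$members, c("G1", "G2"))
  expect_equal(coll$terms$T2$name, "desc two")

  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(0), empty)
  expect_warning(coll0 <- read_gmt(empty), "empty")
  expect_equal(length(coll0), 0L)

  dup <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\ta\tG1", "T1\tb\tG2"), dup)
  expect_error(read_gmt(dup), "T1")

  short <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tonly-two-fields"), short)
  expect_error(read_gmt(short), "fewer than 3")
})

test_that("GMT writing round-trips a collection", {
  coll <- geneset_collection(list(
    A = list(name = "alpha", members = c("G1", "G2")),
    B = list(name = "beta", members = c("G2", "G3", "G4"))), axis = "gene")
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(coll, path)
  expect_identical(read_gmt(path, axis = "gene"), coll)
})

test_that("ora reproduces the exact hypergeometric tail", {
  universe <- sprintf("G%02d", 1:10)
  coll <- geneset_collection(
    list(term = list(name = "t", members = universe[1:4])), axis = "gene")
  res <- ora(universe[c(1, 2, 3, 9, 10)], coll, universe)  # k=3, K=4, n=5
  expect_equal(res$p_value, 66 / 252, tolerance = 1e-12)
  expect_equal(res$k, 3L)
  expect_equal(res$adjusted_p, res$p_value)  # single term: BH is identity

  # zero overlap: P(X >= 0) = 1
  res0 <- ora(universe[9:10], coll, universe)
  expect_equal(res0$p_value, 1)
  # term covering the universe: overlap is forced, p = 1
  collN <- geneset_collection(
    list(all = list(name = "a", members = universe)), axis = "gene")
  expect_equal(ora(universe[1:5], collN, universe)$p_value, 1)
})

test_that("ora matches exhaustive enumeration for all small configurations", {
  for (N in 3:8) {
    universe <- sprintf("x%02d", 1:N)
    for (K in 1:N) {
      for (n in 1:N) {
        # query drawing k members from the term and n-k from outside
        for (k in max(0, n - (N - K)):min(K, n)) {
          query <- c(universe[seq_len(k)],
                     universe[K + seq_len(n - k)])
          coll <- geneset_collection(
            list(tm = list(name = "tm", members = universe[1:K])), "gene")
          expect_equal(ora(query, coll, universe)$p_value,
                       hyper_tail_oracle(N, K, n, k), tolerance = 1e-12,
                       info = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("ora p-values are non-increasing in the overlap", {
  N <- 20; K <- 8; n <- 10
  universe <- sprintf("x%02d", 1:N)
  coll <- geneset_collection(
    list(tm = list(name = "tm", members = universe[1:K])), "gene")
  ps <- vapply(0:8, function(k) {
    query <- c(universe[seq_len(k)], universe[K + seq_len(n - k)])
    ora(query, coll, universe)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("BH adjustment and ordering behave as specified", {
  universe <- sprintf("x%02d", 1:30)
  terms <- list(
    t1 = list(name = "a", members = universe[1:10]),
    t2 = list(name = "b", members = universe[5:20]),
    t3 = list(name = "c", members = universe[25:30]),
    t4 = list(name = "d", members = c("notin1", "notin2")))  # K = 0, dropped
  coll <- geneset_collection(terms, "gene")
  res <- ora(universe[1:8], coll, universe)
  expect_false("t4" %in% res$term_id)
  expect_true(all(res$adjusted_p >= res$p_value - 1e-15))
  expect_true(!is.unsorted(res$p_value))
  # BH monotone after sorting by raw p
  expect_true(!is.unsorted(res$adjusted_p))

  # permuting term order changes nothing in the sorted output
  res2 <- ora(universe[1:8], geneset_collection(rev(terms), "gene"), universe)
  expect_equal(res, res2)

  expect_error(ora(universe[1:3], coll, character(0)), "empty universe")
  expect_error(suppressMessages(ora("zzz", coll, universe)), "empty query")
  expect_message(ora(c("zzz", universe[1:3]), coll, universe), "dropped")
})

test_that("meta-bicluster enrichment ranks the matching term first", {
  universe <- sprintf("G%05d", 1:200)
  truth_members <- universe[1:15]
  terms <- c(list(truth = list(name = "truth", members = truth_members)),
             withr::with_seed(31, stats::setNames(lapply(1:20, function(i)
               list(name = sprintf("noise %d", i),
                    members = sample(universe, 15))),
               sprintf("noise_%d", 1:20))))
  gene_sets <- geneset_collection(terms, "gene")
  trait_universe <- sprintf("T%04d", 1:50)
  trait_sets <- geneset_collection(
    list(truth_t = list(name = "tt", members = trait_universe[1:5])), "trait")
  meta <- structure(list(label = "C1", member_ids = "BC00001",
                         gene_union = truth_members,
                         trait_union = trait_universe[1:5],
                         gene_frequency = NULL, trait_frequency = NULL),
                    class = "meta_bicluster")
  res <- enrich_meta(list(meta), gene_sets, trait_sets,
                     universe, trait_universe)
  top_gene <- res[res$axis == "gene", ][1, ]
  expect_equal(top_gene$term_id, "truth")
  expect_lt(top_gene$adjusted_p, 0.05)
  expect_equal(res[res$axis == "trait", ][1, "term_id"], "truth_t")

  # disjoint union: every k = 0, every p = 1
  meta2 <- meta; meta2$gene_union <- universe[100:120]
  res2 <- enrich_meta(list(meta2), geneset_collection(
    list(tm = list(name = "t", members = universe[1:10])), "gene"),
    trait_sets, universe, trait_universe)
  expect_true(all(res2[res2$axis == "gene", "p_value"] == 1))

  # identical unions give identical tables
  res3 <- enrich_meta(list(meta, meta), gene_sets, trait_sets,
                      universe, trait_universe)
  g <- res3[res3$axis == "gene", ]
  half <- nrow(g) / 2
  expect_equal(g[seq_len(half), -1], g[half + seq_len(half), -1],
               ignore_attr = TRUE)
})
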