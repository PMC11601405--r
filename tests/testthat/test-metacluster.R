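make_set <- function(gene_sets, trait_sets = NULL, n_traits = 10,
                     n_genes = 50) {
  n <- length(gene_sets)
  if (is.null(trait_sets)) trait_sets <- rep(list(1:2), n)
  bcs <- lapply(seq_len(n), function(i)
    list(id = sprintf("BC%05d", i), traits = sort(trait_sets[[i]]),
         genes = sort(gene_sets[[i]])))
  structure(list(biclusters = bcs,
                 trait_ids = sprintf("T%04d", seq_len(n_traits)),
                 gene_ids = sprintf("G%05d", seq_len(n_genes)),
                 params = list()),
            class = "bicluster_set")
}

test_that("filtering keeps biclusters by gene count and trait of interest", {
  set <- make_set(list(1:5, 1:12, 10:24),
                  trait_sets = list(1:2, c(3L, 4L), 5:6))
  kept <- filter_biclusters(set, min_genes = 10,
                            required_trait_ids = "T0003")
  expect_equal(vapply(kept$biclusters, `[[`, character(1), "id"), "BC00002")

  expect_equal(length(filter_biclusters(set, min_genes = 0)), 3L)
  expect_equal(length(filter_biclusters(set, min_genes = 100)), 0L)
  # regex selection is an alternative to explicit ids
  kept2 <- filter_biclusters(set, min_genes = 0, trait_pattern = "^T000[12]$")
  expect_equal(length(kept2), 1L)
})

test_that("jaccard follows the set definition", {
  expect_equal(jaccard(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard(1:3, 1:3), 1.0)
  expect_equal(jaccard(1:3, 4:6), 0.0)
  expect_equal(jaccard(character(0), character(0)), 0)
})

test_that("pairwise similarity is symmetric with unit diagonal", {
  set <- make_set(list(1:10, 1:10, 21:30, c(1:5, 21:25)))
  sim <- pairwise_similarity(set)
  expect_equal(diag(sim), stats::setNames(rep(1, 4), rownames(sim)))
  expect_equal(sim, t(sim))
  expect_equal(sim["BC00001", "BC00002"], 1.0)
  expect_equal(sim["BC00001", "BC00003"], 0.0)
  expect_equal(sim["BC00001", "BC00004"], jaccard(1:10, c(1:5, 21:25)))
  expect_error(pairwise_similarity(make_set(list(1:3))), "at least 2")
})

test_that("average linkage merges the closest pair first", {
  # d(A,B) = 0.1, d(A,C) = 0.9, d(B,C) = 0.8 -> k = 2 gives {A,B} {C}
  sim <- matrix(c(1, 0.9, 0.1,
                  0.9, 1, 0.2,
                  0.1, 0.2, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  labels <- average_linkage_cluster(sim, k = 2)
  expect_equal(as.vector(labels), c("C1", "C1", "C2"))

  expect_equal(length(unique(average_linkage_cluster(sim, k = 3))), 3L)
  expect_equal(length(unique(average_linkage_cluster(sim, k = 1))), 1L)
  expect_error(average_linkage_cluster(sim, k = 4), "between 1")
})

test_that("equal-distance merges break ties toward the lowest member index", {
  # three mutually equidistant points: first merge must join members 1 and 2
  sim <- matrix(0.5, 4, 4); diag(sim) <- 1
  labels <- average_linkage_cluster(sim, k = 3)
  expect_equal(as.vector(labels), c("C1", "C1", "C2", "C3"))
  merges <- attr(average_linkage_cluster(sim, k = 1), "merges")
  expect_equal(merges$a[1], 1)
  expect_equal(merges$b[1], 2)
})

test_that("clustering matches hclust/cutree partitions on random distances", {
  for (seed in 1:15) {
    n <- 6 + (seed %% 10)
    d <- withr::with_seed(seed + 900, {
      m <- matrix(stats::runif(n * n, 0.05, 1), n, n)
      m[lower.tri(m)] <- t(m)[lower.tri(m)]
      diag(m) <- 0
      m
    })
    sim <- 1 - d
    dimnames(sim) <- list(sprintf("B%02d", 1:n), sprintf("B%02d", 1:n))
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    for (k in 1:n) {
      mine <- average_linkage_cluster(sim, k)
      ref <- stats::cutree(hc, k)
      expect_identical(partition_key(mine), partition_key(ref),
                       info = sprintf("seed %d, k %d", seed, k))
    }
  }
})

test_that("cuts are nested: k-1 groups arise by merging two of the k groups", {
  sim <- 1 - withr::with_seed(321, {
    m <- matrix(stats::runif(64, 0, 0.9), 8, 8)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    m
  })
  dimnames(sim) <- list(sprintf("B%d", 1:8), sprintf("B%d", 1:8))
  prev <- average_linkage_cluster(sim, 8)
  for (k in 7:1) {
    cur <- average_linkage_cluster(sim, k)
    # every current group is a union of previous groups, and exactly one
    # pair of previous groups was merged
    tab <- table(prev, cur)
    expect_true(all(rowSums(tab > 0) == 1))
    expect_equal(sum(colSums(tab > 0) == 2), 1)
    prev <- cur
  }
})

test_that("zero cross-family gene overlap separates families at k = 2", {
  sets <- withr::with_seed(5, c(
    lapply(1:4, function(i) sort(sample(1:20, 8))),
    lapply(1:4, function(i) sort(sample(26:50, 8)))))
  set <- make_set(sets)
  labels <- average_linkage_cluster(pairwise_similarity(set), k = 2)
  expect_equal(length(unique(labels[1:4])), 1L)
  expect_equal(length(unique(labels[5:8])), 1L)
  expect_false(labels[1] == labels[5])
})

test_that("meta-bicluster summaries count genes and traits per group", {
  set <- make_set(list(c(1, 2), c(2, 3)), trait_sets = list(1:2, 2:3))
  metas <- summarize_meta(set, stats::setNames(c("C1", "C1"),
                                               c("BC00001", "BC00002")))
  expect_equal(length(metas), 1L)
  m <- metas[[1]]
  expect_equal(m$gene_union, sprintf("G%05d", 1:3))
  expect_equal(m$gene_frequency[["G00002"]], 2L)
  expect_equal(m$gene_frequency[["G00001"]], 1L)
  expect_equal(m$trait_frequency[["T0002"]], 2L)
  expect_equal(names(m$gene_frequency)[1], "G00002")  # sorted by count

  singleton <- summarize_meta(make_set(list(5:8)), c(BC00001 = "C1"))
  expect_equal(singleton[[1]]$gene_union, sprintf("G%05d", 5:8))

  expect_error(summarize_meta(set, c(BC00001 = "C1")), "cover")
})
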