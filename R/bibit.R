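#' @useDynLib twasbiclust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.new_bicluster_set <- function(biclusters, trait_ids, gene_ids, params) {
  structure(list(biclusters = biclusters,
                 trait_ids = trait_ids,
                 gene_ids = gene_ids,
                 params = params),
            class = "bicluster_set")
}

#' @export
print.bicluster_set <- function(x, ...) {
  cat(sprintf("bicluster_set: %d bicluster(s) over %d traits x %d genes\n",
              length(x$biclusters), length(x$trait_ids), length(x$gene_ids)))
  if (length(x$biclusters) > 0) {
    nt <- vapply(x$biclusters, function(b) length(b$traits), integer(1))
    ng <- vapply(x$biclusters, function(b) length(b$genes), integer(1))
    cat(sprintf("  traits per bicluster: %d-%d; genes per bicluster: %d-%d\n",
                min(nt), max(nt), min(ng), max(ng)))
  }
  invisible(x)
}

#' @export
length.bicluster_set <- function(x) length(x$biclusters)

#' @export
as.data.frame.bicluster_set <- function(x, ...) {
  if (length(x$biclusters) == 0) {
    return(data.frame(id = character(), n_traits = integer(),
                      n_genes = integer(), trait_ids = character(),
                      gene_ids = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    id = vapply(x$biclusters, `[[`, character(1), "id"),
    n_traits = vapply(x$biclusters, function(b) length(b$traits), integer(1)),
    n_genes = vapply(x$biclusters, function(b) length(b$genes), integer(1)),
    trait_ids = vapply(x$biclusters, function(b)
      paste(x$trait_ids[b$traits], collapse = ","), character(1)),
    gene_ids = vapply(x$biclusters, function(b)
      paste(x$gene_ids[b$genes], collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
}

.finalize_biclusters <- function(raw, bin, params) {
  bcs <- vector("list", length(raw$traits))
  for (i in seq_along(bcs)) {
    bcs[[i]] <- list(id = sprintf("BC%05d", i),
                     traits = sort(as.integer(raw$traits[[i]])),
                     genes = sort(as.integer(raw$genes[[i]])))
  }
  trait_ids <- rownames(bin)
  gene_ids <- colnames(bin)
  if (is.null(trait_ids)) trait_ids <- sprintf("T%04d", seq_len(nrow(bin)))
  if (is.null(gene_ids)) gene_ids <- sprintf("G%05d", seq_len(ncol(bin)))
  .new_bicluster_set(bcs, trait_ids, gene_ids, params)
}

#' Enumerate all-ones biclusters with the BiBit algorithm
#'
#' A bicluster is a pair of a trait subset and a gene subset such that every
#' covered cell of the binary matrix is 1. BiBit seeds candidate gene
#' patterns from the bitwise AND of every unordered pair of trait rows,
#' keeps patterns with at least `mnc` set bits, extends each new pattern to
#' all rows that contain it, and emits the bicluster when at least `mnr`
#' rows support the pattern. Each distinct gene pattern is emitted once (its
#' supporting row set is a deterministic function of the pattern).
#'
#' Traits are rows and seed the patterns over genes, matching the usual
#' traits-by-genes orientation of TWAS association matrices; transpose the
#' input to run the other way.
#'
#' @param bin a `binary_matrix` from [binarize()], or any logical matrix.
#' @param mnr minimum number of rows (traits) per bicluster, at least 2 —
#'   patterns are seeded from row pairs.
#' @param mnc minimum number of columns (genes) per bicluster, at least 1.
#' @return a `bicluster_set`: list with elements `biclusters` (each a list
#'   `id`, `traits`, `genes` of 1-based indices), `trait_ids`, `gene_ids`,
#'   and `params`.
#' @references Rodriguez-Baena, Perez-Pulido & Aguilar-Ruiz (2011). A
#'   biclustering algorithm for extracting bit-patterns from binary
#'   datasets. Bioinformatics 27(19).
#' @export
run_bibit <- function(bin, mnr = 2, mnc = 2) {
  if (!is.matrix(bin) || !is.logical(bin)) {
    stop("`bin` must be a logical matrix (see binarize())")
  }
  if (nrow(bin) < 2 || ncol(bin) < 1) {
    stop("matrix must have at least 2 rows and 1 column")
  }
  if (mnr < 2) stop("`mnr` must be >= 2: patterns are seeded from row pairs")
  if (mnc < 1) stop("`mnc` must be >= 1")
  raw <- .bibit_enumerate(bin, as.integer(mnr), as.integer(mnc))
  params <- list(mnr = as.integer(mnr), mnc = as.integer(mnc),
                 threshold_used = attr(bin, "threshold"))
  .finalize_biclusters(raw, bin, params)
}

#' Brute-force bicluster enumeration (testing oracle)
#'
#' Same contract as [run_bibit()], computed with literal nested loops:
#' explicit column-by-column AND over each row pair and per-row containment
#' checks on plain logical vectors, no bit packing. Guarded to small
#' matrices; exists so the optimized path can be validated against an
#' independent implementation.
#'
#' @inheritParams run_bibit
#' @return a `bicluster_set`.
#' @export
brute_force_biclusters <- function(bin, mnr = 2, mnc = 2) {
  if (!is.matrix(bin) || !is.logical(bin)) {
    stop("`bin` must be a logical matrix")
  }
  n <- nrow(bin); m <- ncol(bin)
  if (n > 64 || m > 64) stop("brute-force oracle is limited to 64x64 matrices")
  if (n < 2 || m < 1) stop("matrix must have at least 2 rows and 1 column")
  if (mnr < 2) stop("`mnr` must be >= 2")
  if (mnc < 1) stop("`mnc` must be >= 1")
  seen <- new.env(hash = TRUE, parent = emptyenv())
  traits <- list(); genes <- list()
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      pattern <- bin[a, ] & bin[b, ]
      cols <- which(pattern)
      if (length(cols) < mnc) next
      key <- paste(cols, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      support <- integer(0)
      for (r in seq_len(n)) {
        if (all(bin[r, cols])) support <- c(support, r)
      }
      if (length(support) < mnr) next
      traits[[length(traits) + 1]] <- support
      genes[[length(genes) + 1]] <- cols
    }
  }
  params <- list(mnr = as.integer(mnr), mnc = as.integer(mnc),
                 threshold_used = attr(bin, "threshold"))
  .finalize_biclusters(list(traits = traits, genes = genes), bin, params)
}

#' Canonical representation of a bicluster set for comparison
#'
#' Returns a sorted character vector, one entry per bicluster, encoding the
#' (trait set, gene set) pair. Two bicluster sets are equal as sets iff
#' their canonical forms are identical.
#'
#' @param set a `bicluster_set`.
#' @return sorted character vector.
#' @export
canonical_biclusters <- function(set) {
  sort(vapply(set$biclusters, function(b) {
    paste0("T:", paste(sort(b$traits), collapse = ","),
           "|G:", paste(sort(b$genes), collapse = ","))
  }, character(1)))
}

#' Recovery score of found biclusters against planted truth blocks
#'
#' For each truth block, take the maximum over found biclusters of the
#' Jaccard index between the two cell sets (the Cartesian products of trait
#' and gene indices); the score is the mean of these maxima over truth
#' blocks. 1 means every planted block was recovered exactly; an empty
#' found set scores 0.
#'
#' @param found a `bicluster_set`.
#' @param truth list of planted blocks, each with integer fields
#'   `trait_indices` and `gene_indices` (as produced by
#'   [generate_planted_dataset()]).
#' @return a number in \eqn{[0, 1]}.
#' @export
match_score <- function(found, truth) {
  if (length(truth) == 0) stop("`truth` must contain at least one block")
  if (length(found$biclusters) == 0) return(0)
  per_block <- vapply(truth, function(blk) {
    bt <- blk$trait_indices; bg <- blk$gene_indices
    n_truth <- length(bt) * length(bg)
    best <- 0
    for (bc in found$biclusters) {
      inter <- length(intersect(bt, bc$traits)) * length(intersect(bg, bc$genes))
      n_found <- length(bc$traits) * length(bc$genes)
      j <- inter / (n_truth + n_found - inter)
      if (j > best) best <- j
    }
    best
  }, numeric(1))
  mean(per_block)
}

#' Write a bicluster set as JSON-lines
#'
#' One bicluster per line: `{"id", "trait_ids", "gene_ids", "n_traits",
#' "n_genes"}`.
#'
#' @param set a `bicluster_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_biclusters <- function(set, path) {
  lines <- vapply(set$biclusters, function(b) {
    jsonlite::toJSON(list(id = b$id,
                          trait_ids = set$trait_ids[b$traits],
                          gene_ids = set$gene_ids[b$genes],
                          n_traits = length(b$traits),
                          n_genes = length(b$genes)),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
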