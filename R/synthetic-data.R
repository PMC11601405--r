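#' Generate a p-value matrix with planted all-ones blocks
#'
#' Emulates the binarized structure of a biobank-scale TWAS association
#' matrix: background p-values are Uniform(0,1) (the null), an independent
#' per-cell Bernoulli(`background_sig_rate`) subset of background cells is
#' redrawn Uniform(0, `signal_p_max`) to simulate isolated significant noise,
#' and each planted block is a rectangle whose cells are all drawn
#' Uniform(0, `signal_p_max`). Binarizing at any threshold `t` with
#' `signal_p_max < t` therefore turns every planted cell into a 1, giving
#' ground truth for bicluster recovery.
#'
#' Blocks are placed sequentially along the diagonal: each block starts just
#' past the previous one, shifted back by `overlap_rows`/`overlap_cols` shared
#' indices when overlap with the previous block is requested. Overlapping
#' blocks are kept separate in the truth list (they model overlapping
#' biclusters, the motivating structure of the method).
#'
#' @param n_traits number of rows (traits).
#' @param n_genes number of columns (genes).
#' @param blocks list of block specs; each is a list (or named vector) with
#'   `rows`, `cols` and optional `overlap_rows`, `overlap_cols` (shared
#'   indices with the previous block, default 0).
#' @param signal_p_max upper bound of planted/noise p-values; must stay below
#'   any later binarization threshold. Default `1e-12`, well under the
#'   conventional TWAS threshold `5.49e-10`.
#' @param background_sig_rate per-cell probability that a background cell is
#'   significant noise, in \eqn{[0, 1)}. Default 0.01.
#' @param seed integer seed; the dataset is a pure function of the arguments.
#' @param annotation_noise_terms number of random (non-truth) terms added to
#'   each generated annotation collection. Default 0.
#' @param annotation_term_size member count of each noise term; defaults to
#'   the mean planted block size on the relevant axis.
#' @return a `synthetic_dataset`: list with `pvalues`
#'   ([association_matrix()]), `truth` (list of blocks with `trait_indices`,
#'   `gene_indices`), `gene_annotations`, `trait_annotations` (GMT-style
#'   collections aligned to the blocks; see [generate_annotations()]),
#'   `seed`, and `params`.
#' @export
generate_planted_dataset <- function(n_traits, n_genes, blocks,
                                     signal_p_max = 1e-12,
                                     background_sig_rate = 0.01,
                                     seed = 1,
                                     annotation_noise_terms = 0,
                                     annotation_term_size = NULL) {
  if (n_traits < 1 || n_genes < 1) stop("matrix dimensions must be positive")
  if (signal_p_max <= 0 || signal_p_max >= 1) stop("`signal_p_max` must be in (0, 1)")
  if (background_sig_rate < 0 || background_sig_rate >= 1) {
    stop("`background_sig_rate` must be in [0, 1)")
  }
  blocks <- lapply(blocks, as.list)
  placed <- .place_blocks(blocks, n_traits, n_genes)

  params <- list(n_traits = as.integer(n_traits), n_genes = as.integer(n_genes),
                 blocks = blocks, signal_p_max = signal_p_max,
                 background_sig_rate = background_sig_rate,
                 annotation_noise_terms = as.integer(annotation_noise_terms),
                 annotation_term_size = annotation_term_size)

  trait_ids <- sprintf("T%04d", seq_len(n_traits))
  gene_ids <- sprintf("G%05d", seq_len(n_genes))

  # one seed, deterministic sub-streams: matrix, gene terms, trait terms
  sub_seed <- function(offset) (as.integer(seed) %% 1000000L) * 1000L + offset

  vals <- withr::with_seed(sub_seed(0L), {
    v <- matrix(stats::runif(n_traits * n_genes), n_traits, n_genes)
    if (background_sig_rate > 0) {
      noise <- stats::runif(n_traits * n_genes) < background_sig_rate
      v[noise] <- stats::runif(sum(noise), 0, signal_p_max)
    }
    for (blk in placed) {
      ncell <- length(blk$trait_indices) * length(blk$gene_indices)
      v[blk$trait_indices, blk$gene_indices] <-
        stats::runif(ncell, 0, signal_p_max)
    }
    v
  })

  pvalues <- association_matrix(vals, trait_ids, gene_ids)

  mean_size <- function(field, fallback) {
    if (length(placed) == 0) return(fallback)
    round(mean(vapply(placed, function(b) length(b[[field]]), numeric(1))))
  }
  term_size_gene <- annotation_term_size %||% mean_size("gene_indices", 10L)
  term_size_trait <- annotation_term_size %||% mean_size("trait_indices", 5L)

  gene_annotations <- generate_annotations(
    placed, axis = "gene", n_noise_terms = annotation_noise_terms,
    term_size = term_size_gene, universe_size = n_genes, seed = sub_seed(1L),
    id_prefix = "G", id_width = 5L)
  trait_annotations <- generate_annotations(
    placed, axis = "trait", n_noise_terms = annotation_noise_terms,
    term_size = term_size_trait, universe_size = n_traits, seed = sub_seed(2L),
    id_prefix = "T", id_width = 4L)

  structure(list(pvalues = pvalues, truth = placed,
                 gene_annotations = gene_annotations,
                 trait_annotations = trait_annotations,
                 seed = as.integer(seed), params = params),
            class = "synthetic_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.place_blocks <- function(blocks, n_traits, n_genes) {
  placed <- list()
  r_end <- 0L; c_end <- 0L
  for (i in seq_along(blocks)) {
    blk <- blocks[[i]]
    rows <- as.integer(blk$rows %||% blk[[1]])
    cols <- as.integer(blk$cols %||% blk[[2]])
    if (is.na(rows) || is.na(cols) || rows < 1 || cols < 1) {
      stop("block ", i, ": `rows` and `cols` must be positive integers")
    }
    ov_r <- as.integer(blk$overlap_rows %||% 0L)
    ov_c <- as.integer(blk$overlap_cols %||% 0L)
    if (i == 1 && (ov_r > 0 || ov_c > 0)) {
      stop("block 1 cannot overlap a previous block")
    }
    if (ov_r >= rows + 1 || ov_c >= cols + 1 || ov_r > r_end || ov_c > c_end) {
      stop("block ", i, ": overlap exceeds available indices")
    }
    r0 <- r_end - ov_r + 1L
    c0 <- c_end - ov_c + 1L
    r_end <- r0 + rows - 1L
    c_end <- c0 + cols - 1L
    if (r_end > n_traits || c_end > n_genes) {
      stop(sprintf("block %d (rows %d-%d, cols %d-%d) exceeds the %dx%d matrix",
                   i, r0, r_end, c0, c_end, n_traits, n_genes))
    }
    placed[[i]] <- list(trait_indices = r0:r_end, gene_indices = c0:c_end)
  }
  placed
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d traits x %d genes, %d planted block(s), seed %d\n",
              nrow(x$pvalues), ncol(x$pvalues), length(x$truth), x$seed))
  invisible(x)
}

#' Generate an annotation collection aligned to planted blocks
#'
#' Builds a GMT-style collection for testing over-representation analysis:
#' one truth term per planted block, whose members are exactly that block's
#' identifiers on the chosen axis, plus `n_noise_terms` terms of
#' `term_size` members drawn uniformly from the universe. Term identifiers
#' record whether a term is truth (`truth_block_<i>`) or noise
#' (`noise_<j>`).
#'
#' @param blocks list of planted blocks (`trait_indices`, `gene_indices`).
#' @param axis `"gene"` (term members come from `gene_indices`) or
#'   `"trait"`.
#' @param n_noise_terms number of random terms to add.
#' @param term_size member count of each noise term; must not exceed
#'   `universe_size`.
#' @param universe_size size of the identifier universe on this axis.
#' @param seed integer seed for the noise terms.
#' @param id_prefix,id_width formatting of member identifiers, matching the
#'   identifiers used by [generate_planted_dataset()].
#' @return a `geneset_collection` (see [read_gmt()]); empty collection with
#'   a warning when there are no blocks and no noise terms.
#' @export
generate_annotations <- function(blocks, axis = c("gene", "trait"),
                                 n_noise_terms = 0, term_size = 10,
                                 universe_size, seed = 1,
                                 id_prefix = NULL, id_width = NULL) {
  axis <- match.arg(axis)
  if (term_size > universe_size) stop("`term_size` cannot exceed `universe_size`")
  if (n_noise_terms < 0) stop("`n_noise_terms` must be non-negative")
  if (length(blocks) == 0 && n_noise_terms == 0) {
    warning("no blocks and no noise terms: returning an empty collection")
    return(geneset_collection(list(), axis = axis))
  }
  if (is.null(id_prefix)) id_prefix <- if (axis == "gene") "G" else "T"
  if (is.null(id_width)) id_width <- if (axis == "gene") 5L else 4L
  fmt <- function(idx) sprintf(paste0(id_prefix, "%0", id_width, "d"), idx)
  field <- if (axis == "gene") "gene_indices" else "trait_indices"

  terms <- list()
  for (i in seq_along(blocks)) {
    terms[[sprintf("truth_block_%d", i)]] <- list(
      name = sprintf("planted block %d (%s axis)", i, axis),
      members = fmt(sort(blocks[[i]][[field]])))
  }
  if (n_noise_terms > 0) {
    noise <- withr::with_seed(seed, {
      lapply(seq_len(n_noise_terms), function(j)
        fmt(sort(sample.int(universe_size, term_size))))
    })
    for (j in seq_len(n_noise_terms)) {
      terms[[sprintf("noise_%d", j)]] <- list(
        name = sprintf("random term %d (%s axis)", j, axis),
        members = noise[[j]])
    }
  }
  geneset_collection(terms, axis = axis)
}

#' Write a synthetic dataset to a directory
#'
#' Writes the p-value matrix as TSV (`pvalues.tsv`), the truth blocks as
#' JSON (`truth.json`, 1-based indices), and the annotation collections as
#' GMT (`gene_annotations.gmt`, `trait_annotations.gmt`).
#'
#' @param dataset a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_association_matrix(dataset$pvalues, file.path(dir, "pvalues.tsv"))
  jsonlite::write_json(
    lapply(dataset$truth, function(b)
      list(trait_indices = b$trait_indices, gene_indices = b$gene_indices)),
    file.path(dir, "truth.json"))
  write_gmt(dataset$gene_annotations, file.path(dir, "gene_annotations.gmt"))
  write_gmt(dataset$trait_annotations, file.path(dir, "trait_annotations.gmt"))
  invisible(dir)
}
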