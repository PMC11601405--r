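#' Construct a gene-set (or trait-set) collection
#'
#' A flat collection of annotation terms, each a named identifier set —
#' the in-memory form of a GMT file. Used both for gene annotations
#' (GO-style) and trait annotations (Disease-Ontology-style).
#'
#' @param terms named list; each element is a list with `name` (description)
#'   and `members` (character vector, deduplicated). Names are term ids and
#'   must be unique.
#' @param axis `"gene"` or `"trait"`.
#' @return a `geneset_collection`.
#' @export
geneset_collection <- function(terms, axis = c("gene", "trait")) {
  axis <- match.arg(axis)
  if (length(terms) > 0) {
    .check_unique(names(terms), "term")
    empty <- vapply(terms, function(tm) length(tm$members) == 0, logical(1))
    if (any(empty)) {
      stop("term(s) with no members: ", paste(names(terms)[empty], collapse = ", "))
    }
    terms <- lapply(terms, function(tm) {
      tm$members <- unique(as.character(tm$members)); tm
    })
  }
  structure(list(terms = terms, axis = axis), class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection (%s axis): %d term(s)\n",
              x$axis, length(x$terms)))
  invisible(x)
}

#' @export
length.geneset_collection <- function(x) length(x$terms)

#' Read a GMT annotation file
#'
#' Standard GMT: one term per line, tab-separated fields `term_id`,
#' `description`, then members. Duplicate members within a term are
#' collapsed; duplicate term ids or lines with fewer than three fields are
#' errors.
#'
#' @param path path to the GMT file.
#' @param axis `"gene"` or `"trait"` (recorded on the collection).
#' @return a `geneset_collection`; an empty file yields an empty collection
#'   with a warning.
#' @export
read_gmt <- function(path, axis = c("gene", "trait")) {
  axis <- match.arg(axis)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file: ", path)
    return(geneset_collection(list(), axis = axis))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3)
  if (length(short) > 0) {
    stop("GMT line(s) with fewer than 3 fields: line ",
         paste(short, collapse = ", "))
  }
  ids <- vapply(fields, `[[`, character(1), 1)
  .check_unique(ids, "term")
  terms <- lapply(fields, function(f)
    list(name = f[2], members = unique(f[-c(1, 2)])))
  names(terms) <- ids
  geneset_collection(terms, axis = axis)
}

#' Write a collection as GMT
#'
#' @param collection a `geneset_collection`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  lines <- vapply(names(collection$terms), function(id) {
    tm <- collection$terms[[id]]
    paste(c(id, tm$name, tm$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each term of the collection for over-representation in the query
#' set. With universe size \eqn{N}, term size \eqn{K} (after intersection
#' with the universe), query size \eqn{n} and overlap \eqn{k}, the p-value
#' is the upper-tail hypergeometric probability \eqn{P(X \ge k)} (the
#' observed overlap included). Benjamini-Hochberg adjustment is applied
#' across all tested terms of the collection; terms with \eqn{K = 0} after
#' universe intersection carry no test and are dropped before adjustment.
#'
#' @param query character vector of identifiers; members outside the
#'   universe are dropped (a message reports how many).
#' @param collection a `geneset_collection`.
#' @param universe character vector, the sampling frame (e.g. all genes of
#'   the association matrix).
#' @return data frame sorted by `p_value` then `term_id`, with columns
#'   `term_id`, `name`, `k`, `K`, `n`, `N`, `p_value`, `adjusted_p`,
#'   `overlap` (comma-joined overlapping members).
#' @export
ora <- function(query, collection, universe) {
  stopifnot(inherits(collection, "geneset_collection"))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  query <- unique(as.character(query))
  dropped <- sum(!(query %in% universe))
  if (dropped > 0) {
    message(dropped, " query member(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  if (length(query) == 0) stop("empty query after universe intersection")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection$terms), function(id) {
    members <- intersect(collection$terms[[id]]$members, universe)
    K <- length(members)
    if (K == 0) return(NULL)
    hits <- intersect(query, members)
    k <- length(hits)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, name = collection$terms[[id]]$name,
               k = k, K = K, n = n, N = N, p_value = p,
               overlap = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(term_id = character(), name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      adjusted_p = numeric(), overlap = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, rows)
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$term_id),
             c("term_id", "name", "k", "K", "n", "N", "p_value",
               "adjusted_p", "overlap")]
  rownames(res) <- NULL
  res
}

#' Enrichment of meta-biclusters on both axes
#'
#' Runs [ora()] for every meta-bicluster: the gene axis tests the
#' meta-bicluster's gene union against the gene collection, the trait axis
#' tests the set of traits appearing in any member bicluster against the
#' trait collection.
#'
#' @param metas list of `meta_bicluster` objects from [summarize_meta()].
#' @param gene_sets `geneset_collection` for the gene axis.
#' @param trait_sets `geneset_collection` for the trait axis.
#' @param gene_universe,trait_universe character vectors; typically all
#'   genes/traits of the association matrix (the natural sampling frame).
#' @return data frame stacking all per-meta, per-axis results, with leading
#'   columns `meta_label` and `axis` followed by the [ora()] columns.
#' @export
enrich_meta <- function(metas, gene_sets, trait_sets,
                        gene_universe, trait_universe) {
  out <- lapply(metas, function(m) {
    g <- ora(m$gene_union, gene_sets, gene_universe)
    t_ <- ora(m$trait_union, trait_sets, trait_universe)
    g <- if (nrow(g)) cbind(meta_label = m$label, axis = "gene", g,
                            stringsAsFactors = FALSE) else NULL
    t_ <- if (nrow(t_)) cbind(meta_label = m$label, axis = "trait", t_,
                              stringsAsFactors = FALSE) else NULL
    rbind(g, t_)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(meta_label = character(), axis = character(),
                      term_id = character(), name = character(),
                      k = integer(), K = integer(), n = integer(),
                      N = integer(), p_value = numeric(),
                      adjusted_p = numeric(), overlap = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
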