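#' Filter biclusters by gene count and trait membership
#'
#' Standard pre-clustering filter: keep biclusters with at least `min_genes`
#' genes and, when a trait constraint is given, at least one trait of
#' interest (e.g. a set of asthma diagnosis codes). The constraint can be a
#' set of trait identifiers, a regular expression on trait identifiers, or
#' both; an empty constraint keeps all traits.
#'
#' @param set a `bicluster_set` from [run_bibit()].
#' @param min_genes minimum gene count (default 10).
#' @param required_trait_ids character vector of trait identifiers; a
#'   bicluster passes if it contains any of them. `NULL` disables the
#'   constraint.
#' @param trait_pattern optional regular expression matched against trait
#'   identifiers, an alternative way to select traits of interest.
#' @return a `bicluster_set` containing the surviving biclusters (original
#'   ids preserved).
#' @export
filter_biclusters <- function(set, min_genes = 10, required_trait_ids = NULL,
                              trait_pattern = NULL) {
  stopifnot(inherits(set, "bicluster_set"))
  wanted <- required_trait_ids
  if (!is.null(trait_pattern)) {
    wanted <- union(wanted, grep(trait_pattern, set$trait_ids, value = TRUE))
  }
  keep <- vapply(set$biclusters, function(b) {
    if (length(b$genes) < min_genes) return(FALSE)
    if (is.null(wanted)) return(TRUE)
    any(set$trait_ids[b$traits] %in% wanted)
  }, logical(1))
  .new_bicluster_set(set$biclusters[keep], set$trait_ids, set$gene_ids,
                     c(set$params, list(min_genes = min_genes)))
}

#' Jaccard similarity of two sets
#'
#' \eqn{|a \cap b| / |a \cup b|}; defined as 0 when both sets are empty.
#'
#' @param a,b vectors treated as sets.
#' @return a number in \eqn{[0, 1]}.
#' @export
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard similarity of biclusters over their gene sets
#'
#' @param set a `bicluster_set` with at least 2 biclusters.
#' @return a symmetric numeric matrix with unit diagonal, dimnames set to the
#'   bicluster ids.
#' @export
pairwise_similarity <- function(set) {
  stopifnot(inherits(set, "bicluster_set"))
  n <- length(set$biclusters)
  if (n < 2) stop("pairwise similarity needs at least 2 biclusters")
  ids <- vapply(set$biclusters, `[[`, character(1), "id")
  genes <- lapply(set$biclusters, `[[`, "genes")
  sim <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sim[i, j] <- sim[j, i] <- jaccard(genes[[i]], genes[[j]])
    }
  }
  dimnames(sim) <- list(ids, ids)
  sim
}

#' Group biclusters by average-linkage (UPGMA) hierarchical clustering
#'
#' Converts the similarity matrix to Jaccard distance \eqn{d = 1 - J} and
#' agglomerates greedily by minimum average inter-cluster distance, using the
#' size-weighted UPGMA update: after merging clusters \eqn{A} and \eqn{B},
#' the distance to any other cluster \eqn{C} is
#' \eqn{(|A| d_{AC} + |B| d_{BC}) / (|A| + |B|)}. The merge sequence is cut
#' when exactly `k` clusters remain.
#'
#' Ties between equally close pairs are broken deterministically: the pair
#' whose smallest original member index is lowest wins, then the pair whose
#' other smallest member index is lowest, so results are identical across
#' platforms. Group labels are `C1..Ck`, assigned in ascending order of each
#' cluster's smallest member index.
#'
#' @param sim symmetric similarity matrix from [pairwise_similarity()].
#' @param k number of groups, between 1 and `nrow(sim)` (default 10).
#' @return named character vector of group labels, one per bicluster, with
#'   attribute `merges`: a data frame of the merge sequence (step, joined
#'   members' smallest indices, merge height = average distance).
#' @export
average_linkage_cluster <- function(sim, k = 10) {
  if (!is.matrix(sim) || nrow(sim) != ncol(sim)) {
    stop("`sim` must be a square similarity matrix")
  }
  n <- nrow(sim)
  if (k < 1 || k > n) stop("`k` must be between 1 and the number of biclusters")
  if (max(abs(sim - t(sim))) > 1e-12) stop("`sim` must be symmetric")
  d <- 1 - sim
  diag(d) <- Inf

  members <- as.list(seq_len(n))   # original indices per active cluster
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  merges <- data.frame(step = integer(), a = integer(), b = integer(),
                       height = numeric())
  n_active <- n
  step <- 0L
  while (n_active > k) {
    # find the minimum-distance active pair with deterministic tie-breaking
    best <- NULL; best_d <- Inf
    idx <- which(active)
    for (ii in seq_along(idx)[-length(idx)]) {
      i <- idx[ii]
      for (j in idx[(ii + 1):length(idx)]) {
        dij <- d[i, j]
        if (dij < best_d - 1e-15) {
          best_d <- dij; best <- c(i, j)
        } else if (abs(dij - best_d) <= 1e-15 && !is.null(best)) {
          cand <- sort(c(min(members[[i]]), min(members[[j]])))
          cur <- sort(c(min(members[[best[1]]]), min(members[[best[2]]])))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    step <- step + 1L
    merges <- rbind(merges, data.frame(
      step = step, a = min(members[[i]]), b = min(members[[j]]),
      height = best_d))
    # UPGMA update into slot i, retire slot j
    for (o in which(active)) {
      if (o == i || o == j) next
      d[i, o] <- d[o, i] <-
        (sizes[i] * d[i, o] + sizes[j] * d[j, o]) / (sizes[i] + sizes[j])
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
    d[j, ] <- Inf; d[, j] <- Inf
    n_active <- n_active - 1L
  }

  clusters <- members[active]
  ord <- order(vapply(clusters, min, integer(1)))
  labels <- character(n)
  for (g in seq_along(ord)) {
    labels[clusters[[ord[g]]]] <- sprintf("C%d", g)
  }
  names(labels) <- rownames(sim)
  attr(labels, "merges") <- merges
  labels
}

#' Summarize labeled biclusters into meta-biclusters
#'
#' Per group: the member biclusters, the union of their gene sets, and
#' per-gene / per-trait frequency tables (number of member biclusters
#' containing each identifier), sorted by decreasing count then identifier.
#'
#' @param set a `bicluster_set`.
#' @param labels group labels as returned by [average_linkage_cluster()];
#'   must cover every bicluster in `set`.
#' @return list of `meta_bicluster` objects, ordered by label; each has
#'   `label`, `member_ids`, `gene_union`, `trait_union`, `gene_frequency`,
#'   `trait_frequency` (named integer vectors).
#' @export
summarize_meta <- function(set, labels) {
  stopifnot(inherits(set, "bicluster_set"))
  n <- length(set$biclusters)
  if (n == 0) stop("empty bicluster set")
  if (length(labels) != n) stop("labels must cover every bicluster")
  ids <- vapply(set$biclusters, `[[`, character(1), "id")
  if (!is.null(names(labels)) && !identical(names(labels), ids)) {
    labels <- labels[ids]
    if (anyNA(labels)) stop("labels must cover every bicluster")
  }
  freq_table <- function(id_lists) {
    tab <- table(unlist(id_lists))
    counts <- as.integer(tab)
    nm <- names(tab)
    ord <- order(-counts, nm)
    stats::setNames(counts[ord], nm[ord])
  }
  ulabs <- unique(labels)
  ulabs <- if (all(grepl("^C[0-9]+$", ulabs))) {
    ulabs[order(as.integer(sub("^C", "", ulabs)))]
  } else sort(ulabs)
  out <- lapply(ulabs, function(lab) {
    sel <- set$biclusters[labels == lab]
    gene_lists <- lapply(sel, function(b) set$gene_ids[b$genes])
    trait_lists <- lapply(sel, function(b) set$trait_ids[b$traits])
    structure(list(
      label = lab,
      member_ids = vapply(sel, `[[`, character(1), "id"),
      gene_union = sort(unique(unlist(gene_lists))),
      trait_union = sort(unique(unlist(trait_lists))),
      gene_frequency = freq_table(gene_lists),
      trait_frequency = freq_table(trait_lists)),
      class = "meta_bicluster")
  })
  out
}

#' @export
print.meta_bicluster <- function(x, ...) {
  cat(sprintf("meta_bicluster %s: %d bicluster(s), %d genes, %d traits\n",
              x$label, length(x$member_ids), length(x$gene_union),
              length(x$trait_union)))
  invisible(x)
}
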