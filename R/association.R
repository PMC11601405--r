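#' Construct a labeled trait-by-gene association matrix
#'
#' The central input container of the pipeline: a dense numeric matrix of
#' association p-values with traits as rows and genes as columns. Typically
#' these are cross-tissue TWAS p-values (e.g. S-MultiXcan results from
#' PhenomeXcan), one per gene-trait pair. Missing associations are allowed
#' and carried as `NA`; they are never treated as significant.
#'
#' @param values numeric matrix, `n` traits by `m` genes, entries in
#'   \eqn{[0,1]} or `NA`.
#' @param trait_ids character vector of unique row identifiers (length `n`).
#'   Defaults to `rownames(values)`.
#' @param gene_ids character vector of unique column identifiers (length `m`).
#'   Defaults to `colnames(values)`.
#' @return an `association_matrix`: a numeric matrix with dimnames set and
#'   class attribute `"association_matrix"`.
#' @seealso [read_association_matrix()], [binarize()]
#' @export
association_matrix <- function(values,
                               trait_ids = rownames(values),
                               gene_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(trait_ids) || is.null(gene_ids)) {
    stop("trait and gene identifiers are required (as arguments or dimnames)")
  }
  trait_ids <- as.character(trait_ids)
  gene_ids <- as.character(gene_ids)
  if (length(trait_ids) != nrow(values) || length(gene_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  .check_unique(trait_ids, "trait")
  .check_unique(gene_ids, "gene")
  bad <- which(!is.na(values) & (values < 0 | values > 1))
  if (length(bad) > 0) {
    stop("p-values must lie in [0,1]; ", length(bad), " value(s) out of range")
  }
  dimnames(values) <- list(trait_ids, gene_ids)
  structure(values, class = c("association_matrix", "matrix"))
}

.check_unique <- function(ids, axis) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    stop(sprintf("duplicated %s identifier(s): %s",
                 axis, paste(dup, collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.association_matrix <- function(x, ...) {
  cat(sprintf("association_matrix: %d traits x %d genes (%d missing cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Read a trait-by-gene p-value matrix from delimited text
#'
#' Expects a header row of gene identifiers and one row per trait, the first
#' column holding the trait identifier. Empty cells and the strings `NA`/`na`
#' parse as missing values, never as zero.
#'
#' @param path path to the file (plain or gzip-compressed).
#' @param sep field delimiter; `"auto"` (default) lets the reader detect
#'   tab/comma.
#' @return an [association_matrix()].
#' @export
read_association_matrix <- function(path, sep = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          na.strings = c("", "NA", "na"), fill = FALSE,
                          colClasses = list(character = 1),
                          check.names = FALSE, data.table = TRUE)
  if (ncol(dt) < 2) stop("matrix file needs an identifier column plus at least one gene column")
  trait_ids <- as.character(dt[[1]])
  gene_ids <- colnames(dt)[-1]
  vals <- as.matrix(dt[, -1, with = FALSE])
  if (!is.numeric(vals)) {
    nonnum <- colnames(dt)[-1][!vapply(dt[, -1, with = FALSE], is.numeric, logical(1))]
    stop("non-numeric p-value column(s): ", paste(nonnum, collapse = ", "))
  }
  storage.mode(vals) <- "double"
  association_matrix(vals, trait_ids, gene_ids)
}

#' Write an association matrix as TSV
#'
#' First column `trait` carries trait identifiers; remaining columns are gene
#' identifiers. Round-trips through [read_association_matrix()].
#'
#' @param mat an [association_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_association_matrix <- function(mat, path) {
  dt <- data.table::data.table(trait = rownames(mat))
  dt <- cbind(dt, data.table::as.data.table(unclass(mat)))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Binarize a p-value matrix at a significance threshold
#'
#' Produces the binary matrix \eqn{E} with \eqn{E_{ij} = 1} iff
#' \eqn{M_{ij} < t} (strict inequality). Missing p-values binarize to 0:
#' absence of evidence cannot contribute a significant cell.
#'
#' @param mat an [association_matrix()] (or plain numeric matrix with
#'   dimnames).
#' @param t significance threshold, strictly between 0 and 1. The default is
#'   the Bonferroni-corrected threshold conventionally used for the
#'   PhenomeXcan S-MultiXcan matrix, `5.49e-10`; see [bonferroni_threshold()]
#'   to derive one explicitly.
#' @return a `binary_matrix`: logical matrix with the same dimnames and an
#'   attribute `threshold` recording `t`.
#' @export
binarize <- function(mat, t = 5.49e-10) {
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t <= 0 || t >= 1) {
    stop("threshold `t` must be a single value in (0, 1)")
  }
  if (!is.matrix(mat)) stop("`mat` must be a matrix")
  bits <- !is.na(mat) & unclass(mat) < t
  structure(bits, threshold = t, class = c("binary_matrix", "matrix"))
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("binary_matrix: %d traits x %d genes, %d significant cells (t = %g)\n",
              nrow(x), ncol(x), sum(x), attr(x, "threshold")))
  invisible(x)
}

#' Write a binary matrix as 0/1 TSV (for inspection)
#'
#' @param bin a `binary_matrix` from [binarize()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_binary_matrix <- function(bin, path) {
  dt <- data.table::data.table(trait = rownames(bin))
  dt <- cbind(dt, data.table::as.data.table(matrix(as.integer(bin), nrow(bin),
                                                   dimnames = dimnames(bin))))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Bonferroni significance threshold
#'
#' Family-wise threshold `alpha / n_tests`. Provided as an explicit helper:
#' the package default binarization constant (`5.49e-10`) is a fixed
#' configuration value and is deliberately not derived by this function,
#' because the effective number of tests behind a published constant is often
#' unstated.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param n_tests number of tests, a positive integer (may exceed
#'   `.Machine$integer.max`; passed as a double).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single value in (0, 1)")
  }
  if (!is.numeric(n_tests) || length(n_tests) != 1 || is.na(n_tests) ||
      n_tests < 1 || n_tests != floor(n_tests)) {
    stop("`n_tests` must be a positive integer")
  }
  alpha / n_tests
}

#' Convert two-sided p-values to absolute z-scores
#'
#' Reporting transform: the absolute standard-normal quantile corresponding
#' to a two-sided p-value, \eqn{z = \Phi^{-1}(1 - p/2)}. `p = 1` maps to 0.
#' Non-positive p-values (numerical underflow in upstream association tests)
#' map to `cap` with a warning and are flagged in the `capped` attribute.
#'
#' @param p numeric vector of p-values in (0, 1]; values `<= 0` are capped.
#' @param cap z-score assigned to underflowed p-values (default 40, roughly
#'   the double-precision underflow limit of `qnorm`).
#' @return numeric vector of non-negative z-scores, with attribute `capped`
#'   (logical vector) when any value was capped.
#' @export
p_to_z <- function(p, cap = 40) {
  if (!is.numeric(p)) stop("`p` must be numeric")
  if (any(p > 1, na.rm = TRUE)) stop("p-values above 1 are invalid")
  capped <- !is.na(p) & p <= 0
  z <- stats::qnorm(pmax(p, .Machine$double.xmin) / 2, lower.tail = FALSE)
  if (any(capped)) {
    warning(sum(capped), " non-positive p-value(s) capped at z = ", cap)
    z[capped] <- cap
  }
  z <- pmin(z, cap)
  if (any(capped)) attr(z, "capped") <- capped
  z
}
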