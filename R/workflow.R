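#' Assemble and validate a pipeline configuration
#'
#' Collects every stage parameter of the biclustering pipeline in one
#' validated record. Exactly one of `matrix_path` / `simulate` must be
#' supplied. All defaults are recorded explicitly in the returned object so
#' the run manifest never depends on implicit values.
#'
#' @param matrix_path path to a trait-by-gene p-value matrix
#'   (see [read_association_matrix()]), or `NULL` when simulating.
#' @param simulate named list of arguments for
#'   [generate_planted_dataset()], or `NULL` when reading a matrix.
#' @param threshold binarization threshold (default `5.49e-10`, the
#'   Bonferroni-corrected constant conventional for the PhenomeXcan
#'   S-MultiXcan matrix).
#' @param mnr,mnc minimum rows/columns per bicluster (defaults 2, 2).
#' @param min_genes bicluster filter: minimum gene count (default 10).
#' @param required_trait_ids,trait_pattern bicluster filter: traits of
#'   interest (see [filter_biclusters()]); both `NULL` keeps all biclusters.
#' @param k number of meta-bicluster groups (default 10).
#' @param gene_annotations,trait_annotations GMT paths for enrichment;
#'   ignored (and taken from the synthetic dataset) when simulating.
#' @param gene_universe,trait_universe `"matrix"` (all identifiers of the
#'   association matrix, the default) or a path to a one-identifier-per-line
#'   file.
#' @param seed integer seed; consumed only by the simulation stage (the
#'   analysis path is deterministic) but always recorded.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(matrix_path = NULL, simulate = NULL,
                            threshold = 5.49e-10, mnr = 2, mnc = 2,
                            min_genes = 10, required_trait_ids = NULL,
                            trait_pattern = NULL, k = 10,
                            gene_annotations = NULL, trait_annotations = NULL,
                            gene_universe = "matrix",
                            trait_universe = "matrix", seed = 1) {
  if (is.null(matrix_path) == is.null(simulate)) {
    stop("supply exactly one of `matrix_path` or `simulate`")
  }
  if (threshold <= 0 || threshold >= 1) stop("`threshold` must be in (0, 1)")
  if (mnr < 2) stop("`mnr` must be >= 2")
  if (mnc < 1) stop("`mnc` must be >= 1")
  if (min_genes < 0) stop("`min_genes` must be non-negative")
  if (k < 1) stop("`k` must be >= 1")
  structure(list(matrix_path = matrix_path, simulate = simulate,
                 threshold = threshold, mnr = as.integer(mnr),
                 mnc = as.integer(mnc), min_genes = as.integer(min_genes),
                 required_trait_ids = required_trait_ids,
                 trait_pattern = trait_pattern, k = as.integer(k),
                 gene_annotations = gene_annotations,
                 trait_annotations = trait_annotations,
                 gene_universe = gene_universe,
                 trait_universe = trait_universe,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML fields mirror the arguments of [pipeline_config()] exactly.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

.cfg <- function(config, name, default = NULL) {
  v <- config[[name]]
  if (is.null(v) || length(v) == 0) default else v
}

.read_universe <- function(spec, matrix_ids) {
  if (identical(spec, "matrix")) return(matrix_ids)
  if (!file.exists(spec)) stop("universe file not found: ", spec)
  readLines(spec, warn = FALSE)
}

#' Run the full biclustering pipeline
#'
#' Executes, in order: input (read or simulate the p-value matrix),
#' binarize, BiBit enumeration, bicluster filtering, pairwise Jaccard
#' similarity, average-linkage grouping into meta-biclusters, per-group
#' summaries, and over-representation analysis on both axes. Every stage
#' writes a plain-text output under `out_dir`, and a JSON manifest records
#' the configuration, per-stage row counts, and MD5 digests of all outputs.
#' A failing stage aborts with the stage named; outputs of earlier stages
#' are retained next to a `FAILED` marker file.
#'
#' @param config a `pipeline_config` (or plain list with the same fields).
#' @param out_dir output directory, created if needed.
#' @return the run manifest (list), invisibly; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  failed_marker <- file.path(out_dir, "FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 failed_marker)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- input ----------------------------------------------------------------
  sim_spec <- .cfg(config, "simulate")
  gene_gmt <- .cfg(config, "gene_annotations")
  trait_gmt <- .cfg(config, "trait_annotations")
  dataset <- NULL
  pvals <- stage("input", {
    if (!is.null(sim_spec)) {
      sim_spec <- as.list(sim_spec)
      if (!is.null(sim_spec$blocks)) {
        sim_spec$blocks <- lapply(sim_spec$blocks, as.list)
      }
      if (is.null(sim_spec$seed)) sim_spec$seed <- .cfg(config, "seed", 1L)
      dataset <- do.call(generate_planted_dataset, sim_spec)
      write_synthetic_dataset(dataset, file.path(out_dir, "input"))
      dataset$pvalues
    } else {
      read_association_matrix(.cfg(config, "matrix_path"))
    }
  })
  counts$traits <- nrow(pvals); counts$genes <- ncol(pvals)

  # -- binarize -------------------------------------------------------------
  bin <- stage("binarize", binarize(pvals, .cfg(config, "threshold", 5.49e-10)))
  write_binary_matrix(bin, file.path(out_dir, "binary_matrix.tsv"))
  counts$significant_cells <- sum(bin)

  # -- bibit ----------------------------------------------------------------
  bcs <- stage("bibit", run_bibit(bin, .cfg(config, "mnr", 2L),
                                  .cfg(config, "mnc", 2L)))
  write_biclusters(bcs, file.path(out_dir, "biclusters.jsonl"))
  counts$biclusters <- length(bcs)

  # -- filter ---------------------------------------------------------------
  filtered <- stage("filter", filter_biclusters(
    bcs, min_genes = .cfg(config, "min_genes", 10L),
    required_trait_ids = .cfg(config, "required_trait_ids"),
    trait_pattern = .cfg(config, "trait_pattern")))
  write_biclusters(filtered, file.path(out_dir, "filtered_biclusters.jsonl"))
  counts$filtered_biclusters <- length(filtered)

  # -- similarity + clustering ----------------------------------------------
  k <- .cfg(config, "k", 10L)
  labels <- stage("metacluster", {
    if (length(filtered) == 0) stop("no biclusters survive filtering")
    if (length(filtered) == 1) {
      stats::setNames("C1", filtered$biclusters[[1]]$id)
    } else {
      sim <- pairwise_similarity(filtered)
      sim_dt <- data.table::data.table(bicluster_id = rownames(sim))
      sim_dt <- cbind(sim_dt, data.table::as.data.table(sim))
      data.table::fwrite(sim_dt, file.path(out_dir, "similarity.tsv"),
                         sep = "\t", quote = FALSE)
      average_linkage_cluster(sim, k = min(k, length(filtered)))
    }
  })
  data.table::fwrite(
    data.table::data.table(bicluster_id = names(labels),
                           meta_label = as.character(labels)),
    file.path(out_dir, "labels.tsv"), sep = "\t", quote = FALSE)

  # -- meta summaries -------------------------------------------------------
  metas <- stage("summarize", summarize_meta(filtered, labels))
  counts$meta_biclusters <- length(metas)
  meta_dt <- data.table::rbindlist(lapply(metas, function(m) {
    rbind(
      data.table::data.table(meta_label = m$label, axis = "gene",
                             id = names(m$gene_frequency),
                             frequency = as.integer(m$gene_frequency)),
      data.table::data.table(meta_label = m$label, axis = "trait",
                             id = names(m$trait_frequency),
                             frequency = as.integer(m$trait_frequency)))
  }))
  data.table::fwrite(meta_dt, file.path(out_dir, "meta_summary.tsv"),
                     sep = "\t", quote = FALSE)

  # -- enrichment -----------------------------------------------------------
  enr <- stage("enrichment", {
    if (!is.null(dataset)) {
      gene_sets <- dataset$gene_annotations
      trait_sets <- dataset$trait_annotations
    } else {
      if (is.null(gene_gmt) || is.null(trait_gmt)) {
        stop("gene_annotations and trait_annotations GMT paths are required")
      }
      gene_sets <- read_gmt(gene_gmt, axis = "gene")
      trait_sets <- read_gmt(trait_gmt, axis = "trait")
    }
    gu <- .read_universe(.cfg(config, "gene_universe", "matrix"),
                         colnames(pvals))
    tu <- .read_universe(.cfg(config, "trait_universe", "matrix"),
                         rownames(pvals))
    enrich_meta(metas, gene_sets, trait_sets, gu, tu)
  })
  data.table::fwrite(enr, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE)
  counts$enrichment_rows <- nrow(enr)

  # -- manifest -------------------------------------------------------------
  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("manifest.json", "FAILED"))
  digests <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(digests) <- files
  manifest <- list(
    package_version = as.character(utils::packageVersion("twasbiclust")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = unclass(config),
    counts = counts,
    output_digests = digests)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Re-execute a pipeline run from its manifest
#'
#' Reads the configuration snapshot out of `manifest.json` and runs the
#' pipeline again into a new directory. With identical inputs this
#' reproduces identical stage-output digests (the analysis path is
#' deterministic and simulation is seed-driven).
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [run_pipeline()].
#' @param out_dir directory for the re-run.
#' @return the new run's manifest, invisibly.
#' @export
run_from_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  run_pipeline(man$config, out_dir)
}
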