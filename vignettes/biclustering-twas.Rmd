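---
title: "Mining overlapping gene-trait patterns in TWAS matrices by binary biclustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining overlapping gene-trait patterns in TWAS matrices by binary biclustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twasbiclust)
```

## The problem and the model

Transcriptome-wide association studies (TWAS) summarize, for every
gene-trait pair, the evidence that genetically predicted expression of the
gene is associated with the trait. Resources such as PhenomeXcan assemble
these into a dense matrix $M_{n \times m}$ of p-values over thousands of
traits (rows) and tens of thousands of genes (columns). Complex traits are
polygenic and genes are pleiotropic, so the biologically interesting
structure is *local*: a subset of traits jointly associated with a subset of
genes. Global clustering of rows or columns cannot represent such
rectangles, and a gene may belong to several of them at once.

This package works on the binarized matrix
$$E_{ij} = \mathbf{1}\{M_{ij} < t\},$$
with strict inequality at the threshold $t$. A **bicluster**
$\mathcal{B}_\ell = (\mathcal{T}_\ell, \mathcal{G}_\ell)$ is a trait subset
and a gene subset such that $M_{ij} < t$ for all
$i \in \mathcal{T}_\ell, j \in \mathcal{G}_\ell$ — an all-ones submatrix of
$E$. The pipeline has four stages:

1. **Binarization** (`binarize`). The default $t = 5.49\times 10^{-10}$ is
   the Bonferroni-corrected constant conventional for the PhenomeXcan
   S-MultiXcan matrix (4,091 traits × 22,515 genes). A
   `bonferroni_threshold(alpha, n_tests)` helper is provided, but note that
   $0.05 / (4{,}091 \times 22{,}515) \approx 5.43\times 10^{-10}$ differs
   slightly from the conventional printed constant — the effective test
   count behind published thresholds is often unstated — so the threshold
   is always an explicit configuration value and never derived silently.
2. **Enumeration** (`run_bibit`). BiBit seeds a candidate gene pattern from
   the bitwise AND of every unordered pair of trait rows, keeps patterns
   with at least `mnc` genes, extends each new pattern to *all* rows
   containing it, and emits the bicluster when at least `mnr` rows support
   it. Every emitted bicluster is therefore all-ones and row-maximal, and
   each distinct gene pattern appears once.
3. **Meta-clustering** (`filter_biclusters`, `pairwise_similarity`,
   `average_linkage_cluster`, `summarize_meta`). Biclusters overlap heavily
   by construction, so after filtering (at least `min_genes` genes, and
   optionally a trait of interest such as an asthma diagnosis code) they
   are compared pairwise by the Jaccard similarity of their gene sets and
   grouped by average-linkage (UPGMA) hierarchical clustering on the
   Jaccard distance $d = 1 - J$, cut at `k` groups. Each group
   (meta-bicluster) is summarized by its gene union and by gene/trait
   frequency tables.
4. **Enrichment** (`ora`, `enrich_meta`). Each meta-bicluster's gene union
   is tested against a GMT collection (GO-style), and its trait set against
   a trait collection (Disease-Ontology-style), with the upper-tail
   hypergeometric probability $P(X \ge k)$ and Benjamini-Hochberg
   adjustment across the terms of a collection.

For reporting, `p_to_z` converts two-sided p-values into absolute normal
z-scores, the common display transform for association heatmaps.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 5.49e-10 | binarization cutoff on p-values (strict `<`) |
| `mnr`, `mnc` | 2, 2 | minimum rows/columns of an emitted bicluster |
| `min_genes` | 10 | post-hoc bicluster filter before meta-clustering |
| `k` | 10 | number of meta-bicluster groups |
| `signal_p_max` | 1e-12 | generator: upper bound of planted p-values |
| `background_sig_rate` | 0.01 | generator: per-cell rate of significant noise |

`mnr` and `mnc` are deliberately permissive (2, 2): the size selection that
matters scientifically happens downstream in `filter_biclusters`
(`min_genes = 10`), keeping enumeration and filtering separate concerns.
`k` has no automatic selection — the number of groups is an analysis
choice, and 10 is a sensible default for a single disease focus.

## The synthetic-data generator

`generate_planted_dataset` emulates exactly the structure the pipeline
consumes: background p-values are Uniform(0,1) (the global null), planted
rectangular blocks are drawn Uniform(0, `signal_p_max`), and an independent
per-cell Bernoulli(`background_sig_rate`) subset of background cells is
redrawn Uniform(0, `signal_p_max`) to mimic isolated significant
associations that are real but not part of any block. Significance noise is
injected per cell, not per row or column — the simplest null consistent
with per-cell thresholding. Blocks may overlap (via
`overlap_rows`/`overlap_cols`), since overlapping biclusters are the
motivating structure; the truth list keeps them separate rather than
merging. `generate_annotations` adds one truth term per block plus random
noise terms, so enrichment recovery can be checked end-to-end.

A single integer seed drives the generator; deterministic sub-seeds
separate the matrix stream from the two annotation streams, and the whole
dataset is a pure function of (parameters, seed).

What the generator does **not** emulate: linkage disequilibrium between
genes, tissue-specific effects, correlated traits, realistic effect-size
distributions, or the block-diagonal correlation of real phenotype
batteries. Uniform(0,1) background is an assumption of the generator, not a
claim about any real TWAS resource. Passing the planted-recovery tests
therefore demonstrates algorithmic correctness — that all-ones rectangles
present in the binarized matrix are found, grouped, and annotated — not
that any particular biological finding would replicate.

## Numerical and design choices

- **Strict inequality** at the threshold: a cell exactly equal to $t$ is
  not significant.
- **Missing p-values binarize to 0**: absence of evidence cannot create a
  bicluster cell.
- **Bit packing** into 64-bit words (little-endian bit order within a
  word) happens inside the compiled enumeration core; at the R level the
  binary matrix is an ordinary logical matrix. Deduplication is keyed on
  the complete packed pattern, so distinct patterns can never collide.
- **Pair iteration order** is row-index order, but the result is
  order-independent because the supporting row set is a deterministic
  function of the pattern (asserted by a row-permutation test).
- **UPGMA tie-breaking**: when two merges are equally close (within
  1e-15), the pair whose smallest original member index is lowest wins,
  then the pair whose other smallest member index is lowest. This makes
  partitions reproducible across platforms; with continuous similarities
  ties almost never occur and the result coincides with `stats::hclust`
  (verified on random matrices at every cut level).
- **Group labels** are `C1..Ck` in ascending order of each group's
  smallest member index.
- **ORA conventions**: the observed overlap is included in the tail
  ($P(X \ge k)$); the default universe is all genes (resp. traits) of the
  association matrix, the natural sampling frame; terms reduced to zero
  members by universe intersection are dropped before BH adjustment;
  Benjamini-Hochberg is used because it is the least surprising default
  for exploratory enrichment screens.
- **Underflowed p-values** ($p \le 0$ after upstream rounding) convert to
  a capped z-score (default 40) with a warning and a `capped` flag.
- **Degenerate inputs**: an all-zero binary matrix yields an empty
  bicluster set; a single filtered bicluster forms its own meta-bicluster
  without a similarity stage; an empty annotation collection is a warning,
  not an error.

## A worked example

```{r example, eval = FALSE}
blocks <- lapply(1:5, function(i) list(rows = 8, cols = 15))
cfg <- pipeline_config(
  simulate = list(n_traits = 200, n_genes = 1000, blocks = blocks,
                  signal_p_max = 1e-12, background_sig_rate = 0.01,
                  annotation_noise_terms = 50),
  k = 5, min_genes = 10, seed = 42)
man <- run_pipeline(cfg, "run1")
str(man$counts)
```

On this design (five disjoint 8-trait × 15-gene blocks planted in a
200 × 1000 matrix with 1% background significance noise), the pipeline
binarizes to roughly 2,600 significant cells, enumerates a few hundred
biclusters, of which about 20 survive the 10-gene filter; the 5
meta-biclusters recover the planted blocks and each group's top-ranked
gene-axis and trait-axis term is its planted truth term. Problem sizes of
this order run in about a second and are the scale used throughout the test
suite; the algorithms themselves are linear in the number of row pairs
times the packed row width and handle much larger matrices.

## Known limitations

- The bicluster definition is exact: one super-threshold cell splits a
  rectangle. Noise-tolerant biclustering is out of scope.
- Enumeration is quadratic in the number of traits; for matrices with very
  dense rows the number of distinct patterns (and hence biclusters) can
  grow quickly.
- Annotation collections are consumed as flat sets; no ontology graph
  propagation or term redundancy reduction is performed.
- Tissue specificity of TWAS associations is not modeled; the input is one
  p-value per gene-trait pair.
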