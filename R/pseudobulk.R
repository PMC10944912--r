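# Pseudobulk construction: per-cell library-size normalization, per-population
# aggregation to log10 mean expression (no pseudocount), sentinel substitution
# for genes with zero counts in every cell of a population, and invertible
# per-population z-scoring.

#' Library-size normalize a count matrix
#'
#' Scales every cell (or bulk sample) to a fixed total: counts per million for
#' Smart-seq2, counts per ten thousand for 10X, and TPM for bulk (which first
#' divides by exonic gene length in kb). Cells with zero total counts are
#' dropped with a warning.
#'
#' @param counts genes x cells matrix (dense or `Matrix` sparse), nonnegative.
#' @param protocol One of "smartseq2", "tenx", "bulk".
#' @param gene_lengths Named numeric vector of exonic gene lengths in bases
#'   (required for `bulk`; see `exonic_lengths` on a gene table).
#' @return Normalized real matrix of the same class, possibly with zero-total
#'   columns removed.
#' @export
normalize_counts <- function(counts, protocol = c("tenx", "smartseq2", "bulk"),
                             gene_lengths = NULL) {
  protocol <- match.arg(protocol)
  if (min(counts) < 0) stop("counts must be nonnegative")
  if (protocol == "bulk") {
    if (is.null(gene_lengths)) {
      stop("bulk protocol requires gene_lengths (exonic lengths from the annotation)")
    }
    gl <- gene_lengths[rownames(counts)]
    if (anyNA(gl)) stop("gene_lengths missing for some genes in the count matrix")
    counts <- counts / (gl / 1000)
  }
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) {
    warning(sprintf("dropping %d cell(s)/sample(s) with zero total counts",
                    sum(totals == 0)))
    counts <- counts[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  scale_to <- switch(protocol, smartseq2 = 1e6, tenx = 1e4, bulk = 1e6)
  sweep_cols(counts, scale_to / totals)
}

sweep_cols <- function(m, f) {
  if (methods::is(m, "sparseMatrix")) {
    m %*% Matrix::Diagonal(x = f)
  } else {
    sweep(m, 2, f, "*")
  }
}

#' Aggregate normalized expression into pseudobulk values
#'
#' For each population p, `values[g, p] = log10(mean over its cells of the
#' normalized expression)`, without pseudocount. Genes with zero counts in all
#' cells of a population have an undefined log and receive the `sentinel`
#' value instead (−4 is the convention for whole-organism atlas data, −5 for
#' the human motor-cortex preset); those entries are flagged in `zero_mask`.
#' For bulk data the "cells" are samples.
#'
#' @param normalized genes x cells matrix from [normalize_counts()].
#' @param labels Character/factor vector, one population label per cell.
#' @param sentinel Value substituted for all-zero genes (default −4).
#' @return A `pb_matrix` object: list with `values` (genes x populations),
#'   `sentinel`, `zero_mask`, `populations`, `standardizer` (NULL until
#'   [pb_standardize()] is applied).
#' @export
pseudobulk_aggregate <- function(normalized, labels, sentinel = -4) {
  if (length(labels) != ncol(normalized)) {
    stop("labels must have one entry per cell/sample column")
  }
  labels <- as.factor(labels)
  if (any(table(labels) == 0)) {
    stop(sprintf("empty population: %s",
                 paste(levels(labels)[table(labels) == 0], collapse = ", ")))
  }
  pops <- levels(labels)
  vals <- matrix(NA_real_, nrow(normalized), length(pops),
                 dimnames = list(rownames(normalized), pops))
  mask <- matrix(FALSE, nrow(normalized), length(pops),
                 dimnames = dimnames(vals))
  for (p in pops) {
    sub <- normalized[, labels == p, drop = FALSE]
    mu <- Matrix::rowMeans(sub)
    zero <- mu == 0
    v <- suppressWarnings(log10(mu))
    v[zero] <- sentinel
    vals[, p] <- v
    mask[, p] <- zero
  }
  structure(list(values = vals, sentinel = sentinel, zero_mask = mask,
                 populations = pops, standardizer = NULL),
            class = "pb_matrix")
}

#' Per-population z-scoring of a pseudobulk matrix
#'
#' Standardizes each population column over all genes (sentinel entries
#' included, matching the order of operations in which sentinel substitution
#' precedes scaling) so that each column has mean 0 and SD 1 (population SD).
#' The per-population (mean, sd) pairs are stored on the object so
#' predictions can be mapped back to the log scale with [pb_unstandardize()].
#'
#' @param pb A `pb_matrix` from [pseudobulk_aggregate()].
#' @return The standardized `pb_matrix` with `standardizer` filled in.
#' @export
pb_standardize <- function(pb) {
  stopifnot(inherits(pb, "pb_matrix"))
  if (nrow(pb$values) < 2) stop("need at least two genes to standardize")
  mu <- colMeans(pb$values)
  sdv <- apply(pb$values, 2, pop_sd)
  if (any(sdv == 0)) {
    stop(sprintf("zero variance in population(s): %s",
                 paste(pb$populations[sdv == 0], collapse = ", ")))
  }
  pb$values <- sweep(sweep(pb$values, 2, mu), 2, sdv, "/")
  pb$standardizer <- data.frame(population = pb$populations,
                                mean = unname(mu), sd = unname(sdv),
                                stringsAsFactors = FALSE)
  pb
}

#' Invert per-population z-scoring
#'
#' @param x A standardized `pb_matrix`, or a plain genes x populations matrix
#'   of standardized values (e.g. model predictions).
#' @param standardizer Required when `x` is a matrix: the `standardizer`
#'   data.frame stored by [pb_standardize()].
#' @return Same shape as the input, on the log10 scale.
#' @export
pb_unstandardize <- function(x, standardizer = NULL) {
  if (inherits(x, "pb_matrix")) {
    if (is.null(x$standardizer)) stop("pseudobulk matrix is not standardized")
    x$values <- pb_unstandardize(x$values, x$standardizer)
    x$standardizer <- NULL
    return(x)
  }
  if (is.null(standardizer)) stop("standardizer required for matrix input")
  if (ncol(x) != nrow(standardizer)) {
    stop(sprintf("task count mismatch: %d columns vs %d standardizer entries",
                 ncol(x), nrow(standardizer)))
  }
  sweep(sweep(x, 2, standardizer$sd, "*"), 2, standardizer$mean, "+")
}

#' Read a sparse count matrix in MTX format
#'
#' Expects the usual triplet layout: `matrix.mtx`, `genes.tsv` (gene ids in
#' the first column), `barcodes.tsv`.
#'
#' @param dir Directory containing the three files.
#' @return A sparse genes x cells matrix with dimnames.
#' @export
read_counts_mtx <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- read.delim(file.path(dir, "genes.tsv"), header = FALSE)
  barcodes <- read.delim(file.path(dir, "barcodes.tsv"), header = FALSE)
  dimnames(m) <- list(as.character(genes[[1]]), as.character(barcodes[[1]]))
  methods::as(m, "CsparseMatrix")
}

#' Write a pseudobulk matrix and its standardizer
#'
#' @param pb A `pb_matrix`.
#' @param dir Output directory; writes `pseudobulk.tsv` and, when present,
#'   `standardizer.json`.
#' @export
write_pseudobulk <- function(pb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(gene_id = rownames(pb$values), pb$values,
                   check.names = FALSE)
  write.table(df, file.path(dir, "pseudobulk.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(pb$standardizer)) {
    jsonlite::write_json(pb$standardizer, file.path(dir, "standardizer.json"),
                         digits = NA)
  }
  invisible(dir)
}
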