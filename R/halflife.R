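# mRNA half-life proxy features: five transcript-structure covariates that
# proxy degradation rate (UTR lengths, ORF length, intron length, exon
# junction density). Raw features are log10(x + 0.1)-transformed and
# z-scaled; the scaler is retained so new genes can be projected onto the
# training scale.

# Exonic bases of the transcript lying strictly before genomic position x.
exonic_upto <- function(exons, x) {
  sum(pmax(0, pmin(exons[, 2], x) - exons[, 1]))
}

#' Compute raw half-life features for one gene
#'
#' * `utr5_len`: exonic (spliced) distance from the transcript 5' end to the
#'   first CDS base, strand-aware.
#' * `utr3_len`: exonic distance from the last CDS base to the transcript
#'   3' end.
#' * `orf_len`: summed CDS interval length.
#' * `intron_len`: genomic span length minus ORF and both UTRs (equivalently,
#'   span minus total exonic length).
#' * `exon_junction_density`: exon count per kb of ORF.
#'
#' @param gene One row of a [load_genes()] table (data.frame row or list with
#'   `strand`, `exons`, `cds`, `span_start`, `span_end`).
#' @return Named numeric vector of the five raw features.
#' @export
compute_halflife <- function(gene) {
  exons <- if (is.data.frame(gene)) gene$exons[[1]] else gene$exons
  cds <- if (is.data.frame(gene)) gene$cds[[1]] else gene$cds
  strand <- if (is.data.frame(gene)) gene$strand[1] else gene$strand
  if (is.null(cds) || nrow(cds) == 0) {
    stop("gene has no CDS; coding genes are required for half-life features")
  }
  total_exonic <- sum(exons[, 2] - exons[, 1])
  orf_len <- sum(cds[, 2] - cds[, 1])
  cds_lo <- min(cds[, 1])
  cds_hi <- max(cds[, 2])
  if (strand == "+") {
    utr5 <- exonic_upto(exons, cds_lo)
    utr3 <- total_exonic - exonic_upto(exons, cds_hi)
  } else {
    utr5 <- total_exonic - exonic_upto(exons, cds_hi)
    utr3 <- exonic_upto(exons, cds_lo)
  }
  span_start <- if (is.data.frame(gene)) gene$span_start[1] else gene$span_start
  span_end <- if (is.data.frame(gene)) gene$span_end[1] else gene$span_end
  intron <- (span_end - span_start) - orf_len - utr5 - utr3
  c(utr5_len = utr5, utr3_len = utr3, orf_len = orf_len,
    intron_len = intron,
    exon_junction_density = nrow(exons) / orf_len * 1000)
}

#' Half-life feature table for a gene set
#'
#' @param genes A [load_genes()] table.
#' @return data.frame with `gene_id` and the five raw feature columns.
#' @export
halflife_features <- function(genes) {
  feats <- t(vapply(seq_len(nrow(genes)),
                    function(i) compute_halflife(genes[i, ]),
                    numeric(5)))
  data.frame(gene_id = genes$gene_id, feats, row.names = NULL,
             stringsAsFactors = FALSE)
}

HL_FEATURES <- c("utr5_len", "utr3_len", "orf_len", "intron_len",
                 "exon_junction_density")

#' Log-transform and z-scale half-life features
#'
#' Each feature x is mapped to `log10(x + 0.1)` and then z-scored over all
#' genes (population SD). A feature with zero variance after the log
#' transform is set to 0 for all genes with a warning. The per-feature
#' (mean, sd) pairs are returned so new genes can be projected with
#' [apply_halflife_scaler()].
#'
#' @param raw data.frame from [halflife_features()].
#' @return list with `features` (data.frame, normalized columns) and
#'   `scaler` (data.frame feature/mean/sd on the log scale).
#' @export
normalize_halflife <- function(raw) {
  stopifnot(nrow(raw) > 0, all(HL_FEATURES %in% names(raw)))
  logf <- log10(as.matrix(raw[HL_FEATURES]) + 0.1)
  mu <- colMeans(logf)
  sdv <- apply(logf, 2, pop_sd)
  zero_var <- sdv == 0
  if (any(zero_var)) {
    warning(sprintf("zero-variance half-life feature(s) set to 0: %s",
                    paste(HL_FEATURES[zero_var], collapse = ", ")))
    sdv[zero_var] <- 1
    mu[zero_var] <- logf[1, zero_var]
  }
  z <- sweep(sweep(logf, 2, mu), 2, sdv, "/")
  list(features = data.frame(gene_id = raw$gene_id, z, row.names = NULL,
                             stringsAsFactors = FALSE),
       scaler = data.frame(feature = HL_FEATURES, mean = unname(mu),
                           sd = unname(sdv), stringsAsFactors = FALSE))
}

#' Project raw half-life features with a stored scaler
#'
#' @param raw data.frame from [halflife_features()].
#' @param scaler A `scaler` data.frame from [normalize_halflife()].
#' @return data.frame of normalized features.
#' @export
apply_halflife_scaler <- function(raw, scaler) {
  logf <- log10(as.matrix(raw[scaler$feature]) + 0.1)
  z <- sweep(sweep(logf, 2, scaler$mean), 2, scaler$sd, "/")
  data.frame(gene_id = raw$gene_id, z, row.names = NULL,
             stringsAsFactors = FALSE)
}

# Population (n-divisor) standard deviation; the z-scaling convention used
# throughout for targets and covariates.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}
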