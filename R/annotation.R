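# Genome annotation: gene filtering, transcript selection, TSS resolution and
# strand-aware promoter-window extraction.
#
# Coordinates are 0-based half-open internally; GTF input is 1-based
# inclusive and converted once at the parser boundary.

#' Gene-exclusion filter configuration
#'
#' Filters mirror the usual preprocessing for promoter expression models:
#' genes without any coding region, genes on the Y chromosome, ERCC
#' spike-ins, and (configurably) transgenes identified by gene-id prefix.
#'
#' @param transgene_prefixes Character vector of gene-id prefixes flagged as
#'   transgenes (default none; dataset-specific).
#' @param drop_chroms Chromosome names to exclude entirely.
#' @param drop_ercc Drop gene ids starting with "ERCC-".
#' @param require_cds Drop genes with no CDS on any transcript.
#' @return A list with class `exclude_filters`.
#' @export
exclude_filters <- function(transgene_prefixes = character(),
                            drop_chroms = c("chrY", "Y"),
                            drop_ercc = TRUE,
                            require_cds = TRUE) {
  structure(list(transgene_prefixes = transgene_prefixes,
                 drop_chroms = drop_chroms,
                 drop_ercc = drop_ercc,
                 require_cds = require_cds),
            class = "exclude_filters")
}

validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  ntab <- vapply(gregexpr("\t", lines[body], fixed = TRUE),
                 function(x) if (x[1] == -1L) 0L else length(x), integer(1))
  if (any(ntab != 8L)) {
    bad <- which(body)[which(ntab != 8L)[1]]
    stop(sprintf("malformed GTF line %d in '%s': expected 9 tab-separated fields",
                 bad, path))
  }
  invisible(TRUE)
}

#' Load, filter and resolve genes from a GTF annotation
#'
#' Parses an Ensembl-style GTF (attributes `gene_id`, `transcript_id`),
#' applies the exclusion filters, and resolves one transcript per gene:
#' the entry of `canonical_map` when present, otherwise the transcript with
#' the largest summed CDS length (ties broken by transcript id). The TSS is
#' the transcript's 5' end on its strand.
#'
#' @param gtf_source Path to a GTF file.
#' @param exclude An [exclude_filters()] configuration.
#' @param canonical_map Optional named character vector or two-column
#'   data.frame (gene_id, transcript_id) giving canonical transcripts. A
#'   mapping that names an absent transcript triggers a warning and the
#'   longest-CDS fallback for that gene.
#' @return A data.frame with one row per retained gene: `gene_id`,
#'   `gene_name`, `chrom`, `strand`, `tss` (0-based), `transcript_id`,
#'   `span_start`, `span_end`, `n_exons`, and list-columns `exons`, `cds`
#'   (two-column matrices of 0-based half-open intervals, sorted,
#'   non-overlapping).
#' @export
load_genes <- function(gtf_source, exclude = exclude_filters(),
                       canonical_map = NULL) {
  validate_gtf_lines(gtf_source)
  gr <- rtracklayer::import(gtf_source, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)

  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,   # 1-based incl -> 0-based half-open
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    gene_name = if (!is.null(md$gene_name)) as.character(md$gene_name) else
      as.character(md$gene_id),
    stringsAsFactors = FALSE
  )

  if (is.data.frame(canonical_map)) {
    canonical_map <- setNames(as.character(canonical_map[[2]]),
                              as.character(canonical_map[[1]]))
  }

  # summed CDS length per transcript
  cds_df <- df[df$type == "CDS", , drop = FALSE]
  cds_len <- tapply(cds_df$end0 - cds_df$start0, cds_df$transcript_id, sum)

  records <- list()
  for (gid in unique(df$gene_id)) {
    gdf <- df[df$gene_id == gid, , drop = FALSE]
    if (isTRUE(exclude$drop_ercc) && startsWith(gid, "ERCC-")) next
    if (length(exclude$transgene_prefixes) &&
        any(startsWith(gid, exclude$transgene_prefixes))) next
    if (gdf$chrom[1] %in% exclude$drop_chroms) next

    txs <- sort(unique(gdf$transcript_id))
    tx_cds <- cds_len[txs]
    tx_cds[is.na(tx_cds)] <- 0
    if (isTRUE(exclude$require_cds) && all(tx_cds == 0)) next

    tx <- NULL
    if (!is.null(canonical_map) && gid %in% names(canonical_map)) {
      cand <- canonical_map[[gid]]
      if (cand %in% txs) {
        tx <- cand
      } else {
        warning(sprintf(
          "canonical transcript '%s' for gene '%s' not found; falling back to longest CDS",
          cand, gid))
      }
    }
    if (is.null(tx)) tx <- txs[which.max(tx_cds)]

    tdf <- gdf[gdf$transcript_id == tx, , drop = FALSE]
    ex <- tdf[tdf$type == "exon", c("start0", "end0"), drop = FALSE]
    ex <- as.matrix(ex[order(ex$start0), , drop = FALSE])
    cds <- tdf[tdf$type == "CDS", c("start0", "end0"), drop = FALSE]
    cds <- as.matrix(cds[order(cds$start0), , drop = FALSE])
    dimnames(ex) <- dimnames(cds) <- NULL
    span_start <- min(ex[, 1])
    span_end <- max(ex[, 2])
    strand <- tdf$strand[1]
    records[[gid]] <- list(
      gene_id = gid, gene_name = tdf$gene_name[1], chrom = tdf$chrom[1],
      strand = strand,
      tss = if (strand == "+") span_start else span_end - 1L,
      transcript_id = tx, span_start = span_start, span_end = span_end,
      n_exons = nrow(ex), exons = ex, cds = cds)
  }

  if (!length(records)) {
    return(data.frame(gene_id = character(), gene_name = character(),
                      chrom = character(), strand = character(),
                      tss = integer(), transcript_id = character(),
                      span_start = integer(), span_end = integer(),
                      n_exons = integer()))
  }
  out <- data.frame(
    gene_id = vapply(records, `[[`, "", "gene_id"),
    gene_name = vapply(records, `[[`, "", "gene_name"),
    chrom = vapply(records, `[[`, "", "chrom"),
    strand = vapply(records, `[[`, "", "strand"),
    tss = vapply(records, function(r) as.integer(r$tss), 1L),
    transcript_id = vapply(records, `[[`, "", "transcript_id"),
    span_start = vapply(records, function(r) as.integer(r$span_start), 1L),
    span_end = vapply(records, function(r) as.integer(r$span_end), 1L),
    n_exons = vapply(records, function(r) as.integer(r$n_exons), 1L),
    row.names = NULL, stringsAsFactors = FALSE
  )
  out$exons <- unname(lapply(records, `[[`, "exons"))
  out$cds <- unname(lapply(records, `[[`, "cds"))
  out
}

load_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet")) {
    stop("genome must be a FASTA path or a Biostrings::DNAStringSet")
  }
  # FASTA headers may carry descriptions; keep the first word as the name
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Extract the oriented promoter window around one TSS
#'
#' For '+' genes the genomic interval `[tss - up_len, tss + down_len)` is read
#' forward; for '-' genes `[tss - down_len + 1, tss + up_len + 1)` is read and
#' reverse-complemented, so that the output is always oriented transcript
#' 5'->3' and position `up_len` (0-based) is the TSS base. Positions outside
#' the contig are filled with 'N'.
#'
#' @param genome A `DNAStringSet` or FASTA path.
#' @param chrom,strand,tss Chromosome name, strand ('+'/'-'), 0-based TSS.
#' @param up_len,down_len Bases upstream/downstream of the TSS (transcript
#'   orientation); defaults 7000 and 3500.
#' @return A character string of length `up_len + down_len`.
#' @export
extract_window <- function(genome, chrom, strand, tss,
                           up_len = 7000L, down_len = 3500L) {
  genome <- load_genome(genome)
  if (!chrom %in% names(genome)) {
    stop(sprintf("chromosome '%s' not present in the genome FASTA", chrom))
  }
  contig <- genome[[chrom]]
  clen <- length(contig)
  if (strand == "+") {
    s0 <- tss - up_len; e0 <- tss + down_len
  } else {
    s0 <- tss - down_len + 1L; e0 <- tss + up_len + 1L
  }
  lo <- max(s0, 0L); hi <- min(e0, clen)
  core <- if (hi > lo) as.character(Biostrings::subseq(contig, lo + 1L, hi)) else ""
  seq <- paste0(strrep("N", max(0L, lo - s0)), core, strrep("N", max(0L, e0 - hi)))
  if (strand == "-") seq <- reverse_complement(seq)
  seq
}

#' Extract promoter windows for a gene table
#'
#' @param genome A `DNAStringSet` or FASTA path.
#' @param genes A gene table from [load_genes()].
#' @inheritParams extract_window
#' @return Named character vector of window sequences (names = gene ids).
#' @export
extract_windows <- function(genome, genes, up_len = 7000L, down_len = 3500L) {
  genome <- load_genome(genome)
  out <- vapply(seq_len(nrow(genes)), function(i) {
    extract_window(genome, genes$chrom[i], genes$strand[i], genes$tss[i],
                   up_len, down_len)
  }, character(1))
  names(out) <- genes$gene_id
  out
}

#' Write promoter windows as FASTA
#'
#' Headers follow `gene_id|chrom|strand|tss`.
#'
#' @param windows Named character vector from [extract_windows()].
#' @param genes Matching gene table.
#' @param path Output FASTA path.
#' @export
write_windows <- function(windows, genes, path) {
  stopifnot(all(names(windows) == genes$gene_id))
  ss <- Biostrings::DNAStringSet(windows)
  names(ss) <- sprintf("%s|%s|%s|%d", genes$gene_id, genes$chrom,
                       genes$strand, genes$tss)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# Exonic (spliced) transcript length per gene; used for bulk TPM.
exonic_lengths <- function(genes) {
  setNames(vapply(genes$exons, function(e) sum(e[, 2] - e[, 1]), 1),
           genes$gene_id)
}
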