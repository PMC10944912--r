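# Shared fixtures: all built programmatically at test time.

# A toy GTF exercising the gene filters: one gene without CDS, one on chrY,
# one ERCC spike-in, two coding autosomal genes (one minus strand), and one
# gene with two transcripts whose summed CDS lengths differ (300 vs 900).
write_toy_gtf <- function(path = tempfile(fileext = ".gtf")) {
  att <- function(g, t = NULL) {
    if (is.null(t)) sprintf('gene_id "%s"; gene_name "%s";', g, g)
    else sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";', g, t, g)
  }
  row <- function(chr, type, s, e, strand, a) {
    sprintf("%s\tsrc\t%s\t%d\t%d\t.\t%s\t.\t%s", chr, type, s, e, strand, a)
  }
  lines <- c(
    "#!toy annotation",
    # gene A: plus strand, 2 exons with CDS (the half-life worked example:
    # exons [0,100)+[200,300) 0-based -> 1..100, 201..300 1-based)
    row("chr1", "gene", 1, 300, "+", att("geneA")),
    row("chr1", "transcript", 1, 300, "+", att("geneA", "tA1")),
    row("chr1", "exon", 1, 100, "+", att("geneA", "tA1")),
    row("chr1", "exon", 201, 300, "+", att("geneA", "tA1")),
    row("chr1", "CDS", 51, 100, "+", att("geneA", "tA1")),
    row("chr1", "CDS", 201, 250, "+", att("geneA", "tA1")),
    # gene B: minus strand, exon span [100,200) 0-based -> 101..200
    row("chr1", "gene", 101, 200, "-", att("geneB")),
    row("chr1", "transcript", 101, 200, "-", att("geneB", "tB1")),
    row("chr1", "exon", 101, 200, "-", att("geneB", "tB1")),
    row("chr1", "CDS", 121, 180, "-", att("geneB", "tB1")),
    # gene C: no CDS on any transcript -> filtered
    row("chr1", "gene", 401, 500, "+", att("geneC")),
    row("chr1", "transcript", 401, 500, "+", att("geneC", "tC1")),
    row("chr1", "exon", 401, 500, "+", att("geneC", "tC1")),
    # gene D: on chrY -> filtered
    row("chrY", "gene", 1, 200, "+", att("geneD")),
    row("chrY", "transcript", 1, 200, "+", att("geneD", "tD1")),
    row("chrY", "exon", 1, 200, "+", att("geneD", "tD1")),
    row("chrY", "CDS", 51, 150, "+", att("geneD", "tD1")),
    # ERCC spike-in -> filtered
    row("chr1", "gene", 601, 700, "+", att("ERCC-0042")),
    row("chr1", "transcript", 601, 700, "+", att("ERCC-0042", "tE1")),
    row("chr1", "exon", 601, 700, "+", att("ERCC-0042", "tE1")),
    row("chr1", "CDS", 601, 700, "+", att("ERCC-0042", "tE1")),
    # gene F: two transcripts, summed CDS 300 bp (tF1) vs 900 bp (tF2)
    row("chr2", "gene", 1001, 3000, "+", att("geneF")),
    row("chr2", "transcript", 1001, 2000, "+", att("geneF", "tF1")),
    row("chr2", "exon", 1001, 2000, "+", att("geneF", "tF1")),
    row("chr2", "CDS", 1101, 1400, "+", att("geneF", "tF1")),
    row("chr2", "transcript", 1001, 3000, "+", att("geneF", "tF2")),
    row("chr2", "exon", 1001, 3000, "+", att("geneF", "tF2")),
    row("chr2", "CDS", 1201, 2100, "+", att("geneF", "tF2"))
  )
  writeLines(lines, path)
  path
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

toy_genome <- function(lens = c(chr1 = 2000, chr2 = 4000)) {
  g <- Biostrings::DNAStringSet(vapply(lens, random_dna, ""))
  names(g) <- names(lens)
  g
}

# A tiny plus-strand gene record for direct half-life computations
# (the worked example: exons {[0,100),[200,300)}, CDS {[50,100),[200,250)}).
worked_gene <- function(strand = "+", shift = 0L) {
  if (strand == "+") {
    list(gene_id = "gX", strand = "+",
         exons = cbind(c(0, 200), c(100, 300)) + shift,
         cds = cbind(c(50, 200), c(100, 250)) + shift,
         span_start = 0 + shift, span_end = 300 + shift)
  } else {
    # mirrored around 300: interval [a,b) -> [300-b, 300-a)
    list(gene_id = "gXm", strand = "-",
         exons = cbind(c(0, 200), c(100, 300)) + shift,
         cds = cbind(c(50, 200), c(100, 250)) + shift,
         span_start = 0 + shift, span_end = 300 + shift)
  }
}

# Independent plain-R forward pass for the CNN (oracle; mirrors the
# conv -> ReLU -> max-pool -> conv -> ReLU -> max-pool -> concat -> head
# contract without touching the C++ path).
r_forward <- function(w, cfg, seqs, hl) {
  K1 <- cfg$conv_widths[1]; K2 <- cfg$conv_widths[2]
  P1 <- cfg$pool_widths[1]; P2 <- cfg$pool_widths[2]
  F1 <- cfg$conv_filters[1]; F2 <- cfg$conv_filters[2]
  out <- NULL
  for (n in seq_along(seqs)) {
    X <- one_hot(seqs[[n]])
    L1 <- ncol(X) - K1 + 1
    Y1 <- sapply(seq_len(L1), function(j) w$W1 %*% as.vector(X[, j:(j + K1 - 1)]) + w$b1)
    Y1 <- pmax(matrix(Y1, nrow = F1), 0)
    M1 <- L1 %/% P1
    P1m <- sapply(seq_len(M1), function(m)
      apply(Y1[, ((m - 1) * P1 + 1):(m * P1), drop = FALSE], 1, max))
    P1m <- matrix(P1m, nrow = F1)
    L2 <- M1 - K2 + 1
    Y2 <- sapply(seq_len(L2), function(j) w$W2 %*% as.vector(P1m[, j:(j + K2 - 1)]) + w$b2)
    Y2 <- pmax(matrix(Y2, nrow = F2), 0)
    M2 <- L2 %/% P2
    P2m <- sapply(seq_len(M2), function(m)
      apply(Y2[, ((m - 1) * P2 + 1):(m * P2), drop = FALSE], 1, max))
    h <- c(as.vector(matrix(P2m, nrow = F2)), hl[n, ])
    o <- if (!is.null(w$Wh)) {
      w$Wo %*% pmax(w$Wh %*% h + w$bh, 0) + w$bo
    } else {
      w$Wo %*% h + w$bo
    }
    out <- rbind(out, as.vector(o))
  }
  out
}

# Small random model dataset for model-level tests.
random_dataset <- function(N, L, Tn, seed = 1, alphabet = c("A", "C", "G", "T")) {
  set.seed(seed)
  seqs <- vapply(seq_len(N), function(i)
    paste(sample(alphabet, L, replace = TRUE), collapse = ""), "")
  names(seqs) <- sprintf("g%03d", seq_len(N))
  hl <- matrix(rnorm(N * 5), N, 5)
  Y <- matrix(rnorm(N * Tn), N, Tn,
              dimnames = list(names(seqs), paste0("task", seq_len(Tn))))
  model_dataset(seqs, hl, Y)
}

# Small simulated dataset prepared through the full data path; memoized per
# session because several test files reuse it.
small_sim_bundle <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_genes = 250, up_len = 300, down_len = 100,
                      n_cells = 40L, seed = 42)
    sim <- simulate_dataset(cfg)
    dir <- tempfile("smallsim")
    write_simulation(sim, dir)
    genes <- load_genes(file.path(dir, "annotation.gtf"))
    windows <- extract_windows(file.path(dir, "genome.fa"), genes,
                               cfg$up_len, cfg$down_len)
    hl <- normalize_halflife(halflife_features(genes))
    counts <- read_counts_mtx(file.path(dir, "counts"))
    labels <- utils::read.delim(file.path(dir, "labels.tsv"))
    pb <- pb_standardize(pseudobulk_aggregate(
      normalize_counts(counts, "tenx"), labels$population))
    common <- intersect(genes$gene_id, rownames(pb$values))
    genes <- genes[match(common, genes$gene_id), ]
    data <- model_dataset(windows[common], hl$features,
                          pb$values[common, , drop = FALSE],
                          standardizer = pb$standardizer)
    cache <<- list(sim = sim, dir = dir, genes = genes, data = data, pb = pb,
                   truth_log = pb_unstandardize(pb$values[common, , drop = FALSE],
                                                pb$standardizer))
    cache
  }
})
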