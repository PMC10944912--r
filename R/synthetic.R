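# Seeded synthetic-data generator: a toy genome + GTF with strand-mixed
# multi-exon transcripts, planted population-specific promoter motifs,
# half-life covariates, and per-cell counts whose population means follow a
# latent log-expression, so that every pipeline stage and the end-to-end
# benchmark run without any external download.

#' Simulation configuration
#'
#' The latent model is
#' `y[g,p] = beta0 + sum_k c[g,k] * beta[k,p] + gamma . hl_z[g] + eps[g,p]`,
#' with `c[g,k]` the planted copy count of motif k in gene g's window,
#' `hl_z` the z-scored log half-life features, and `eps ~ N(0, sigma^2)`.
#' Each cell of population p then draws gene counts with mean proportional
#' to `10^y[g,p]` times its library-size factor.
#'
#' @param n_genes Number of genes (default 1500).
#' @param n_chromosomes Chromosomes the genes are spread over (default 4).
#' @param up_len,down_len Window extent; reduced defaults (1500/500) keep the
#'   benchmark CPU-friendly while exercising the same machinery as the full
#'   7000/3500 window.
#' @param motifs List of planted motifs, each `list(name, consensus, beta)`
#'   with `beta` a per-population effect vector (zeros make the motif
#'   population-specific). Defaults: two 10-mers, each active in exactly one
#'   of the populations.
#' @param motif_rate Per-gene planting probability for each motif.
#' @param copy_probs Distribution of the number of planted copies (1, 2 or 3)
#'   given a motif is planted; transcription-factor binding sites commonly
#'   occur in multiple copies, and the latent effect scales with the copy
#'   count.
#' @param beta0 Baseline log10 expression.
#' @param gamma Weights of the five z-scored half-life features in the
#'   latent expression.
#' @param sigma SD of the gene-by-population latent noise.
#' @param populations Population names (P >= 2 for population-specific
#'   motifs).
#' @param classes Named vector mapping population -> parent class (used by
#'   hierarchy experiments); default splits populations over two classes.
#' @param n_cells Cells per population (scalar or per-population vector).
#' @param count_model "negative_binomial" (default, dispersion 0.1) or
#'   "poisson".
#' @param dispersion NB dispersion (1/size).
#' @param lib_sdlog SD of the log-normal library-size factors.
#' @param silent_frac Fraction of genes silenced (zero counts) in one random
#'   population, exercising the sentinel path.
#' @param seed RNG seed; the same seed reproduces the dataset byte for byte.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 1500L, n_chromosomes = 4L,
                       up_len = 1500L, down_len = 500L,
                       motifs = list(
                         list(name = "m1", consensus = "TGACGTCATC",
                              beta = c(1, 0, 0)),
                         list(name = "m2", consensus = "CAGGTAAACA",
                              beta = c(0, 1, 0))),
                       motif_rate = 0.35, copy_probs = c(0.25, 0.5, 0.25),
                       beta0 = 1,
                       gamma = c(0.25, 0.2, 0.3, 0.15, 0.2),
                       sigma = 0.3,
                       populations = c("pop1", "pop2", "pop3"),
                       classes = NULL,
                       n_cells = 60L,
                       count_model = c("negative_binomial", "poisson"),
                       dispersion = 0.1, lib_sdlog = 0.3,
                       silent_frac = 0.01, seed = 1L) {
  count_model <- match.arg(count_model)
  P <- length(populations)
  stopifnot(P >= 2, n_genes >= 10, motif_rate >= 0, sigma >= 0,
            dispersion >= 0, silent_frac >= 0)
  L <- up_len + down_len
  for (m in motifs) {
    stopifnot(length(m$beta) == P)
    if (nchar(m$consensus) > L) stop("motif longer than the window")
  }
  if (is.null(classes)) {
    classes <- setNames(rep(c("class1", "class2"), length.out = P), populations)
  }
  if (length(n_cells) == 1) n_cells <- rep(n_cells, P)
  stopifnot(length(copy_probs) == 3, all(copy_probs >= 0),
            abs(sum(copy_probs) - 1) < 1e-8)
  structure(list(n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 up_len = as.integer(up_len), down_len = as.integer(down_len),
                 motifs = motifs, motif_rate = motif_rate,
                 copy_probs = copy_probs, beta0 = beta0,
                 gamma = gamma, sigma = sigma, populations = populations,
                 classes = classes, n_cells = as.integer(n_cells),
                 count_model = count_model, dispersion = dispersion,
                 lib_sdlog = lib_sdlog, silent_frac = silent_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Random transcript structure in local 5'->3' genomic coordinates [0, tl).
# Returns exon/CDS local intervals plus the exonic UTR lengths.
random_transcript <- function(tl, min_seg = 30L) {
  n_ex <- sample(1:3, 1)
  if ((2 * n_ex - 1) * min_seg + 20 > tl) n_ex <- 1L
  if (n_ex == 1) {
    exons <- matrix(c(0L, tl), 1)
  } else {
    nseg <- 2L * n_ex - 1L
    w <- runif(nseg)
    extra <- floor(w / sum(w) * (tl - nseg * min_seg))
    lens <- min_seg + extra
    lens[nseg] <- lens[nseg] + (tl - sum(lens))
    ends <- cumsum(lens)
    starts <- c(0L, ends[-nseg])
    keep <- seq(1, nseg, by = 2)
    exons <- cbind(starts[keep], ends[keep])
  }
  ex1 <- exons[1, 2] - exons[1, 1]
  exl <- exons[nrow(exons), 2] - exons[nrow(exons), 1]
  exonic <- sum(exons[, 2] - exons[, 1])
  repeat {
    u5 <- sample.int(max(ex1 - 5L, 1L), 1) - 1L
    u3 <- sample.int(max(exl - 5L, 1L), 1) - 1L
    if (exonic - u5 - u3 >= 3) break
  }
  cds_start <- exons[1, 1] + u5
  cds_end <- exons[nrow(exons), 2] - u3
  cds <- exons
  cds[, 1] <- pmax(cds[, 1], cds_start)
  cds[, 2] <- pmin(cds[, 2], cds_end)
  cds <- cds[cds[, 2] > cds[, 1], , drop = FALSE]
  list(exons = exons, cds = cds, utr5 = u5, utr3 = u3,
       orf = exonic - u5 - u3, intron = tl - exonic, n_exons = nrow(exons))
}

#' Simulate a toy genome, annotation, counts and ground truth
#'
#' Background sequence is i.i.d. uniform ACGT; motifs are written into the
#' oriented promoter window at recorded offsets; every gene gets a 1-3-exon
#' transcript with a CDS (so the half-life module operates); counts are
#' drawn per cell from the latent population expression. Fully seeded.
#'
#' @param config A [sim_config()].
#' @return A `sim_data` list: `genome` (DNAStringSet), `gtf` (data.frame of
#'   GTF fields, 1-based inclusive), `counts` (sparse genes x cells),
#'   `labels` (barcode/population/class), `truth` (latent `y` matrix with
#'   `-Inf` for silenced entries, motif `placements`, raw half-life
#'   features), and `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  up <- config$up_len; down <- config$down_len; L <- up + down
  margin <- 200L
  slot <- up + down + 2L * margin
  P <- length(config$populations)
  n <- config$n_genes
  per_chrom <- ceiling(n / config$n_chromosomes)
  chrom_names <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_len <- per_chrom * slot + margin

  chrom_seq <- lapply(chrom_names, function(cn) {
    sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  })
  names(chrom_seq) <- chrom_names

  genes <- vector("list", n)
  placements <- list()
  hl_raw <- matrix(0, n, 5,
                   dimnames = list(NULL, c("utr5_len", "utr3_len", "orf_len",
                                           "intron_len",
                                           "exon_junction_density")))
  K <- length(config$motifs)
  cmat <- matrix(0L, n, K)

  for (g in seq_len(n)) {
    ci <- ((g - 1L) %/% per_chrom) + 1L
    si <- ((g - 1L) %% per_chrom)
    base0 <- si * slot
    strand <- sample(c("+", "-"), 1)
    tl <- sample(150:(down + margin - 10L), 1)
    tx <- random_transcript(tl)
    if (strand == "+") {
      tss <- base0 + margin + up
      tog <- function(iv) cbind(tss + iv[, 1], tss + iv[, 2])
    } else {
      tss <- base0 + margin + down - 1L
      tog <- function(iv) {
        m <- cbind(tss - iv[, 2] + 1L, tss - iv[, 1] + 1L)
        m[order(m[, 1]), , drop = FALSE]
      }
    }
    gid <- sprintf("G%04d", g)
    genes[[g]] <- list(gene_id = gid, chrom = chrom_names[ci],
                       strand = strand, tss = tss,
                       exons = tog(tx$exons), cds = tog(tx$cds))
    hl_raw[g, ] <- c(tx$utr5, tx$utr3, tx$orf, tx$intron,
                     tx$n_exons / tx$orf * 1000)

    # plant motifs in the oriented window (1-3 copies per planted motif)
    occupied <- matrix(numeric(0), 0, 2)
    for (k in seq_len(K)) {
      if (runif(1) >= config$motif_rate) next
      mseq <- config$motifs[[k]]$consensus
      ml <- nchar(mseq)
      ncopy <- sample(1:3, 1, prob = config$copy_probs)
      for (cpy in seq_len(ncopy)) {
        for (try in 1:25) {
          o <- sample.int(L - ml + 1L, 1) - 1L
          if (!nrow(occupied) ||
              all(o + ml <= occupied[, 1] | o >= occupied[, 2])) break
          o <- NA_integer_
        }
        if (is.na(o)) next
        occupied <- rbind(occupied, c(o, o + ml))
        cmat[g, k] <- cmat[g, k] + 1L
        chars <- strsplit(if (strand == "+") mseq else reverse_complement(mseq),
                          "", fixed = TRUE)[[1]]
        if (strand == "+") {
          gpos <- (tss - up + o) + seq_len(ml)   # 1-based genomic
        } else {
          gpos <- (tss + up - o - ml + 1L) + seq_len(ml)
        }
        chrom_seq[[chrom_names[ci]]][gpos] <- chars
        placements[[length(placements) + 1]] <- data.frame(
          gene_id = gid, motif = config$motifs[[k]]$name, offset = o,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }

  gene_ids <- vapply(genes, `[[`, "", "gene_id")

  # latent expression
  logf <- log10(hl_raw + 0.1)
  hl_z <- sweep(sweep(logf, 2, colMeans(logf)), 2,
                apply(logf, 2, pop_sd), "/")
  beta_mat <- do.call(rbind, lapply(config$motifs, `[[`, "beta"))  # K x P
  y <- matrix(config$beta0, n, P, dimnames = list(gene_ids, config$populations))
  if (K > 0) y <- y + cmat %*% beta_mat
  y <- y + as.vector(hl_z %*% config$gamma)
  y <- y + matrix(rnorm(n * P, 0, config$sigma), n, P)
  if (config$silent_frac > 0) {
    ns <- round(config$silent_frac * n)
    if (ns > 0) {
      sg <- sample.int(n, ns)
      sp <- sample.int(P, ns, replace = TRUE)
      y[cbind(sg, sp)] <- -Inf
    }
  }

  # counts
  ncell <- config$n_cells
  total_cells <- sum(ncell)
  labels <- data.frame(
    barcode = sprintf("cell%04d", seq_len(total_cells)),
    population = rep(config$populations, ncell),
    class = rep(unname(config$classes[config$populations]), ncell),
    stringsAsFactors = FALSE)
  counts <- matrix(0L, n, total_cells,
                   dimnames = list(gene_ids, labels$barcode))
  libf <- rlnorm(total_cells, 0, config$lib_sdlog)
  for (cidx in seq_len(total_cells)) {
    p <- match(labels$population[cidx], config$populations)
    mu <- libf[cidx] * 10^y[, p]
    mu[!is.finite(mu)] <- 0
    counts[, cidx] <- if (config$count_model == "poisson") {
      rpois(n, mu)
    } else {
      rnbinom(n, size = 1 / config$dispersion, mu = mu)
    }
  }

  gtf <- build_gtf_table(genes)
  genome <- Biostrings::DNAStringSet(vapply(chrom_seq, paste, "", collapse = ""))
  names(genome) <- chrom_names

  structure(list(genome = genome, gtf = gtf,
                 counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                      "CsparseMatrix"),
                 labels = labels,
                 truth = list(y = y,
                              placements = if (length(placements))
                                do.call(rbind, placements) else
                                data.frame(gene_id = character(),
                                           motif = character(),
                                           offset = integer(),
                                           strand = character()),
                              hl_raw = data.frame(gene_id = gene_ids, hl_raw,
                                                  stringsAsFactors = FALSE),
                              copy_count = cmat),
                 config = config),
            class = "sim_data")
}

# GTF fields (1-based inclusive) for gene/transcript/exon/CDS features.
build_gtf_table <- function(genes) {
  rows <- list()
  for (gr in genes) {
    gid <- gr$gene_id
    tid <- paste0(gid, ".t1")
    attr_g <- sprintf('gene_id "%s"; gene_name "%s";', gid, gid)
    attr_t <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                      gid, tid, gid)
    span <- c(min(gr$exons[, 1]), max(gr$exons[, 2]))
    add <- function(type, s0, e0, attr) {
      data.frame(seqname = gr$chrom, source = "sim", feature = type,
                 start = s0 + 1L, end = e0, score = ".", strand = gr$strand,
                 frame = ".", attributes = attr, stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1]] <- add("gene", span[1], span[2], attr_g)
    rows[[length(rows) + 1]] <- add("transcript", span[1], span[2], attr_t)
    for (i in seq_len(nrow(gr$exons))) {
      rows[[length(rows) + 1]] <- add("exon", gr$exons[i, 1], gr$exons[i, 2],
                                      attr_t)
    }
    for (i in seq_len(nrow(gr$cds))) {
      rows[[length(rows) + 1]] <- add("CDS", gr$cds[i, 1], gr$cds[i, 2],
                                      attr_t)
    }
  }
  do.call(rbind, rows)
}

#' Write a simulated dataset in standard formats
#'
#' Emits the exact formats the real-data path consumes: `genome.fa`,
#' `annotation.gtf`, an MTX triplet under `counts/`, `labels.tsv`, and the
#' ground truth (`truth_y.tsv`, `truth_placements.tsv`).
#'
#' @param sim A `sim_data` from [simulate_dataset()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  g <- sim$gtf
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   g$seqname, g$source, g$feature, g$start, g$end, g$score,
                   g$strand, g$frame, g$attributes)
  writeLines(lines, file.path(dir, "annotation.gtf"))
  cdir <- file.path(dir, "counts")
  dir.create(cdir, showWarnings = FALSE)
  Matrix::writeMM(sim$counts, file.path(cdir, "matrix.mtx"))
  writeLines(rownames(sim$counts), file.path(cdir, "genes.tsv"))
  writeLines(colnames(sim$counts), file.path(cdir, "barcodes.tsv"))
  write.table(sim$labels, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  ytab <- data.frame(gene_id = rownames(sim$truth$y), sim$truth$y,
                     check.names = FALSE)
  write.table(ytab, file.path(dir, "truth_y.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$truth$placements, file.path(dir, "truth_placements.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Model configuration used for the synthetic benchmark
#'
#' A motif-detector geometry suited to small training sets: a wide bank of
#' first-layer filters whose responses are max-pooled globally (so detection
#' is position-invariant by construction), followed by a pointwise (width-1)
#' convolutional combination layer. With only ~1e3 training genes, the
#' reference promoter-CNN geometry with local pooling must additionally
#' learn position invariance in the head and fails to bootstrap motif
#' detection; global pooling makes the gradient reach a motif-aligned filter
#' whenever any filter responds maximally at a planted site.
#'
#' @param config A [sim_config()]; window extent and population count are
#'   taken from it.
#' @param conv_filters,conv_widths,dropout Overridable geometry defaults.
#' @return A [model_config()].
#' @export
benchmark_model_config <- function(config,
                                   conv_filters = c(256L, 32L),
                                   conv_widths = c(12L, 1L),
                                   dropout = 0.1) {
  L <- config$up_len + config$down_len
  model_config(up_len = config$up_len, down_len = config$down_len,
               n_tasks = length(config$populations),
               conv_filters = as.integer(conv_filters),
               conv_widths = as.integer(conv_widths),
               pool_widths = c(L - conv_widths[1] + 1L, 1L),
               dropout = dropout)
}

#' Motif-recovery and performance report for a trained ensemble
#'
#' Reports (1) held-out Pearson correlation per population between the
#' pseudobulk truth and the ensemble predictions on the log scale, (2) ISM
#' motif localization: the ratio of the mean absolute predicted effect
#' inside planted motif sites to the mean outside (background), and (3)
#' population specificity: for each planted motif, the mean absolute ISM
#' effect inside its sites per population (the motif's target population
#' should lead).
#'
#' @param sim The `sim_data` the model was trained on.
#' @param ensemble A trained `seqexpr_ensemble`.
#' @param data The [model_dataset()] used for training/evaluation.
#' @param truth_log genes x populations matrix of unstandardized log targets
#'   (the pseudobulk values).
#' @param test_genes Gene ids held out from training.
#' @param ism_genes Number of motif-bearing test genes profiled with ISM.
#' @return list with `population_r`, `ism_enrichment`, `motif_task_effect`
#'   (motif x population matrix) and the profiled gene ids.
#' @export
benchmark_report <- function(sim, ensemble, data, truth_log, test_genes,
                             ism_genes = 8L) {
  stopifnot(all(test_genes %in% data$gene_ids))
  idx <- match(test_genes, data$gene_ids)
  sub <- structure(list(codes = data$codes[, idx, drop = FALSE],
                        halflife = data$halflife[idx, , drop = FALSE],
                        targets = NULL, gene_ids = test_genes,
                        tasks = data$tasks,
                        standardizer = ensemble$standardizer),
                   class = "model_dataset")
  pred <- predict(ensemble, sub, scale = "log")
  pops <- colnames(truth_log)
  population_r <- vapply(pops, function(p) {
    suppressWarnings(pearson_cor(truth_log[test_genes, p], pred[, p]))
  }, numeric(1))

  pl <- sim$truth$placements
  mot_genes <- intersect(test_genes, unique(pl$gene_id))
  mot_genes <- head(mot_genes, ism_genes)
  inside_sum <- outside_sum <- 0
  inside_n <- outside_n <- 0
  motif_names <- vapply(sim$config$motifs, `[[`, "", "name")
  mt_sum <- matrix(0, length(motif_names), length(pops),
                   dimnames = list(motif_names, pops))
  mt_n <- matrix(0, length(motif_names), length(pops),
                 dimnames = list(motif_names, pops))
  profiles <- list()
  for (gid in mot_genes) {
    gi <- match(gid, data$gene_ids)
    window <- paste(IUPAC_LETTERS[data$codes[, gi]], collapse = "")
    prof <- saturation_mutagenesis(ensemble, window, data$halflife[gi, ],
                                   gene_id = gid)
    profiles[[gid]] <- prof
    gp <- pl[pl$gene_id == gid, , drop = FALSE]
    L <- length(prof$ref)
    in_site <- rep(FALSE, L)
    for (r in seq_len(nrow(gp))) {
      ml <- nchar(sim$config$motifs[[match(gp$motif[r], motif_names)]]$consensus)
      in_site[(gp$offset[r] + 1):(gp$offset[r] + ml)] <- TRUE
    }
    abs_eff <- abs(prof$effects)                       # L x 3 x P
    pos_mean <- apply(abs_eff, 1, mean, na.rm = TRUE)  # over alts and tasks
    inside_sum <- inside_sum + sum(pos_mean[in_site], na.rm = TRUE)
    inside_n <- inside_n + sum(in_site & !is.na(pos_mean))
    outside_sum <- outside_sum + sum(pos_mean[!in_site], na.rm = TRUE)
    outside_n <- outside_n + sum(!in_site & !is.na(pos_mean))
    for (r in seq_len(nrow(gp))) {
      k <- match(gp$motif[r], motif_names)
      ml <- nchar(sim$config$motifs[[k]]$consensus)
      site <- (gp$offset[r] + 1):(gp$offset[r] + ml)
      for (p in seq_along(pops)) {
        v <- abs_eff[site, , p]
        mt_sum[k, p] <- mt_sum[k, p] + sum(v, na.rm = TRUE)
        mt_n[k, p] <- mt_n[k, p] + sum(!is.na(v))
      }
    }
  }
  list(population_r = population_r,
       ism_enrichment = (inside_sum / inside_n) / (outside_sum / outside_n),
       motif_task_effect = mt_sum / pmax(mt_n, 1),
       ism_gene_ids = mot_genes,
       profiles = profiles)
}
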