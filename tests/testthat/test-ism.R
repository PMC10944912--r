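# ISM tests run on small untrained (random-weight) ensembles: consistency,
# combinatorics and error contracts do not depend on training.

make_tiny_ensemble <- function(Tn = 2, seed = 1, up = 60L, down = 40L) {
  cfg <- model_config(up_len = up, down_len = down, n_tasks = Tn,
                      conv_filters = c(6L, 4L), conv_widths = c(5L, 3L),
                      pool_widths = c(4L, 2L), dropout = 0)
  models <- lapply(seed + 0:1, function(s) build_model(cfg, seed = s, head_sd = 1))
  structure(list(models = models, config = cfg,
                 tasks = paste0("P", seq_len(Tn)),
                 standardizer = data.frame(population = paste0("P", seq_len(Tn)),
                                           mean = c(1, -1)[seq_len(Tn)],
                                           sd = c(2, 0.5)[seq_len(Tn)]),
                 seeds = seed + 0:1), class = "seqexpr_ensemble")
}

test_that("saturation profiles cover exactly the three alternatives per position", {
  set.seed(20)
  ens <- make_tiny_ensemble()
  win <- random_dna(100)
  hl <- rnorm(5)
  prof <- saturation_mutagenesis(ens, win, hl, gene_id = "g1")
  expect_equal(dim(prof$effects), c(100, 3, 2))
  expect_true(all(is.finite(prof$effects)))
  # alternatives never equal the reference and follow A<C<G<T order
  for (i in c(1, 37, 100)) {
    expect_false(prof$ref[i] %in% prof$alts[i, ])
    expect_equal(prof$alts[i, ], sort(prof$alts[i, ]))
  }
})

test_that("ambiguous reference positions are flagged as missing", {
  set.seed(21)
  ens <- make_tiny_ensemble()
  win <- random_dna(100)
  substr(win, 10, 10) <- "N"
  prof <- saturation_mutagenesis(ens, win, rnorm(5))
  expect_true(all(is.na(prof$effects[10, , ])))
  expect_true(all(is.finite(prof$effects[11, , ])))
})

test_that("a model whose convolution weights are zero yields zero effects", {
  set.seed(22)
  ens <- make_tiny_ensemble(Tn = 2)
  for (r in seq_along(ens$models)) {
    ens$models[[r]]$weights$W1[] <- 0
    ens$models[[r]]$weights$b1[] <- 0
  }
  prof <- saturation_mutagenesis(ens, random_dna(100), rnorm(5))
  expect_true(all(abs(prof$effects) < 1e-6))
})

test_that("max-effect profiles keep the sign of the largest absolute effect", {
  prof <- structure(list(gene_id = "g", ref = c("A", "C"),
                         alts = rbind(c("C", "G", "T"), c("A", "G", "T")),
                         effects = array(c(-0.3, 0, 0.1, 0, 0.2, 0),
                                         dim = c(2, 3, 1)),
                         tasks = "P1"), class = "ism_profile")
  expect_equal(max_effect_profile(prof, 1), c(-0.3, 0))
  # random profiles match a brute-force scan
  set.seed(23)
  eff <- array(rnorm(30), dim = c(10, 3, 1))
  prof$ref <- rep("A", 10); prof$alts <- matrix("C", 10, 3)
  prof$effects <- eff
  got <- max_effect_profile(prof, 1)
  want <- vapply(1:10, function(i) {
    e <- eff[i, , 1]; e[which.max(abs(e))]
  }, 1)
  expect_equal(got, want)
})

test_that("the positional mean-max formula matches direct evaluation", {
  set.seed(24)
  mk <- function(eff) structure(
    list(gene_id = "g", ref = rep("A", 6), alts = matrix("C", 6, 3),
         effects = eff, tasks = "P1"), class = "ism_profile")
  effs <- lapply(1:3, function(i) array(rnorm(18), dim = c(6, 3, 1)))
  profs <- lapply(effs, mk)
  got <- hvg_mean_max_profile(profs, 1)
  want <- rowMeans(sapply(effs, function(e)
    apply(abs(e[, , 1]), 1, max)))
  expect_equal(got, want)
  # one gene: equals that gene's absolute max-effect profile
  expect_equal(hvg_mean_max_profile(profs[1], 1),
               abs(max_effect_profile(profs[[1]], 1)))
  # mirrored profiles average to the common absolute profile
  m2 <- mk(-effs[[1]])
  expect_equal(hvg_mean_max_profile(list(profs[[1]], m2), 1),
               abs(max_effect_profile(profs[[1]], 1)))
  bad <- mk(array(0, dim = c(5, 3, 1))); bad$ref <- rep("A", 5)
  expect_error(hvg_mean_max_profile(list(profs[[1]], bad), 1), "lengths")
})

test_that("variant effects equal the matching saturation-mutagenesis entries", {
  set.seed(25)
  ens <- make_tiny_ensemble()
  L <- ens$config$L; up <- ens$config$up_len
  win <- random_dna(L)
  hl <- rnorm(5)
  prof <- saturation_mutagenesis(ens, win, hl, gene_id = "g1")
  gene_plus <- list(gene_id = "g1", strand = "+", tss = 5000L, chrom = "chr1")
  wchars <- strsplit(win, "")[[1]]
  for (i in 1:25) {
    off <- sample(0:(L - 1), 1)
    pos <- 5000 - up + off + 1  # 1-based genomic on '+'
    ref <- wchars[off + 1]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ve <- variant_effect(ens, gene_plus, win, hl, pos, ref, alt)
    ai <- match(alt, prof$alts[off + 1, ])
    for (tk in 1:2) {
      # chunked vs single-sequence forward passes differ only by float
      # accumulation order, so compare with an absolute tolerance
      expect_lt(abs(ve$effect[ve$task == ens$tasks[tk]] -
                    prof$effects[off + 1, ai, tk]), 2e-5)
    }
  }
  # minus-strand mapping: same checks with flipped coordinates and alleles
  gene_minus <- list(gene_id = "g2", strand = "-", tss = 5000L, chrom = "chr1")
  for (i in 1:25) {
    off <- sample(0:(L - 1), 1)
    pos <- 5000 + up - off + 1  # 1-based genomic on '-'
    ref_w <- wchars[off + 1]
    alt_w <- sample(setdiff(c("A", "C", "G", "T"), ref_w), 1)
    ve <- variant_effect(ens, gene_minus, win, hl, pos,
                         reverse_complement(ref_w), reverse_complement(alt_w))
    ai <- match(alt_w, prof$alts[off + 1, ])
    expect_lt(abs(ve$effect[ve$task == "P1"] - prof$effects[off + 1, ai, 1]),
              2e-5)
  }
})

test_that("percentile ranks position a variant within the gene's ISM distribution", {
  set.seed(26)
  ens <- make_tiny_ensemble()
  win <- random_dna(ens$config$L)
  hl <- rnorm(5)
  prof <- saturation_mutagenesis(ens, win, hl, gene_id = "g1")
  gene <- list(gene_id = "g1", strand = "+", tss = 5000L, chrom = "chr1")
  off <- 10
  pos <- 5000 - ens$config$up_len + off + 1
  ref <- substr(win, off + 1, off + 1)
  ve <- variant_effect(ens, gene, win, hl, pos, ref, alt = NA, profile = prof)
  expect_equal(nrow(ve), 6)  # 3 alternatives x 2 tasks
  expect_true(all(ve$percentile >= 0 & ve$percentile <= 100))
  # the rank of the largest |effect| in the profile is 100
  tk <- "P1"
  big <- which.max(abs(prof$effects[, , 1]))
  idx <- arrayInd(big, dim(prof$effects[, , 1]))
  pos_big <- 5000 - ens$config$up_len + idx[1]
  ve_big <- variant_effect(ens, gene, win, hl, pos_big,
                           substr(win, idx[1], idx[1]),
                           prof$alts[idx[1], idx[2]], profile = prof)
  expect_equal(max(ve_big$percentile[ve_big$task == tk]), 100)
})

test_that("out-of-window and mismatching variants raise the specified errors", {
  set.seed(27)
  ens <- make_tiny_ensemble()
  up <- ens$config$up_len
  win <- random_dna(ens$config$L)
  gene <- list(gene_id = "g1", strand = "+", tss = 5000L, chrom = "chr1")
  # variant upstream of the window start
  expect_error(variant_effect(ens, gene, win, rnorm(5),
                              5000 - up - 100, "A", "C"), "outside")
  # reference allele disagreeing with the genome
  off <- 5
  ref <- substr(win, off + 1, off + 1)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(variant_effect(ens, gene, win, rnorm(5),
                              5000 - up + off + 1, wrong, "A"),
               "mismatch")
})

test_that("mutating back restores the wild-type prediction", {
  set.seed(28)
  ens <- make_tiny_ensemble()
  L <- ens$config$L; up <- ens$config$up_len
  win <- random_dna(L)
  hl <- rnorm(5)
  off <- 17
  ref <- substr(win, off + 1, off + 1)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[2]
  gene <- list(gene_id = "g1", strand = "+", tss = 5000L, chrom = "chr1")
  fwd <- variant_effect(ens, gene, win, hl, 5000 - up + off + 1, ref, alt)
  mut_win <- win
  substr(mut_win, off + 1, off + 1) <- alt
  back <- variant_effect(ens, gene, mut_win, hl, 5000 - up + off + 1, alt, ref)
  expect_equal(back$effect, -fwd$effect, tolerance = 1e-6)
})

test_that("profiles export one TSV row per alternative", {
  set.seed(29)
  ens <- make_tiny_ensemble()
  prof <- saturation_mutagenesis(ens, random_dna(ens$config$L), rnorm(5),
                                 gene_id = "g1")
  path <- tempfile(fileext = ".tsv")
  write_ism_profile(prof, path)
  df <- read.delim(path)
  expect_equal(nrow(df), ens$config$L * 3)
  expect_equal(df$P1[1:3], prof$effects[1, , 1])
})
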