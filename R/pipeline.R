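# End-to-end orchestration: prepare -> pseudobulk -> folds -> train -> predict
# -> evaluate, with one global seed deriving per-stage seeds and a manifest
# recording configuration and seeds.

#' Experiment configuration
#'
#' Inputs can be file paths (FASTA/GTF/MTX/TSV) or in-memory objects
#' (`DNAStringSet`, gene tables, matrices), so the same driver serves both
#' the command line and programmatic use.
#'
#' @param genome FASTA path or `DNAStringSet`.
#' @param gtf GTF path.
#' @param counts Matrix, or directory containing an MTX triplet.
#' @param labels data.frame (`barcode`, `population`, optional `class`) or a
#'   TSV path.
#' @param canonical_map Optional gene -> transcript mapping (TSV path or
#'   data.frame).
#' @param protocol Count normalization protocol; see [normalize_counts()].
#' @param sentinel Pseudobulk sentinel for all-zero genes (default -4; use
#'   -5 for the motor-cortex convention).
#' @param resolution Aggregation resolution: "population" and "class" use
#'   the corresponding label column as tasks; "tissue" collapses all cells
#'   into one task.
#' @param up_len,down_len Window extent.
#' @param model Named list of [model_config()] overrides (e.g. smaller
#'   filter counts for desk-scale runs).
#' @param train Named list of [train_config()] overrides.
#' @param k,scheme Fold plan settings; see [make_folds()].
#' @param folds_subset Which folds to train (default all k).
#' @param n_replicates Ensemble replicates per fold.
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param out_dir Optional output directory for artifacts and the manifest.
#' @return A `run_config` list.
#' @export
run_config <- function(genome, gtf, counts, labels, canonical_map = NULL,
                       protocol = "tenx", sentinel = -4,
                       resolution = c("population", "tissue", "class"),
                       up_len = 7000L, down_len = 3500L,
                       model = list(), train = list(),
                       k = 20L, scheme = "random_gene",
                       folds_subset = NULL, n_replicates = 5L,
                       seed = 1L, out_dir = NULL) {
  structure(list(genome = genome, gtf = gtf, counts = counts, labels = labels,
                 canonical_map = canonical_map, protocol = protocol,
                 sentinel = sentinel, resolution = match.arg(resolution),
                 up_len = as.integer(up_len), down_len = as.integer(down_len),
                 model = model, train = train, k = as.integer(k),
                 scheme = scheme, folds_subset = folds_subset,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# Deterministic per-stage seed derived from the global seed and stage name.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' Run an experiment end to end
#'
#' Executes prepare (genes, windows, half-life), pseudobulk, fold
#' construction, per-fold ensemble training, prediction of each fold's test
#' genes, and evaluation. When `out_dir` is set, writes the pseudobulk TSV,
#' per-fold predictions, the performance report and a JSON manifest
#' (config, seeds, package version).
#'
#' @param config A [run_config()].
#' @return list with `genes`, `pb` (standardized `pb_matrix`), `data`,
#'   `fold_plan`, `ensembles` (by fold), `pred` (log-scale predictions for
#'   all test genes), `truth_log`, `report` and `summary`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))

  # --- prepare -------------------------------------------------------------
  canonical <- config$canonical_map
  if (is.character(canonical)) canonical <- read.delim(canonical, header = FALSE)
  genes <- load_genes(config$gtf, canonical_map = canonical)
  windows <- extract_windows(config$genome, genes, config$up_len, config$down_len)
  hl_raw <- halflife_features(genes)
  hl <- normalize_halflife(hl_raw)

  # --- counts and labels ---------------------------------------------------
  counts <- config$counts
  if (is.character(counts)) counts <- read_counts_mtx(counts)
  labels <- config$labels
  if (is.character(labels)) labels <- read.delim(labels)
  lab_vec <- switch(config$resolution,
                    tissue = rep("tissue", nrow(labels)),
                    population = labels$population,
                    class = labels$class)
  if (is.null(lab_vec)) {
    stop(sprintf("label column for resolution '%s' missing", config$resolution))
  }

  # --- pseudobulk ----------------------------------------------------------
  glen <- exonic_lengths(genes)
  norm <- normalize_counts(counts, config$protocol,
                           gene_lengths = if (config$protocol == "bulk") glen)
  pb <- pseudobulk_aggregate(norm, lab_vec, sentinel = config$sentinel)
  pb <- pb_standardize(pb)

  common <- intersect(genes$gene_id, rownames(pb$values))
  genes <- genes[match(common, genes$gene_id), ]
  windows <- windows[common]
  targets <- pb$values[common, , drop = FALSE]
  data <- model_dataset(windows, hl$features, targets,
                        standardizer = pb$standardizer)

  # --- folds ---------------------------------------------------------------
  plan <- make_folds(genes, k = config$k, scheme = config$scheme,
                     seed = stage_seed(config$seed, "folds"))
  fold_ids <- config$folds_subset %||% seq_len(config$k)

  mcfg <- do.call(model_config, c(
    list(up_len = config$up_len, down_len = config$down_len,
         n_tasks = ncol(targets)),
    config$model))
  tcfg <- do.call(train_config, config$train)

  # --- train + predict per fold -------------------------------------------
  ensembles <- list()
  pred <- matrix(NA_real_, nrow(targets), ncol(targets),
                 dimnames = dimnames(targets))
  for (fi in fold_ids) {
    fold <- plan$folds[[fi]]
    tr <- match(intersect(fold$train, common), data$gene_ids)
    va <- match(intersect(fold$val, common), data$gene_ids)
    te <- match(intersect(fold$test, common), data$gene_ids)
    ens <- train_ensemble(data, tr, va, mcfg, tcfg,
                          n_replicates = config$n_replicates,
                          base_seed = stage_seed(config$seed,
                                                 sprintf("train_fold%d", fi)))
    ensembles[[as.character(fi)]] <- ens
    sub <- structure(list(codes = data$codes[, te, drop = FALSE],
                          halflife = data$halflife[te, , drop = FALSE],
                          targets = NULL, gene_ids = data$gene_ids[te],
                          tasks = data$tasks,
                          standardizer = pb$standardizer),
                     class = "model_dataset")
    pred[te, ] <- predict(ens, sub, scale = "log")
  }

  truth_log <- pb_unstandardize(targets, pb$standardizer)
  scored <- !is.na(pred[, 1])
  report <- performance_report(truth_log[scored, , drop = FALSE],
                               pred[scored, , drop = FALSE], plan)
  result <- list(genes = genes, pb = pb, data = data, fold_plan = plan,
                 ensembles = ensembles, pred = pred, truth_log = truth_log,
                 report = report, summary = summarize_performance(report),
                 config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pseudobulk(pb, config$out_dir)
    write.table(report, file.path(config$out_dir, "performance_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(result$summary,
                file.path(config$out_dir, "performance_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    preddf <- data.frame(gene_id = rownames(pred)[scored],
                         pred[scored, , drop = FALSE], check.names = FALSE)
    write.table(preddf, file.path(config$out_dir, "predictions_log.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("seqexpr")),
      seed = config$seed,
      stage_seeds = list(folds = stage_seed(config$seed, "folds"),
                         train = vapply(fold_ids, function(fi)
                           stage_seed(config$seed, sprintf("train_fold%d", fi)),
                           1L)),
      resolution = config$resolution, protocol = config$protocol,
      sentinel = config$sentinel, k = config$k, scheme = config$scheme,
      folds_trained = fold_ids, n_replicates = config$n_replicates,
      window = c(config$up_len, config$down_len),
      model = unclass(mcfg), train = unclass(tcfg))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
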