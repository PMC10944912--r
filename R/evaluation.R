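# Cross-validation folds, performance metrics, model comparison and
# hierarchy broadcasting.

#' Build a cross-validation fold plan
#'
#' `random_gene`: genes are shuffled with the seed and split into k
#' equal-as-possible test folds; the validation set of fold i is the next
#' test fold cyclically and the training set is the rest, so the three sets
#' are disjoint and the test sets partition the gene universe.
#' `cross_chromosome`: chromosomes are first assigned to k bins balancing
#' gene counts (greedy, largest chromosome first), then the same rotation is
#' applied to bins, so no chromosome contributes genes to more than one of a
#' fold's three sets.
#'
#' @param genes A [load_genes()] table, or a character vector of gene ids
#'   (random scheme only).
#' @param k Number of folds (default 20).
#' @param scheme "random_gene" or "cross_chromosome".
#' @param seed RNG seed; the same seed reproduces the same plan, which is the
#'   basis for comparing model variants on identical splits.
#' @return A `fold_plan`: list with `k`, `scheme`, `seed` and `folds`, each
#'   fold holding disjoint `train`, `val`, `test` gene-id vectors.
#' @export
make_folds <- function(genes, k = 20L, scheme = c("random_gene", "cross_chromosome"),
                       seed = 1L) {
  scheme <- match.arg(scheme)
  ids <- if (is.character(genes)) genes else genes$gene_id
  if (scheme == "random_gene") {
    if (length(ids) < k) stop("need at least k genes for k folds")
    groups <- local({
      set.seed(seed)
      shuffled <- sample(ids)
      split(shuffled, rep_len(seq_len(k), length(shuffled)))
    })
  } else {
    if (is.character(genes)) stop("cross_chromosome scheme needs a gene table with chrom")
    chroms <- table(genes$chrom)
    if (length(chroms) < k) {
      stop(sprintf("only %d chromosomes for %d bins; use a smaller k",
                   length(chroms), k))
    }
    ord <- order(chroms, names(chroms), decreasing = TRUE)
    bin_of <- setNames(integer(length(chroms)), names(chroms)[ord])
    load <- numeric(k)
    for (cn in names(bin_of)) {
      b <- which.min(load)
      bin_of[cn] <- b
      load[b] <- load[b] + chroms[[cn]]
    }
    groups <- lapply(seq_len(k), function(b) {
      ids[genes$chrom %in% names(bin_of)[bin_of == b]]
    })
  }
  folds <- lapply(seq_len(k), function(i) {
    vi <- if (i == k) 1L else i + 1L
    list(test = groups[[i]], val = groups[[vi]],
         train = unlist(groups[-c(i, vi)], use.names = FALSE))
  })
  structure(list(k = as.integer(k), scheme = scheme, seed = as.integer(seed),
                 folds = folds), class = "fold_plan")
}

#' Pearson correlation with metric guards
#'
#' @param x,y Equal-length numeric vectors (length >= 3). A constant input
#'   makes the correlation undefined: `NA` is returned with a warning.
#' @return Pearson product-moment correlation.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (pop_sd(x) == 0 || pop_sd(y) == 0) {
    warning("Pearson correlation undefined for constant input")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Per-gene correlation across populations
#'
#' Row-wise Pearson correlation between true and predicted expression across
#' populations, computed on the unstandardized log scale. A gene with a flat
#' profile in either matrix yields `NA`.
#'
#' @param true,pred genes x populations matrices (>= 3 populations).
#' @return Named numeric vector, one r per gene.
#' @export
per_gene_correlation <- function(true, pred) {
  stopifnot(all(dim(true) == dim(pred)), ncol(true) >= 3)
  r <- vapply(seq_len(nrow(true)), function(g) {
    tx <- true[g, ]; px <- pred[g, ]
    if (pop_sd(tx) == 0 || pop_sd(px) == 0) return(NA_real_)
    stats::cor(tx, px)
  }, numeric(1))
  names(r) <- rownames(true)
  r
}

#' Assemble a cross-validated performance report
#'
#' @param truth,pred genes x populations matrices on the unstandardized log
#'   scale, aligned by gene id rownames.
#' @param fold_plan A `fold_plan`; per population and fold, the Pearson
#'   correlation is computed over that fold's test genes.
#' @return data.frame (`population`, `fold`, `r`).
#' @export
performance_report <- function(truth, pred, fold_plan) {
  stopifnot(inherits(fold_plan, "fold_plan"))
  rows <- list()
  for (i in seq_along(fold_plan$folds)) {
    test <- intersect(fold_plan$folds[[i]]$test, rownames(pred))
    if (length(test) < 3) next
    for (p in colnames(truth)) {
      rows[[length(rows) + 1]] <- data.frame(
        population = p, fold = i,
        r = suppressWarnings(pearson_cor(truth[test, p], pred[test, p])))
    }
  }
  do.call(rbind, rows)
}

#' Median fold-wise performance per population
#'
#' @param report A report from [performance_report()].
#' @return data.frame (`population`, `median_r`).
#' @export
summarize_performance <- function(report) {
  agg <- tapply(report$r, report$population, median, na.rm = TRUE)
  data.frame(population = names(agg), median_r = as.numeric(agg),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Performance gain of the population model over the tissue model
#'
#' For each population, the median-over-folds Pearson correlation of the
#' cell-population model minus that of the tissue model evaluated on the
#' same folds.
#'
#' @param cp_report,t_report Reports from [performance_report()] covering the
#'   same folds and populations.
#' @return data.frame (`population`, `delta`).
#' @export
delta_cp_t <- function(cp_report, t_report) {
  if (!setequal(unique(cp_report$fold), unique(t_report$fold))) {
    stop("reports cover different folds")
  }
  cp <- summarize_performance(cp_report)
  tt <- summarize_performance(t_report)
  if (!setequal(cp$population, tt$population)) {
    stop("reports cover different populations")
  }
  tt <- tt[match(cp$population, tt$population), ]
  data.frame(population = cp$population, delta = cp$median_r - tt$median_r,
             stringsAsFactors = FALSE)
}

#' Rank-sum comparison of two models' fold-wise performance
#'
#' One-sided two-sample Wilcoxon rank-sum test that model `a` reaches higher
#' fold-wise correlations than model `b`, pooled over populations.
#'
#' @param report_a,report_b Reports from [performance_report()].
#' @param alternative Passed to [stats::wilcox.test()] (default "greater").
#' @return The `htest` object.
#' @export
compare_performance <- function(report_a, report_b, alternative = "greater") {
  wilcox.test(report_a$r, report_b$r, alternative = alternative,
              exact = FALSE)
}

#' Broadcast parent-class predictions to child populations
#'
#' A coarse-resolution model (tissue or class level) predicts one value per
#' parent; children inherit their parent's column, so the coarse model can be
#' scored on the fine-grained task.
#'
#' @param parent_pred genes x parents prediction matrix.
#' @param hierarchy Named character vector mapping child -> parent.
#' @return genes x children matrix, each column a copy of its parent column.
#' @export
broadcast_parent_predictions <- function(parent_pred, hierarchy) {
  missing <- setdiff(unname(hierarchy), colnames(parent_pred))
  if (length(missing)) {
    stop(sprintf("no parent column for: %s", paste(missing, collapse = ", ")))
  }
  out <- parent_pred[, unname(hierarchy), drop = FALSE]
  colnames(out) <- names(hierarchy)
  out
}
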