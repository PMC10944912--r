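test_that("random-gene folds partition genes with cyclic validation sets", {
  ids <- sprintf("g%03d", 1:100)
  plan <- make_folds(ids, k = 20, seed = 4)
  expect_length(plan$folds, 20)
  sizes <- vapply(plan$folds, function(f) length(f$test), 1L)
  expect_true(all(sizes == 5))  # 100 genes over 20 folds
  expect_setequal(unlist(lapply(plan$folds, `[[`, "test")), ids)
  for (f in plan$folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_length(intersect(f$train, f$val), 0)
    expect_length(intersect(f$val, f$test), 0)
    expect_setequal(c(f$train, f$val, f$test), ids)
  }
  # validation set of fold i is the test set of fold i+1 (cyclically)
  expect_setequal(plan$folds[[1]]$val, plan$folds[[2]]$test)
  expect_setequal(plan$folds[[20]]$val, plan$folds[[1]]$test)
  # reproducibility
  expect_identical(plan, make_folds(ids, k = 20, seed = 4))
  expect_false(identical(plan$folds, make_folds(ids, k = 20, seed = 5)$folds))
})

test_that("cross-chromosome folds never split a chromosome across sets", {
  set.seed(9)
  genes <- data.frame(
    gene_id = sprintf("g%03d", 1:120),
    chrom = sample(sprintf("chr%d", 1:8), 120, replace = TRUE,
                   prob = c(4, 3, 2, 2, 1, 1, 1, 1)))
  plan <- make_folds(genes, k = 6, scheme = "cross_chromosome", seed = 2)
  chrom_of <- setNames(genes$chrom, genes$gene_id)
  for (f in plan$folds) {
    expect_length(intersect(unique(chrom_of[f$train]),
                            unique(chrom_of[f$test])), 0)
    expect_length(intersect(unique(chrom_of[f$val]),
                            unique(chrom_of[f$test])), 0)
  }
  expect_error(make_folds(genes, k = 10, scheme = "cross_chromosome"),
               "smaller k")
})

test_that("pearson correlation matches its closed forms and guards", {
  expect_equal(pearson_cor(1:5, 1:5 * 2 + 3), 1.0)
  x <- c(-2, -1, 0, 1, 2)
  expect_equal(pearson_cor(x, -x), -1.0)
  expect_equal(pearson_cor(c(1, 2, 3, 4), c(1, 2, 3, 5)), 0.98270,
               tolerance = 1e-5)
  expect_warning(r <- pearson_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(r))
})

test_that("pearson agrees with a textbook two-pass implementation", {
  two_pass <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  set.seed(14)
  for (i in 1:100) {
    n <- sample(5:50, 1)
    x <- rnorm(n); y <- rnorm(n)
    expect_equal(pearson_cor(x, y), two_pass(x, y), tolerance = 1e-12)
  }
})

test_that("per-gene correlation is row-wise, affine-invariant and guarded", {
  truth <- rbind(g1 = c(1, 3, 2, 5), g2 = c(2, 2, 2, 2), g3 = c(0, 1, 2, 3))
  pred <- rbind(g1 = c(10, 30, 20, 50) + 7, g2 = c(1, 2, 3, 4),
                g3 = c(3, 2, 1, 0))
  r <- per_gene_correlation(truth, pred)
  expect_equal(unname(r["g1"]), 1.0)   # correct ranking up to affine map
  expect_true(is.na(r["g2"]))          # flat true profile
  expect_equal(unname(r["g3"]), -1.0)
  # random matrices match a brute-force loop
  set.seed(15)
  for (i in 1:20) {
    t2 <- matrix(rnorm(40), 8, 5)
    p2 <- matrix(rnorm(40), 8, 5)
    expect_equal(unname(per_gene_correlation(t2, p2)),
                 vapply(1:8, function(g) cor(t2[g, ], p2[g, ]), 1),
                 tolerance = 1e-12)
  }
})

test_that("delta between model resolutions is a difference of fold medians", {
  cp <- data.frame(population = "P", fold = 1:3, r = c(0.70, 0.71, 0.72))
  tt <- data.frame(population = "P", fold = 1:3, r = c(0.74, 0.75, 0.76))
  d <- delta_cp_t(cp, tt)
  expect_equal(d$delta, 0.71 - 0.75)
  expect_equal(delta_cp_t(cp, cp)$delta, 0)
  # permutation of fold order leaves the medians unchanged
  expect_equal(delta_cp_t(cp[c(3, 1, 2), ], tt)$delta, -0.04)
  expect_error(delta_cp_t(cp, tt[tt$fold < 3, ]), "folds")
})

test_that("parent predictions broadcast to children by copying columns", {
  parent <- matrix(rnorm(15), 5, 3,
                   dimnames = list(paste0("g", 1:5), c("A", "B", "C")))
  hier <- setNames(rep(c("A", "B", "C"), c(8, 7, 5)), paste0("sub", 1:20))
  child <- broadcast_parent_predictions(parent, hier)
  expect_equal(dim(child), c(5, 20))
  for (s in names(hier)) expect_equal(child[, s], parent[, hier[[s]]])
  # single-parent hierarchy: all children identical
  one <- broadcast_parent_predictions(parent[, "A", drop = FALSE],
                                      c(x = "A", y = "A"))
  expect_equal(one[, "x"], one[, "y"])
  # aggregating children by parent recovers the parent predictions
  agg <- sapply(c("A", "B", "C"), function(p)
    rowMeans(child[, names(hier)[hier == p], drop = FALSE]))
  expect_equal(agg, parent)
  expect_error(broadcast_parent_predictions(parent, c(z = "D")), "D")
})

test_that("performance reports summarize fold-wise correlations per population", {
  set.seed(16)
  ids <- sprintf("g%03d", 1:60)
  plan <- make_folds(ids, k = 5, seed = 1)
  truth <- matrix(rnorm(120), 60, 2, dimnames = list(ids, c("P1", "P2")))
  pred <- truth + matrix(rnorm(120, sd = 0.2), 60, 2)
  rep <- performance_report(truth, pred, plan)
  expect_equal(nrow(rep), 10)  # 5 folds x 2 populations
  s <- summarize_performance(rep)
  expect_equal(s$median_r,
               c(median(rep$r[rep$population == "P1"]),
                 median(rep$r[rep$population == "P2"])))
  # a model compared against a clearly worse one wins the rank-sum test
  worse <- matrix(rnorm(120), 60, 2, dimnames = dimnames(truth))
  rep_bad <- performance_report(truth, worse, plan)
  expect_lt(compare_performance(rep, rep_bad)$p.value, 0.01)
})
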