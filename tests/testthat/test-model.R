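tiny_cfg <- function(Tn = 3, dropout = 0) {
  model_config(up_len = 80, down_len = 40, n_tasks = Tn,
               conv_filters = c(8L, 6L), conv_widths = c(5L, 3L),
               pool_widths = c(4L, 2L), dropout = dropout)
}

test_that("configurations that collapse the window are rejected", {
  expect_error(model_config(up_len = 4, down_len = 2, n_tasks = 1,
                            conv_widths = c(6L, 9L)),
               "flattened size 0")
  expect_error(train_config(lr_factor = 1), "lr_factor")
})

test_that("an untrained network respects the shape and determinism contracts", {
  cfg <- model_config(up_len = 60, down_len = 40, n_tasks = 7,
                      conv_filters = c(6L, 4L), conv_widths = c(5L, 3L),
                      pool_widths = c(4L, 2L))
  d <- random_dataset(5, 100, 7, seed = 2)
  m <- build_model(cfg, seed = 1, head_sd = 1)
  p <- predict(m, d)
  expect_equal(dim(p), c(5, 7))
  # identical inputs give identical outputs
  d2 <- d
  d2$codes[, 2] <- d2$codes[, 1]
  d2$halflife[2, ] <- d2$halflife[1, ]
  p2 <- predict(m, d2)
  expect_equal(p2[1, ], p2[2, ])
  # sequence channels reach the output: all-N vs all-A inputs differ
  dn <- d
  dn$codes[, 1] <- match("N", c("A", "C", "G", "T", "R", "Y", "S", "W",
                                "K", "M", "B", "D", "H", "V", "N"))
  dn$codes[, 2] <- 1L
  dn$halflife[2, ] <- dn$halflife[1, ]
  pn <- predict(m, dn)
  expect_gt(abs(pn[1, 1] - pn[2, 1]), 1e-6)
})

test_that("the compiled forward pass matches an independent R implementation", {
  for (hidden in list(integer(0), 16L)) {
    cfg <- model_config(up_len = 60, down_len = 40, n_tasks = 2,
                        conv_filters = c(7L, 5L), conv_widths = c(6L, 3L),
                        pool_widths = c(5L, 3L), fc_hidden = hidden,
                        dropout = 0)
    d <- random_dataset(6, 100, 2, seed = 4,
                        alphabet = c("A", "C", "G", "T", "N", "R"))
    m <- build_model(cfg, seed = 9, head_sd = 1)
    seqs <- apply(d$codes, 2, function(cd)
      paste(colnames(iupac_onehot_table())[cd], collapse = ""))
    p_r <- r_forward(m$weights, cfg, seqs, d$halflife)
    expect_equal(unname(predict(m, d)), p_r, tolerance = 1e-5)
  }
})

test_that("analytic gradients agree with finite differences on the head and descend", {
  cfg <- tiny_cfg()
  d <- random_dataset(10, 120, 3, seed = 6)
  m <- build_model(cfg, seed = 3, head_sd = 1)
  tab <- iupac_onehot_table()
  lg <- seqexpr:::cpp_loss_grad(d$codes, tab, d$halflife, d$targets,
                                m$weights, cfg)
  # output layer is linear in its weights: finite differences are exact
  h <- 1e-2
  for (q in c(1, 5, 20)) {
    wp <- m$weights; wp$Wo[q] <- wp$Wo[q] + h
    wm <- m$weights; wm$Wo[q] <- wm$Wo[q] - h
    fd <- (seqexpr:::cpp_loss_grad(d$codes, tab, d$halflife, d$targets, wp, cfg)$loss -
           seqexpr:::cpp_loss_grad(d$codes, tab, d$halflife, d$targets, wm, cfg)$loss) / (2 * h)
    expect_equal(fd, lg$grads$Wo[q], tolerance = 1e-3)
  }
  # a small step along the negative gradient reduces the loss
  step <- m$weights
  for (nm in names(step)) step[[nm]] <- step[[nm]] - 0.01 * lg$grads[[nm]]
  l2 <- seqexpr:::cpp_loss_grad(d$codes, tab, d$halflife, d$targets, step, cfg)$loss
  expect_lt(l2, lg$loss)
})

test_that("training is seed-reproducible and fits constant targets", {
  cfg <- tiny_cfg(Tn = 2, dropout = 0.2)
  d <- random_dataset(60, 120, 2, seed = 8)
  d$targets[] <- 0.5
  tc <- train_config(initial_lr = 5e-3, batch_size = 8, max_epochs = 40)
  f1 <- train_model(d, 1:40, 41:60, cfg, tc, seed = 5)
  f2 <- train_model(d, 1:40, 41:60, cfg, tc, seed = 5)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$weights, f2$weights)
  # a different seed gives a different trajectory
  f3 <- train_model(d, 1:40, 41:60, cfg, tc, seed = 6)
  expect_false(identical(f1$weights, f3$weights))
  # without dropout noise the degenerate constant fit reaches ~0 MSE
  cfg0 <- tiny_cfg(Tn = 2, dropout = 0)
  f0 <- train_model(d, 1:40, 41:60, cfg0,
                    train_config(initial_lr = 1e-2, batch_size = 8,
                                 max_epochs = 40), seed = 5)
  expect_lt(f0$best_val_loss, 0.01)
})

test_that("train and validation sets must be disjoint and targets must match tasks", {
  cfg <- tiny_cfg(Tn = 2)
  d <- random_dataset(20, 120, 2, seed = 9)
  expect_error(train_model(d, 1:10, 10:15, cfg), "disjoint")
  cfg3 <- tiny_cfg(Tn = 3)
  expect_error(train_model(d, 1:10, 11:15, cfg3), "n_tasks")
})

test_that("ensembles hold one model per replicate and average predictions", {
  cfg <- tiny_cfg(Tn = 2)
  d <- random_dataset(30, 120, 2, seed = 10)
  tc <- train_config(batch_size = 8, max_epochs = 3)
  ens <- train_ensemble(d, 1:20, 21:30, cfg, tc, n_replicates = 5,
                        base_seed = 3)
  expect_length(ens$models, 5)
  expect_equal(ens$seeds, 3:7)
  expect_true(all(vapply(ens$models, function(m) nrow(m$history), 1L) == 3))
  # replicates with different seeds produce distinct parameters
  expect_false(identical(ens$models[[1]]$weights, ens$models[[2]]$weights))
  # n_replicates = 1 equals the single model's predictions
  ens1 <- train_ensemble(d, 1:20, 21:30, cfg, tc, n_replicates = 1,
                         base_seed = 3)
  expect_equal(predict(ens1, d), predict(ens1$models[[1]], d))
  # the ensemble is the element-wise mean of its replicates
  manual <- (predict(ens$models[[1]], d) + predict(ens$models[[2]], d) +
             predict(ens$models[[3]], d) + predict(ens$models[[4]], d) +
             predict(ens$models[[5]], d)) / 5
  expect_equal(predict(ens, d), manual, tolerance = 1e-10)
})

test_that("stored standardizers invert ensemble predictions", {
  cfg <- tiny_cfg(Tn = 2)
  d <- random_dataset(20, 120, 2, seed = 12)
  std <- data.frame(population = c("task1", "task2"), mean = c(1, -2),
                    sd = c(2, 0.5))
  d$standardizer <- std
  tc <- train_config(batch_size = 8, max_epochs = 2)
  ens <- train_ensemble(d, 1:12, 13:20, cfg, tc, n_replicates = 1)
  p_std <- predict(ens, d)
  p_log <- predict(ens, d, scale = "log")
  expect_equal(p_log, sweep(sweep(p_std, 2, std$sd, "*"), 2, std$mean, "+"))
  # identity standardizer leaves predictions unchanged
  ens$standardizer <- data.frame(population = c("task1", "task2"),
                                 mean = c(0, 0), sd = c(1, 1))
  expect_equal(predict(ens, d, scale = "log"), p_std)
})

test_that("ensembles survive a JSON round trip", {
  cfg <- tiny_cfg(Tn = 2)
  d <- random_dataset(20, 120, 2, seed = 13)
  d$standardizer <- data.frame(population = c("task1", "task2"),
                               mean = c(0.5, 1), sd = c(1.5, 2))
  ens <- train_ensemble(d, 1:12, 13:20, cfg,
                        train_config(batch_size = 8, max_epochs = 2),
                        n_replicates = 2)
  path <- tempfile(fileext = ".json")
  save_ensemble(ens, path)
  ens2 <- load_ensemble(path)
  expect_equal(predict(ens2, d), predict(ens, d), tolerance = 1e-6)
  expect_equal(ens2$tasks, ens$tasks)
})

test_that("multitask training on identical targets matches single-task models", {
  b <- small_sim_bundle()
  d <- b$data
  # a learnable covariate-driven target duplicated into two identical tasks
  y1 <- scale(d$halflife %*% c(0.5, 0.4, 0.6, 0.3, 0.4))[, 1]
  y <- cbind(y1, y1)
  rownames(y) <- d$gene_ids
  colnames(y) <- c("t1", "t2")
  dd <- d; dd$targets <- y; dd$tasks <- colnames(y)
  ds <- d; ds$targets <- y[, 1, drop = FALSE]; ds$tasks <- "t1"
  cfg2 <- benchmark_model_config(b$sim$config, conv_filters = c(48L, 16L))
  cfg2$n_tasks <- 2L
  cfg1 <- cfg2; cfg1$n_tasks <- 1L
  n <- length(d$gene_ids)
  tr <- 1:150; va <- 151:200; te <- 201:n
  tc <- train_config(batch_size = 16)
  mm <- train_model(dd, tr, va, cfg2, tc, seed = 2)
  ms <- train_model(ds, tr, va, cfg1, tc, seed = 2)
  r_multi <- cor(predict(mm, dd)[te, 1], y[te, 1])
  r_single <- cor(predict(ms, ds)[te, 1], y[te, 1])
  expect_lt(abs(r_multi - r_single), 0.15)
  expect_gt(r_multi, 0.5)
})

test_that("feature pathways carry the signal they are supposed to", {
  b <- small_sim_bundle()
  d <- b$data
  cfg <- benchmark_model_config(b$sim$config, conv_filters = c(48L, 16L))
  n <- length(d$gene_ids)
  tr <- 1:150; va <- 151:200; te <- 201:n
  tc <- train_config(batch_size = 16)
  # target driven only by half-life features: shuffling each gene's sequence
  # must not change performance materially
  hl_target <- matrix(d$halflife %*% c(0.5, 0.4, 0.6, 0.3, 0.4),
                      ncol = 1, dimnames = list(d$gene_ids, "t"))
  hl_target <- scale(hl_target)[, , drop = FALSE]
  cfg1 <- cfg; cfg1$n_tasks <- 1L
  dh <- d; dh$targets <- hl_target; dh$tasks <- "t"
  set.seed(77)
  dh_shuf <- dh
  for (i in seq_len(ncol(dh_shuf$codes))) {
    dh_shuf$codes[, i] <- sample(dh_shuf$codes[, i])
  }
  r_full <- cor(predict(train_model(dh, tr, va, cfg1, tc, seed = 3), dh)[te, 1],
                hl_target[te, 1])
  r_shuf <- cor(predict(train_model(dh_shuf, tr, va, cfg1, tc, seed = 3),
                        dh_shuf)[te, 1], hl_target[te, 1])
  expect_gt(r_full, 0.8)
  expect_lt(abs(r_full - r_shuf), 0.1)
})
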