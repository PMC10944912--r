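# The multitask CNN: configuration, datasets, training, ensembling and
# prediction. The numerical core (forward/backward, Adam, plateau LR
# schedule, best-validation checkpointing) lives in src/cnn.cpp and runs in
# single precision; everything here is plumbing and contracts.

#' CNN architecture configuration
#'
#' Two convolutional blocks (convolution -> ReLU -> max-pool), flatten,
#' concatenation with the five half-life features, dropout, and a fully
#' connected head. The multitask head is a single linear output layer
#' (`fc_hidden = integer(0)`); single-task models conventionally insert one
#' hidden layer.
#'
#' @param up_len,down_len Window extent around the TSS; the input length is
#'   their sum.
#' @param n_tasks Number of output tasks (cell populations / tissues).
#' @param conv_filters,conv_widths,pool_widths Integer vectors of length 2:
#'   filter count, kernel width and max-pool width per block. Defaults follow
#'   the promoter-CNN reference design (128 filters of width 6 with pool 30,
#'   then 32 filters of width 9 with pool 10).
#' @param fc_hidden Hidden widths of the head; empty for the multitask model,
#'   one entry (e.g. 64) for single-task variants.
#' @param dropout Dropout rate applied to the concatenated feature vector
#'   before the head.
#' @return A `model_config` list; the fixed channel order (A, C, G, T) is
#'   recorded so serialized models are self-describing.
#' @export
model_config <- function(up_len = 7000L, down_len = 3500L, n_tasks = 1L,
                         conv_filters = c(128L, 32L), conv_widths = c(6L, 9L),
                         pool_widths = c(30L, 10L), fc_hidden = integer(0),
                         dropout = 0.5) {
  cfg <- list(up_len = as.integer(up_len), down_len = as.integer(down_len),
              L = as.integer(up_len + down_len), n_tasks = as.integer(n_tasks),
              conv_filters = as.integer(conv_filters),
              conv_widths = as.integer(conv_widths),
              pool_widths = as.integer(pool_widths),
              fc_hidden = as.integer(fc_hidden),
              dropout = dropout,
              channels = c("A", "C", "G", "T"))
  stopifnot(cfg$n_tasks >= 1, all(cfg$conv_filters > 0),
            all(cfg$conv_widths > 0), all(cfg$pool_widths > 0),
            dropout >= 0, dropout < 1)
  # fail early if the window collapses under the conv/pool stack
  l1 <- cfg$L - cfg$conv_widths[1] + 1
  m1 <- l1 %/% cfg$pool_widths[1]
  l2 <- m1 - cfg$conv_widths[2] + 1
  m2 <- l2 %/% cfg$pool_widths[2]
  if (any(c(l1, m1, l2, m2) < 1)) {
    stop(sprintf("window length %d incompatible with conv/pool widths (flattened size 0)",
                 cfg$L))
  }
  structure(cfg, class = "model_config")
}

#' Training configuration
#'
#' Adam on the mean squared error of standardized targets; the learning rate
#' is divided by `lr_factor` when the validation loss has not improved for
#' `lr_patience` consecutive epochs, and the parameters with the lowest
#' validation loss (earliest epoch on ties) are returned.
#'
#' @param initial_lr Initial learning rate (default 5e-4).
#' @param lr_patience Plateau patience in epochs (default 5).
#' @param lr_factor Reduction factor (default 10).
#' @param max_epochs Training epochs (default 40).
#' @param batch_size Minibatch size (default 128).
#' @return A `train_config` list.
#' @export
train_config <- function(initial_lr = 5e-4, lr_patience = 5L, lr_factor = 10,
                         max_epochs = 40L, batch_size = 128L) {
  cfg <- list(initial_lr = initial_lr, lr_patience = as.integer(lr_patience),
              lr_factor = lr_factor, max_epochs = as.integer(max_epochs),
              batch_size = as.integer(batch_size))
  stopifnot(initial_lr > 0, cfg$lr_patience > 0, lr_factor > 1,
            cfg$max_epochs >= 1, cfg$batch_size >= 1)
  structure(cfg, class = "train_config")
}

#' Bundle encoded inputs and targets into a model dataset
#'
#' @param windows Named character vector of window sequences (one per gene).
#' @param halflife Matrix or data.frame of the five normalized half-life
#'   features, rows aligned with `windows` (a `gene_id` column is honored).
#' @param targets Optional genes x tasks matrix of standardized expression.
#' @param standardizer Optional per-task standardizer (from
#'   [pb_standardize()]), carried along for unstandardized predictions.
#' @return A `model_dataset`: integer-coded sequences (L x N), features,
#'   targets, gene ids and task names.
#' @export
model_dataset <- function(windows, halflife, targets = NULL,
                          standardizer = NULL) {
  codes <- encode_seq_matrix(windows)
  if (is.data.frame(halflife)) {
    if ("gene_id" %in% names(halflife)) {
      stopifnot(all(names(windows) %in% halflife$gene_id))
      halflife <- halflife[match(names(windows), halflife$gene_id), ]
      halflife$gene_id <- NULL
    }
    halflife <- as.matrix(halflife)
  }
  stopifnot(nrow(halflife) == length(windows), ncol(halflife) == 5)
  tasks <- NULL
  if (!is.null(targets)) {
    targets <- as.matrix(targets)
    stopifnot(nrow(targets) == length(windows))
    tasks <- colnames(targets)
  }
  structure(list(codes = codes, halflife = unname(halflife),
                 targets = targets, gene_ids = names(windows),
                 tasks = tasks, standardizer = standardizer),
            class = "model_dataset")
}

#' Build an untrained network
#'
#' Convolutional and hidden layers are drawn with He initialization from a
#' dedicated RNG stream; the linear output layer starts at zero so an
#' untrained network predicts the standardized target mean (`head_sd > 0`
#' draws a random readout instead, useful for null analyses of an untrained
#' network).
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the initialization stream.
#' @param head_sd SD scale of the output layer (default 0 = zero init).
#' @return A `seqexpr_model` (weights + config).
#' @export
build_model <- function(config, seed = 1L, head_sd = 0) {
  stopifnot(inherits(config, "model_config"))
  w <- cpp_init_weights(config, as.integer(seed), head_sd)
  structure(list(weights = w, config = config, history = NULL,
                 seed = as.integer(seed)), class = "seqexpr_model")
}

#' Train one network replicate
#'
#' @param data A [model_dataset()] with targets.
#' @param train_idx,val_idx Disjoint integer indices (1-based) into the
#'   dataset genes.
#' @param config A [model_config()]; `n_tasks` must match the target columns.
#' @param tconfig A [train_config()].
#' @param seed Seed controlling initialization, shuffling and dropout; a
#'   fixed seed makes training bit-reproducible for a fixed thread count.
#' @return A trained `seqexpr_model` with the per-epoch history and the
#'   parameters that achieved the lowest validation loss.
#' @export
train_model <- function(data, train_idx, val_idx, config, tconfig = train_config(),
                        seed = 1L) {
  stopifnot(inherits(data, "model_dataset"), !is.null(data$targets))
  if (length(intersect(train_idx, val_idx)) > 0) {
    stop("train and validation gene sets must be disjoint")
  }
  w0 <- cpp_init_weights(config, as.integer(seed))
  fit <- cpp_train(data$codes, iupac_onehot_table(), data$halflife,
                   data$targets, as.integer(train_idx), as.integer(val_idx),
                   w0, config, tconfig, as.integer(seed))
  structure(list(weights = fit$weights, config = config,
                 history = fit$history, best_epoch = fit$best_epoch,
                 best_val_loss = fit$best_val_loss, seed = as.integer(seed)),
            class = "seqexpr_model")
}

#' Train an ensemble of replicates
#'
#' CNN training is stochastic; an ensemble of `n_replicates` networks
#' (default 5) is trained with consecutive seeds and their predictions are
#' averaged at prediction time.
#'
#' @inheritParams train_model
#' @param n_replicates Number of replicates (default 5).
#' @param base_seed Seed of the first replicate; replicate r uses
#'   `base_seed + r - 1`.
#' @param standardizer Optional per-task standardizer stored with the
#'   ensemble (defaults to the dataset's).
#' @return A `seqexpr_ensemble`.
#' @export
train_ensemble <- function(data, train_idx, val_idx, config,
                           tconfig = train_config(), n_replicates = 5L,
                           base_seed = 1L, standardizer = NULL) {
  seeds <- as.integer(base_seed) + seq_len(n_replicates) - 1L
  models <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    models[[r]] <- tryCatch(
      train_model(data, train_idx, val_idx, config, tconfig, seed = seeds[r]),
      error = function(e) {
        stop(sprintf("ensemble build failed (replicate seeds: %s): %s",
                     paste(seeds, collapse = ", "), conditionMessage(e)))
      })
  }
  if (is.null(standardizer)) standardizer <- data$standardizer
  structure(list(models = models, config = config, tasks = data$tasks,
                 standardizer = standardizer, seeds = seeds),
            class = "seqexpr_ensemble")
}

#' @export
predict.seqexpr_model <- function(object, data, batch_size = 128L, ...) {
  stopifnot(inherits(data, "model_dataset"))
  p <- cpp_forward(data$codes, iupac_onehot_table(), data$halflife,
                   object$weights, object$config, as.integer(batch_size))
  dimnames(p) <- list(data$gene_ids, data$tasks)
  p
}

#' Predict expression with an ensemble
#'
#' Element-wise mean of the replicate predictions; `scale = "log"` maps the
#' standardized outputs back to log10 expression through the stored
#' standardizer.
#'
#' @param object A `seqexpr_ensemble`.
#' @param data A [model_dataset()].
#' @param scale `"standardized"` (network output) or `"log"` (unstandardized
#'   log10 expression).
#' @param batch_size Forward-pass chunk size.
#' @param ... Unused.
#' @return genes x tasks prediction matrix.
#' @export
predict.seqexpr_ensemble <- function(object, data,
                                     scale = c("standardized", "log"),
                                     batch_size = 128L, ...) {
  scale <- match.arg(scale)
  preds <- lapply(object$models, predict, data = data,
                  batch_size = batch_size)
  p <- Reduce(`+`, preds) / length(preds)
  if (scale == "log") {
    if (is.null(object$standardizer)) {
      stop("ensemble has no standardizer; cannot unstandardize predictions")
    }
    p <- pb_unstandardize(p, object$standardizer)
  }
  p
}

#' Save / load an ensemble as a self-describing JSON archive
#'
#' The archive stores weights, configuration, task names, standardizer and
#' channel order, so a checkpoint is portable and reproducibly invertible.
#'
#' @param ensemble A `seqexpr_ensemble`.
#' @param path Output `.json` file.
#' @export
save_ensemble <- function(ensemble, path) {
  pack <- function(w) lapply(w, function(W) list(dim = dim(W),
                                                 data = as.vector(W)))
  obj <- list(config = unclass(ensemble$config), tasks = ensemble$tasks,
              standardizer = ensemble$standardizer, seeds = ensemble$seeds,
              weights = lapply(ensemble$models,
                               function(m) pack(m$weights)))
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' @rdname save_ensemble
#' @param path Path of a saved archive.
#' @export
load_ensemble <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cf <- obj$config
  cfg <- model_config(up_len = cf$up_len, down_len = cf$down_len,
                      n_tasks = cf$n_tasks,
                      conv_filters = as.integer(cf$conv_filters),
                      conv_widths = as.integer(cf$conv_widths),
                      pool_widths = as.integer(cf$pool_widths),
                      fc_hidden = as.integer(unlist(cf$fc_hidden)),
                      dropout = cf$dropout)
  models <- lapply(obj$weights, function(w) {
    weights <- lapply(w, function(x) matrix(x$data, x$dim[1], x$dim[2]))
    structure(list(weights = weights, config = cfg), class = "seqexpr_model")
  })
  std <- obj$standardizer
  if (!is.null(std) && !is.data.frame(std)) std <- as.data.frame(std)
  structure(list(models = models, config = cfg, tasks = unlist(obj$tasks),
                 standardizer = std, seeds = unlist(obj$seeds)),
            class = "seqexpr_ensemble")
}
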