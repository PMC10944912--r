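# In-silico saturation mutagenesis (ISM): substitute every base of the
# promoter window, re-predict with the full ensemble, and report effects on
# the unstandardized log10 scale.
#
# Sign convention (used in all outputs): effect = mutant - wild-type, so a
# positive effect means the substitution is predicted to increase expression.

BASES <- c("A", "C", "G", "T")

#' Saturation mutagenesis of one promoter window
#'
#' Evaluates all three alternative bases at every position with the full
#' ensemble, holding the half-life features fixed, and reports per-task
#' effects on the unstandardized log scale. Positions whose reference base is
#' ambiguous (non-ACGT) have no defined set of three alternatives and are
#' flagged as missing.
#'
#' @param ensemble A `seqexpr_ensemble` with a standardizer.
#' @param window Window sequence (character) matching the model's input
#'   length.
#' @param halflife Numeric vector of the gene's five normalized half-life
#'   features.
#' @param gene_id Optional label stored on the profile.
#' @param chunk_size Number of mutant sequences evaluated per forward pass.
#' @return An `ism_profile`: list with `gene_id`, `ref` (length-L character),
#'   `alts` (L x 3 character, alternatives in A<C<G<T order), `effects`
#'   (L x 3 x tasks array, mutant - wild-type), `wildtype` (per-task
#'   wild-type prediction) and `tasks`.
#' @export
saturation_mutagenesis <- function(ensemble, window, halflife, gene_id = NULL,
                                   chunk_size = 512L) {
  stopifnot(inherits(ensemble, "seqexpr_ensemble"))
  if (is.null(ensemble$standardizer)) {
    stop("ensemble has no standardizer; ISM effects are defined on the log scale")
  }
  codes <- encode_seq(window)
  L <- length(codes)
  if (L != ensemble$config$L) {
    stop(sprintf("window length %d does not match model input %d", L,
                 ensemble$config$L))
  }
  tasks <- ensemble$tasks
  n_tasks <- ensemble$config$n_tasks
  hl <- matrix(as.numeric(halflife), nrow = 1)

  ref <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  unambig <- ref %in% BASES
  alts <- t(vapply(seq_len(L), function(i) {
    if (unambig[i]) setdiff(BASES, ref[i]) else rep(NA_character_, 3)
  }, character(3)))

  # wild-type prediction (log scale)
  wt_data <- structure(list(codes = matrix(codes, ncol = 1),
                            halflife = hl, targets = NULL,
                            gene_ids = gene_id %||% "gene", tasks = tasks,
                            standardizer = ensemble$standardizer),
                       class = "model_dataset")
  wt <- predict(ensemble, wt_data, scale = "log")[1, ]

  pos <- rep(which(unambig), each = 3)
  alt_codes <- match(t(alts[unambig, , drop = FALSE]), BASES)
  n_mut <- length(pos)
  effects <- array(NA_real_, dim = c(L, 3, n_tasks),
                   dimnames = list(NULL, NULL, tasks))
  eff_flat <- matrix(NA_real_, n_mut, n_tasks)
  for (s0 in seq(1, n_mut, by = chunk_size)) {
    s1 <- min(s0 + chunk_size - 1, n_mut)
    idx <- s0:s1
    mut <- matrix(codes, nrow = L, ncol = length(idx))
    mut[cbind(pos[idx], seq_along(idx))] <- alt_codes[idx]
    mdata <- structure(list(codes = mut,
                            halflife = hl[rep(1, length(idx)), , drop = FALSE],
                            targets = NULL, gene_ids = as.character(idx),
                            tasks = tasks,
                            standardizer = ensemble$standardizer),
                       class = "model_dataset")
    p <- predict(ensemble, mdata, scale = "log")
    eff_flat[idx, ] <- sweep(p, 2, wt)
  }
  k <- 0
  for (i in which(unambig)) {
    for (a in 1:3) {
      k <- k + 1
      effects[i, a, ] <- eff_flat[k, ]
    }
  }
  structure(list(gene_id = gene_id, ref = ref, alts = alts, effects = effects,
                 wildtype = wt, tasks = tasks), class = "ism_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-position maximum-effect profile
#'
#' For each position, the signed effect of the substitution with the largest
#' absolute effect for the given task; ties are broken by the fixed
#' alternative order A<C<G<T. Ambiguous positions yield `NA`.
#'
#' @param profile An `ism_profile`.
#' @param task Task name or index.
#' @return Numeric vector of length L.
#' @export
max_effect_profile <- function(profile, task = 1) {
  stopifnot(inherits(profile, "ism_profile"))
  eff <- profile$effects[, , task, drop = FALSE]
  dim(eff) <- dim(profile$effects)[1:2]
  apply(eff, 1, function(e) {
    if (all(is.na(e))) return(NA_real_)
    e[which.max(abs(e))]
  })
}

#' Positional mean of maximum absolute effects over a gene set
#'
#' For each window position i, the average over genes of the maximum
#' absolute predicted effect across the three substitutions:
#' `(1/|G|) * sum_g max_alt |effect_g(i, alt)|`. The gene set (typically the
#' highly variable genes) is an input.
#'
#' @param profiles List of `ism_profile`s sharing the window length.
#' @param task Task name or index.
#' @return Numeric vector of length L.
#' @export
hvg_mean_max_profile <- function(profiles, task = 1) {
  lens <- vapply(profiles, function(p) length(p$ref), 1L)
  if (length(unique(lens)) > 1) stop("profiles have mixed window lengths")
  mats <- vapply(profiles, function(p) abs(max_effect_profile(p, task)),
                 numeric(lens[1]))
  rowMeans(mats)
}

#' Predicted effect of a single variant
#'
#' Maps a genomic variant (1-based position, VCF-style) into the gene's
#' oriented window, verifies the reference allele against the genome
#' (reverse-complemented for '-' genes), and predicts the per-task expression
#' change (alt - ref, unstandardized log scale) for the stated alternative
#' allele, or all three if `alt` is `NA`. When the gene's full ISM profile is
#' supplied, the effect's percentile rank among all |effects| of that
#' gene-task is reported, which is how "top x% strongest mutations"
#' statements are made.
#'
#' @param ensemble A `seqexpr_ensemble`.
#' @param gene One row of a gene table (needs `strand`, `tss`, `chrom`).
#' @param window The gene's oriented window sequence.
#' @param halflife The gene's normalized half-life features.
#' @param pos 1-based genomic variant position.
#' @param ref,alt Alleles on the forward genomic strand; `alt = NA` returns
#'   all three alternatives.
#' @param profile Optional precomputed `ism_profile` for percentile ranks
#'   (also used to read effects without re-predicting).
#' @param up_len Upstream extent of the window (defaults to the model
#'   config's).
#' @return data.frame with one row per (alt, task): `offset` (0-based window
#'   position), `ref_window`, `alt_window` (window-strand alleles), `task`,
#'   `effect`, and `percentile` when a profile was given.
#' @export
variant_effect <- function(ensemble, gene, window, halflife, pos, ref,
                           alt = NA, profile = NULL, up_len = NULL) {
  stopifnot(inherits(ensemble, "seqexpr_ensemble"))
  up_len <- up_len %||% ensemble$config$up_len
  L <- ensemble$config$L
  tss <- if (is.data.frame(gene)) gene$tss[1] else gene$tss
  strand <- if (is.data.frame(gene)) gene$strand[1] else gene$strand
  pos0 <- pos - 1L
  offset <- if (strand == "+") pos0 - (tss - up_len) else (tss + up_len) - pos0
  if (offset < 0 || offset >= L) {
    stop(sprintf("variant at %d falls outside the [%d, %d) window of the gene (offset %d)",
                 pos, -up_len, L - up_len, offset))
  }
  flip <- function(b) vapply(b, function(x) reverse_complement(x), character(1))
  ref_w <- if (strand == "+") toupper(ref) else unname(flip(toupper(ref)))
  wchars <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  if (wchars[offset + 1] != ref_w) {
    stop(sprintf("reference allele mismatch at offset %d: genome has '%s', variant states '%s' (window strand)",
                 offset, wchars[offset + 1], ref_w))
  }
  alts_w <- if (is.na(alt)) setdiff(BASES, ref_w) else {
    if (strand == "+") toupper(alt) else unname(flip(toupper(alt)))
  }

  if (is.null(profile)) {
    # predict just the required mutants
    codes <- encode_seq(window)
    hl <- matrix(as.numeric(halflife), nrow = 1)
    mk_data <- function(m) {
      structure(list(codes = m, halflife = hl[rep(1, ncol(m)), , drop = FALSE],
                     targets = NULL, gene_ids = as.character(seq_len(ncol(m))),
                     tasks = ensemble$tasks,
                     standardizer = ensemble$standardizer),
                class = "model_dataset")
    }
    wt <- predict(ensemble, mk_data(matrix(codes, ncol = 1)), scale = "log")[1, ]
    mut <- matrix(codes, nrow = L, ncol = length(alts_w))
    mut[offset + 1, ] <- match(alts_w, BASES)
    pm <- predict(ensemble, mk_data(mut), scale = "log")
    eff <- sweep(pm, 2, wt)
  } else {
    stopifnot(inherits(profile, "ism_profile"))
    ai <- match(alts_w, profile$alts[offset + 1, ])
    eff <- matrix(profile$effects[offset + 1, ai, ],
                  nrow = length(alts_w),
                  ncol = length(ensemble$tasks %||% seq_len(ensemble$config$n_tasks)))
  }
  tasks <- ensemble$tasks %||% as.character(seq_len(ncol(eff)))
  out <- expand.grid(alt_window = alts_w, task = tasks,
                     stringsAsFactors = FALSE)
  out$offset <- offset
  out$ref_window <- ref_w
  out$effect <- as.vector(eff)
  if (!is.null(profile)) {
    out$percentile <- mapply(function(a, tk) {
      all_eff <- abs(as.vector(profile$effects[, , tk]))
      e <- abs(profile$effects[offset + 1, match(a, profile$alts[offset + 1, ]), tk])
      mean(all_eff[!is.na(all_eff)] <= e) * 100
    }, out$alt_window, out$task)
  }
  out[, c("offset", "ref_window", "alt_window", "task", "effect",
          if (!is.null(profile)) "percentile")]
}

#' Write an ISM profile as TSV
#'
#' One row per (position, alternative): `position` (0-based), `ref`, `alt`,
#' and one effect column per task.
#'
#' @param profile An `ism_profile`.
#' @param path Output path.
#' @export
write_ism_profile <- function(profile, path) {
  L <- length(profile$ref)
  df <- data.frame(position = rep(seq_len(L) - 1L, each = 3),
                   ref = rep(profile$ref, each = 3),
                   alt = as.vector(t(profile$alts)))
  for (tk in seq_along(profile$tasks %||% seq_len(dim(profile$effects)[3]))) {
    eff <- profile$effects[, , tk]
    nm <- (profile$tasks %||% paste0("task", seq_len(dim(profile$effects)[3])))[tk]
    df[[nm]] <- as.vector(t(eff))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
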