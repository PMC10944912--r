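# One-hot encoding of IUPAC nucleotide strings.
#
# Channel order is fixed to (A, C, G, T) and serialized with every model so
# that checkpoints are portable. Ambiguous IUPAC codes receive fractional
# mass spread uniformly over their compatible bases, so every column sums
# to one.

IUPAC_LETTERS <- c("A", "C", "G", "T", "R", "Y", "S", "W",
                   "K", "M", "B", "D", "H", "V", "N")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Fractional one-hot code table for IUPAC nucleotide letters
#'
#' @return A 4 x 15 numeric matrix; rows are the channels (A, C, G, T),
#'   columns the IUPAC letters. Each column sums to 1; ambiguous letters put
#'   uniform mass on their compatible bases (e.g. N -> 0.25 on all four).
#' @export
iupac_onehot_table <- function() {
  tab <- matrix(0, 4, length(IUPAC_LETTERS),
                dimnames = list(c("A", "C", "G", "T"), IUPAC_LETTERS))
  for (l in IUPAC_LETTERS) {
    bases <- IUPAC_SETS[[l]]
    tab[bases, l] <- 1 / length(bases)
  }
  tab
}

#' Integer-encode a nucleotide string
#'
#' Maps each character to its index in the fixed IUPAC alphabet (A=1 ... N=15),
#' case-insensitively. This is the storage format consumed by the CNN backend,
#' which expands codes to fractional one-hot columns on the fly.
#'
#' @param seq A single nucleotide string.
#' @return Integer vector of codes, one per position.
#' @export
encode_seq <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  codes <- match(chars, IUPAC_LETTERS)
  if (anyNA(codes)) {
    bad <- which(is.na(codes))[1]
    stop(sprintf("non-IUPAC character '%s' at position %d", chars[bad], bad))
  }
  codes
}

#' One-hot encode a nucleotide sequence
#'
#' @param seq A nucleotide string over the IUPAC alphabet (case-insensitive).
#' @return A 4 x L numeric matrix with rownames (A, C, G, T). Columns for
#'   unambiguous bases contain a single 1; ambiguous codes get uniform
#'   fractional mass; every column sums to 1.
#' @examples
#' one_hot("ACGT")
#' one_hot("NRY")
#' @export
one_hot <- function(seq) {
  codes <- encode_seq(seq)
  tab <- iupac_onehot_table()
  m <- tab[, codes, drop = FALSE]
  colnames(m) <- NULL
  m
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' @param seq A nucleotide string.
#' @return The reverse complement, uppercase.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

# Integer-encode many window strings into an L x N matrix (one column per gene).
encode_seq_matrix <- function(seqs) {
  codes <- lapply(seqs, encode_seq)
  lens <- lengths(codes)
  if (length(unique(lens)) > 1) stop("window sequences have mixed lengths")
  m <- matrix(unlist(codes, use.names = FALSE), nrow = lens[1])
  colnames(m) <- names(seqs)
  m
}
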