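# --- sequence encoders -------------------------------------------------------
#
# Each encoder maps one padded sequence (length `target_len`, pad character
# 'B' as a contiguous suffix) to a fixed-shape numeric matrix whose rows are
# convolved over by the base classifiers:
#   onehot   : target_len x 20   positional residue indicators, 'B' -> 0.05
#   aaindex  : target_len x 14   physicochemical property profiles
#   ggap     : 440 x 10          g-gap dipeptide counts, one-hot by count
#   word2vec : target_len x d    skip-gram residue embeddings

check_padded <- function(padded) {
  if (length(padded) != 1L || !is.character(padded)) {
    abort("expected a single padded sequence string")
  }
  chars <- strsplit(padded, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% PAD_ALPHABET)) {
    abort("padded sequence contains characters outside the 21-letter alphabet")
  }
  b <- chars == PAD_CHAR
  if (any(b) && any(diff(which(b)) != 1L) ||
      (any(b) && max(which(b)) != length(chars))) {
    abort("pad characters 'B' must form a contiguous suffix")
  }
  chars
}

as_encoded <- function(m, encoder_id) {
  attr(m, "encoder_id") <- encoder_id
  m
}

#' One-hot encode a padded peptide sequence
#'
#' Each natural residue becomes the standard basis vector of its position in
#' the alphabetical residue order; every pad character `B` becomes the
#' constant vector 0.05, the uniform average residue frequency (20 x 0.05
#' sums to 1), so padding carries no positional preference.
#'
#' @param padded A padded sequence (see [pad_sequence()]).
#' @return A `nchar(padded)` x 20 numeric matrix with attribute
#'   `encoder_id = "onehot"`.
#' @export
#' @examples
#' m <- encode_onehot(pad_sequence("ACD"))
#' dim(m)
encode_onehot <- function(padded) {
  chars <- check_padded(padded)
  L <- length(chars)
  m <- matrix(0, L, 20L, dimnames = list(NULL, AA_ALPHABET))
  idx <- match(chars, AA_ALPHABET)
  nat <- !is.na(idx)
  m[cbind(which(nat), idx[nat])] <- 1
  m[!nat, ] <- 0.05
  stopifnot(ncol(m) == 20L)
  as_encoded(m, "onehot")
}

#' Encode a padded peptide with AAIndex physicochemical properties
#'
#' Row i holds the 14 property values of residue i. Pad positions get the
#' per-property mean over the 20 natural residues, the same
#' uniform-frequency convention the one-hot pad vector uses.
#'
#' @param padded A padded sequence.
#' @param table A 20 x p property matrix (default the bundled
#'   [aaindex_table()]).
#' @param scale Standardise each property to zero mean and unit variance
#'   over the 20 residues (default `TRUE`): the raw indices span three
#'   orders of magnitude, which would otherwise let a few bulky properties
#'   dominate the convolution inputs.
#' @return A `nchar(padded)` x `ncol(table)` matrix, `encoder_id = "aaindex"`.
#' @export
encode_aaindex <- function(padded, table = aaindex_table(), scale = TRUE) {
  chars <- check_padded(padded)
  if (!all(AA_ALPHABET %in% rownames(table)) || any(!is.finite(table))) {
    abort("AAIndex table must cover all 20 residues with finite values")
  }
  table <- table[AA_ALPHABET, , drop = FALSE]
  if (scale) {
    mu <- colMeans(table)
    sd_ <- apply(table, 2L, stats::sd)
    sd_[sd_ == 0] <- 1
    table <- sweep(sweep(table, 2L, mu), 2L, sd_, `/`)
  }
  ext <- rbind(table, colMeans(table))
  rownames(ext) <- PAD_ALPHABET
  m <- ext[match(chars, PAD_ALPHABET), , drop = FALSE]
  rownames(m) <- NULL
  as_encoded(m, "aaindex")
}

# 440 ordered dipeptide bin names: 21 x 21 pairs minus (B,B), first residue
# varying slowest
ggap_bins <- function() {
  bins <- as.vector(t(outer(PAD_ALPHABET, PAD_ALPHABET, paste0)))
  bins[bins != paste0(PAD_CHAR, PAD_CHAR)]
}

#' Count g-gap dipeptides in a padded sequence
#'
#' Tallies ordered residue pairs `(s[i], s[i+g+1])` over all positions of the
#' padded sequence. Pairs range over the 21 x 21 ordered-pair space minus the
#' pure-pad pair `BB` (441 - 1 = 440 bins); `BB` occurrences are discarded.
#' `g = 0` counts adjacent dipeptides.
#'
#' @param padded A padded sequence.
#' @param g Gap size (number of residues between the pair), `>= 0`.
#' @return A named integer vector of length 440.
#' @export
count_ggap_pairs <- function(padded, g = 0L) {
  chars <- check_padded(padded)
  L <- length(chars)
  stopifnot(g >= 0L, L - g - 1L >= 1L)
  a <- chars[seq_len(L - g - 1L)]
  b <- chars[seq_len(L - g - 1L) + g + 1L]
  pairs <- paste0(a, b)
  bins <- ggap_bins()
  counts <- tabulate(match(pairs, bins), nbins = 440L)
  names(counts) <- bins
  counts
}

#' G-gap dipeptide one-hot count matrix
#'
#' Turns the 440 g-gap dipeptide counts into a 440 x `count_cap` binary
#' matrix: the row for a pair seen c times has column c set (1 <= c <=
#' `count_cap`), the all-zero row encodes c = 0, and counts above the cap are
#' clipped to the cap. The default cap of 10 is the largest pair count
#' observed in typical 5-100 residue peptide sets.
#'
#' @param padded A padded sequence.
#' @param g Gap size.
#' @param count_cap Number of count columns (default 10).
#' @return A 440 x `count_cap` binary matrix, `encoder_id = "ggap"`.
#' @export
encode_ggap <- function(padded, g = 0L, count_cap = 10L) {
  stopifnot(count_cap >= 1L)
  counts <- count_ggap_pairs(padded, g)
  m <- matrix(0, 440L, count_cap, dimnames = list(names(counts), NULL))
  c_clip <- pmin(counts, count_cap)
  nz <- which(c_clip > 0L)
  m[cbind(nz, c_clip[nz])] <- 1
  stopifnot(nrow(m) == 440L)
  as_encoded(m, "ggap")
}

#' Embed a padded peptide with a trained residue embedding
#'
#' Row i is the embedding vector of residue i from `table` (see
#' [train_word2vec()]).
#'
#' @param padded A padded sequence.
#' @param table An `embedding_table`.
#' @return A `nchar(padded)` x d matrix, `encoder_id = "word2vec"`.
#' @export
encode_word2vec <- function(padded, table) {
  chars <- check_padded(padded)
  if (!inherits(table, "embedding_table")) {
    abort("`table` must be an embedding_table from train_word2vec()")
  }
  idx <- match(chars, rownames(table$vectors))
  if (anyNA(idx)) abort("token missing from embedding table")
  m <- table$vectors[idx, , drop = FALSE]
  rownames(m) <- NULL
  as_encoded(m, "word2vec")
}

# encode every record with one encoder; returns a list of matrices in record
# order. `...` forwards encoder-specific arguments (table, g, count_cap).
encode_peptides <- function(records, encoder, target_len = 100L, ...) {
  validate_peptides(records)
  encoder <- match.arg(encoder, ENCODER_IDS)
  padded <- pad_sequence(records$sequence, target_len)
  fn <- switch(encoder,
    onehot   = encode_onehot,
    aaindex  = encode_aaindex,
    ggap     = encode_ggap,
    word2vec = encode_word2vec
  )
  lapply(padded, fn, ...)
}
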