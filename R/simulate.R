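# --- synthetic benchmark generator ------------------------------------------
#
# Stands in for the curated neuropeptide/non-neuropeptide benchmark:
# balanced two-class sets of variable-length peptides (5-100 aa) over a
# background residue-frequency model, where positives carry a plantable
# sequence motif of controllable strength. The motif is overwritten onto the
# sequence (never inserted) so lengths are untouched.

#' Swiss-Prot-like background residue frequencies
#'
#' Average amino-acid composition of UniProtKB/Swiss-Prot (release-note
#' statistics, rounded), for use as a more protein-like background than the
#' uniform default.
#'
#' @return Named numeric vector over the 20 residues, summing to 1.
#' @export
swissprot_freqs <- function() {
  f <- c(A = 8.25, C = 1.38, D = 5.46, E = 6.71, F = 3.86, G = 7.07,
         H = 2.27, I = 5.91, K = 5.80, L = 9.65, M = 2.41, N = 4.06,
         P = 4.74, Q = 3.93, R = 5.53, S = 6.63, T = 5.35, V = 6.86,
         W = 1.10, Y = 2.92)
  f / sum(f)
}

#' Generate a labelled synthetic peptide benchmark
#'
#' Samples `n_pos + n_neg` peptides with lengths uniform over
#' `length_range`. Negatives are i.i.d. draws from `background_freqs`;
#' positives are drawn the same way and then, with probability
#' `motif_rate`, have `motif` overwritten at a uniformly chosen valid
#' position. Deterministic per seed; ids encode class and index
#' (`pos_1`, ..., `neg_1`, ...).
#'
#' @param n_pos,n_neg Class sizes.
#' @param length_range Inclusive length bounds, default `c(5, 100)`.
#' @param motif Residue string planted in positives (default a fixed 5-mer).
#' @param motif_rate Probability a positive carries the motif (default 1).
#' @param background_freqs 20 residue probabilities summing to 1; default
#'   uniform (1/20 each).
#' @param seed Integer seed.
#' @return A labelled peptide tibble (`id`, `sequence`, `label`).
#' @export
#' @examples
#' simulate_peptides(n_pos = 3, n_neg = 3, seed = 42)
simulate_peptides <- function(n_pos, n_neg, length_range = c(5L, 100L),
                              motif = "WKRFC", motif_rate = 1,
                              background_freqs = NULL, seed) {
  stopifnot(n_pos >= 1L, n_neg >= 1L,
            length_range[1L] >= 1L, length_range[2L] >= length_range[1L],
            motif_rate >= 0, motif_rate <= 1)
  if (nchar(motif) > length_range[1L]) {
    abort("motif longer than the minimum peptide length")
  }
  if (!all(strsplit(motif, "")[[1L]] %in% AA_ALPHABET)) {
    abort("motif contains characters outside the 20 natural residues")
  }
  if (is.null(background_freqs)) {
    background_freqs <- rep(1 / 20, 20L)
    names(background_freqs) <- AA_ALPHABET
  }
  if (abs(sum(background_freqs) - 1) > 1e-9 || length(background_freqs) != 20L) {
    abort("background_freqs must be 20 probabilities summing to 1")
  }
  mchars <- strsplit(motif, "")[[1L]]
  mlen <- length(mchars)
  with_seed(seed, {
    draw <- function(n, planted) {
      lens <- sample(seq(length_range[1L], length_range[2L]), n,
                     replace = TRUE)
      vapply(lens, function(L) {
        s <- sample(AA_ALPHABET, L, replace = TRUE, prob = background_freqs)
        if (planted && runif(1) < motif_rate) {
          pos <- sample.int(L - mlen + 1L, 1L)
          s[pos:(pos + mlen - 1L)] <- mchars
        }
        paste(s, collapse = "")
      }, "")
    }
    tibble(
      id = c(paste0("pos_", seq_len(n_pos)), paste0("neg_", seq_len(n_neg))),
      sequence = c(draw(n_pos, TRUE), draw(n_neg, FALSE)),
      label = rep(c(1L, 0L), c(n_pos, n_neg))
    )
  })
}

#' Generate synthetic 4-column meta-features
#'
#' Direct fixture for the meta-learner and attribution layers: balanced
#' class-conditional 4-D Gaussians clipped to `[0, 1]`, with class means
#' `0.5 -/+ separation/2` on the informative columns and 0.5 on the rest
#' (sd 0.15 per column). `n` odd gives class sizes differing by one.
#'
#' @param n Total samples.
#' @param separation Distance between the class means on informative columns.
#' @param seed Integer seed.
#' @param informative Which of the four columns carry signal (default all).
#' @param sd Per-column standard deviation.
#' @return List with `X` (n x 4 matrix, columns `p_onehot` ...
#'   `p_word2vec`) and `y` (0/1 labels).
#' @export
simulate_meta_features <- function(n, separation, seed, informative = 1:4,
                                   sd = 0.15) {
  stopifnot(n >= 2L, separation >= 0)
  n1 <- n %/% 2L
  n0 <- n - n1
  y <- rep(c(0L, 1L), c(n0, n1))
  mu <- matrix(0.5, 2L, 4L)
  mu[1L, informative] <- 0.5 - separation / 2
  mu[2L, informative] <- 0.5 + separation / 2
  X <- with_seed(seed, {
    m <- matrix(rnorm(n * 4L, sd = sd), n, 4L)
    m + mu[y + 1L, ]
  })
  X <- pmin(pmax(X, 0), 1)
  colnames(X) <- META_FEATURES
  list(X = X, y = y)
}
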