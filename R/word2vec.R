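# --- residue embeddings (skip-gram) -----------------------------------------

# center/context co-occurrence counts over a symmetric window; rows = center
# token, cols = context token, both indexed over PAD_ALPHABET
cooccurrence_counts <- function(corpus, window) {
  K <- length(PAD_ALPHABET)
  counts <- matrix(0, K, K, dimnames = list(PAD_ALPHABET, PAD_ALPHABET))
  for (seqs in corpus) {
    idx <- match(strsplit(seqs, "", fixed = TRUE)[[1L]], PAD_ALPHABET)
    L <- length(idx)
    for (o in seq_len(min(window, L - 1L))) {
      a <- idx[seq_len(L - o)]
      b <- idx[seq_len(L - o) + o]
      # both directions: (center a, context b) and (center b, context a)
      tb <- tabulate((a - 1L) * K + b, nbins = K * K) +
            tabulate((b - 1L) * K + a, nbins = K * K)
      counts <- counts + matrix(tb, K, K, byrow = TRUE)
    }
  }
  counts
}

#' Train skip-gram residue embeddings
#'
#' Learns a d-dimensional vector per residue token (20 natural residues plus
#' the pad character `B`) with the word2vec skip-gram objective: each center
#' token predicts the tokens inside a symmetric window, scored with a full
#' softmax over the 21-token vocabulary. Because the vocabulary is tiny, the
#' exact full-corpus gradient depends only on the center/context
#' co-occurrence counts, so training is deterministic full-batch Adam on the
#' aggregated counts — no negative sampling, no stochastic updates.
#'
#' Tokens never seen in the corpus receive the zero vector. Train the table
#' on the training split only, so embeddings never see held-out peptides.
#'
#' @param corpus Character vector of (padded or unpadded) sequences.
#' @param d Embedding dimension (default 32).
#' @param window Symmetric context window in residues (default 5).
#' @param epochs Optimiser iterations over the aggregated counts (default 100).
#' @param seed Integer seed for the weight initialisation.
#' @param learning_rate Adam step size.
#' @param algorithm `"skipgram"` (default) or `"cbow"`. The CBOW switch is
#'   provided for experimentation only; it trains the reversed
#'   (context-predicts-center) objective and carries no performance claims.
#' @return An `embedding_table`: list with `vectors` (21 x d matrix, rows
#'   named by token) and `params`.
#' @export
#' @examples
#' tab <- train_word2vec(c("ACDEFGHIK", "KLMNPQRST"), d = 4, epochs = 20, seed = 1)
#' dim(tab$vectors)
train_word2vec <- function(corpus, d = 32L, window = 5L, epochs = 100L, seed,
                           learning_rate = 0.05, algorithm = c("skipgram", "cbow")) {
  algorithm <- match.arg(algorithm)
  if (length(corpus) == 0L) abort("corpus is empty")
  stopifnot(d >= 1L, window >= 1L, epochs >= 1L)
  C <- cooccurrence_counts(corpus, window)
  if (algorithm == "cbow") C <- t(C)
  K <- nrow(C)
  N <- rowSums(C)
  V <- with_seed(seed, matrix(rnorm(K * d, sd = 0.1), K, d))
  U <- with_seed(seed + 1L, matrix(rnorm(K * d, sd = 0.1), K, d))
  opt_v <- adam_state(dim(V)); opt_u <- adam_state(dim(U))
  active <- N > 0
  for (it in seq_len(epochs)) {
    S <- V %*% t(U)
    S <- S - apply(S, 1L, max)            # row-wise stabilisation
    P <- exp(S); P <- P / rowSums(P)
    R <- N * P - C                        # d(loss)/d(scores)
    dV <- R %*% U
    dU <- crossprod(R, V)
    upd <- adam_update(opt_v, dV, learning_rate, it); opt_v <- upd$state
    V <- V - upd$step
    upd <- adam_update(opt_u, dU, learning_rate, it); opt_u <- upd$state
    U <- U - upd$step
  }
  seen <- active | colSums(C) > 0
  V[!seen, ] <- 0
  rownames(V) <- PAD_ALPHABET
  structure(
    list(vectors = V,
         params = list(d = as.integer(d), window = as.integer(window),
                       epochs = as.integer(epochs), seed = as.integer(seed),
                       algorithm = algorithm)),
    class = "embedding_table"
  )
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table>", nrow(x$vectors), "tokens x", ncol(x$vectors),
      "dims (", x$params$algorithm, ", window", x$params$window, ")\n")
  invisible(x)
}

#' Write an embedding table as TSV
#'
#' @param table An `embedding_table`.
#' @param path Output path; columns are `token`, `v1` ... `vd`.
#' @return `path`, invisibly.
#' @export
write_embedding_tsv <- function(table, path) {
  df <- data.frame(token = rownames(table$vectors), table$vectors)
  names(df) <- c("token", paste0("v", seq_len(ncol(table$vectors))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
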