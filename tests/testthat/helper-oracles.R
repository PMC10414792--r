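# Independent oracles and small fixture builders shared across tests.

# all-pairs Mann-Whitney AUC with ties counted one half
brute_force_auc <- function(y, scores) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# direct subset-enumeration Shapley value, written independently of
# exact_shapley(): coalitions via combn, value function evaluated row by row
brute_force_shapley <- function(f, x, background) {
  p <- length(x)
  m <- nrow(background)
  vfun <- function(S) {
    tot <- 0
    for (r in seq_len(m)) {
      z <- background[r, ]
      z[S] <- x[S]
      tot <- tot + f(matrix(z, 1L))
    }
    tot / m
  }
  vapply(seq_len(p), function(j) {
    others <- setdiff(seq_len(p), j)
    phi <- 0
    for (s in 0:length(others)) {
      subsets <- if (s == 0) list(integer(0)) else
        asplit(utils::combn(others, s), 2L)
      for (S in subsets) {
        S <- as.integer(S)
        w <- factorial(s) * factorial(p - s - 1) / factorial(p)
        phi <- phi + w * (vfun(c(S, j)) - vfun(S))
      }
    }
    phi
  }, 0)
}

# direct (non-log) Gaussian naive Bayes posterior from the density formula
brute_force_gnb_posterior <- function(fit, x) {
  dens <- function(cl) {
    fit$priors[cl] *
      prod(stats::dnorm(x, fit$means[cl, ], sqrt(fit$variances[cl, ])))
  }
  d1 <- dens("1"); d0 <- dens("0")
  d1 / (d0 + d1)
}

# deterministic labelled records without simulation machinery
toy_records <- function(seqs, labels = NULL) {
  tibble::tibble(
    id = paste0("r", seq_along(seqs)),
    sequence = seqs,
    label = if (is.null(labels)) NA_integer_ else as.integer(labels)
  )
}

# fast CNN settings for unit tests (study-scale settings live in the
# acceptance tests)
quick_configs <- function(epochs = 3L, seed = 1L) {
  default_base_configs(epochs = epochs, seed = seed)
}
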