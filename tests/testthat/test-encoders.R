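test_that("one-hot rows are basis vectors and pad rows are uniform 0.05", {
  padded <- pad_sequence("ACDW")
  m <- encode_onehot(padded)
  expect_equal(dim(m), c(100L, 20L))
  expect_equal(attr(m, "encoder_id"), "onehot")
  expect_equal(m[1, ], stats::setNames(as.numeric(AA_ALPHABET == "A"),
                                       AA_ALPHABET))
  expect_equal(unname(m[4, "W"]), 1)
  expect_equal(sum(m[4, ]), 1)
  expect_equal(unname(m[5, ]), rep(0.05, 20))
  expect_equal(unname(m[100, ]), rep(0.05, 20))
  expect_equal(unname(rowSums(m)), rep(1, 100))
})

test_that("one-hot inverts back to the original sequence", {
  seqs <- c("MKTAYIAKQR", "WWWWW", paste(AA_ALPHABET, collapse = ""))
  for (s in seqs) {
    m <- encode_onehot(pad_sequence(s))
    nat <- seq_len(nchar(s))
    decoded <- paste(AA_ALPHABET[max.col(m[nat, , drop = FALSE])],
                     collapse = "")
    expect_equal(decoded, s)
  }
})

test_that("padded-input validation rejects interior pads and bad characters", {
  expect_error(encode_onehot("ABCDE"), "suffix")
  expect_error(encode_onehot("ACXDE"), "alphabet")
  expect_error(encode_onehot(c("ACD", "ACD")), "single")
})

test_that("AAIndex encoding looks up per-residue property rows", {
  tab <- aaindex_table()
  expect_equal(dim(tab), c(20L, 14L))
  m_raw <- encode_aaindex(pad_sequence("AR"), scale = FALSE)
  expect_equal(dim(m_raw), c(100L, 14L))
  expect_equal(unname(m_raw[1, ]), unname(tab["A", ]))
  expect_equal(unname(m_raw[2, ]), unname(tab["R", ]))
  expect_equal(unname(m_raw[3, ]), unname(colMeans(tab)))
  expect_equal(attr(m_raw, "encoder_id"), "aaindex")
})

test_that("AAIndex standardisation yields zero-mean unit-variance properties", {
  allaa <- paste(AA_ALPHABET, collapse = "")
  m <- encode_aaindex(pad_sequence(allaa))
  resid <- m[1:20, ]
  expect_equal(unname(colMeans(resid)), rep(0, 14), tolerance = 1e-12)
  expect_equal(unname(apply(resid, 2, stats::sd)), rep(1, 14),
               tolerance = 1e-12)
  # pad rows carry the (scaled) property means, i.e. zero
  expect_equal(unname(m[21, ]), rep(0, 14), tolerance = 1e-12)
})

test_that("the dipeptide bin set is the 441 ordered pairs minus pure pad", {
  bins <- pepstack:::ggap_bins()
  expect_length(bins, 440L)
  expect_false("BB" %in% bins)
  expect_true(all(c("AA", "YY", "AB", "BA") %in% bins))
  expect_equal(anyDuplicated(bins), 0L)
  full <- as.vector(t(outer(PAD_ALPHABET, PAD_ALPHABET, paste0)))
  expect_setequal(c(bins, "BB"), full)
})

test_that("adjacent dipeptide counts match a hand count", {
  padded <- pad_sequence("AACA", target_len = 6L)  # AACABB
  cts <- count_ggap_pairs(padded, g = 0L)
  expect_equal(sum(cts), 4L)  # 5 windows, one is BB and discarded
  expect_equal(unname(cts["AA"]), 1L)
  expect_equal(unname(cts["AC"]), 1L)
  expect_equal(unname(cts["CA"]), 1L)
  expect_equal(unname(cts["AB"]), 1L)
})

test_that("gap size g skips g residues between the paired positions", {
  padded <- pad_sequence("ACDEF", target_len = 5L)
  c1 <- count_ggap_pairs(padded, g = 1L)
  expect_equal(sum(c1), 3L)
  expect_equal(unname(c1[c("AD", "CE", "DF")]), c(1L, 1L, 1L))
  c3 <- count_ggap_pairs(padded, g = 3L)
  expect_equal(sum(c3), 1L)
  expect_equal(unname(c3["AF"]), 1L)
})

test_that("g-gap one-hot count matrix encodes count magnitude with clipping", {
  padded <- pad_sequence(strrep("A", 13), target_len = 20L)
  m <- encode_ggap(padded, g = 0L, count_cap = 10L)
  expect_equal(dim(m), c(440L, 10L))
  expect_equal(attr(m, "encoder_id"), "ggap")
  # AA occurs 12 times -> clipped into column 10
  expect_equal(unname(m["AA", ]), c(rep(0, 9), 1))
  # AB occurs once
  expect_equal(unname(m["AB", ]), c(1, rep(0, 9)))
  # BB windows are discarded entirely, BA never occurs
  expect_equal(unname(m["BA", ]), rep(0, 10))
  expect_true(all(rowSums(m) <= 1))
  expect_equal(sum(m), 2)  # only AA and AB bins are occupied
})

test_that("word2vec encoding maps each position to its token vector", {
  emb <- train_word2vec(c("ACDEF", "CADFE"), d = 4L, epochs = 5L, seed = 7L)
  m <- encode_word2vec(pad_sequence("CA", target_len = 4L), emb)
  expect_equal(dim(m), c(4L, 4L))
  expect_equal(attr(m, "encoder_id"), "word2vec")
  expect_equal(unname(m[1, ]), unname(emb$vectors["C", ]))
  expect_equal(unname(m[2, ]), unname(emb$vectors["A", ]))
  expect_equal(unname(m[3, ]), unname(emb$vectors["B", ]))
  expect_equal(unname(m[4, ]), unname(m[3, ]))
  expect_error(encode_word2vec(pad_sequence("CA"), table = list()),
               "embedding_table")
})
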