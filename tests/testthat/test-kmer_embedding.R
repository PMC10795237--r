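# kmer_embedding: tokenization, vocabulary, CBOW training, embedding.

test_that("tokenize follows the sliding-window rule", {
  expect_length(tokenize(random_window(1)), 39L)
  expect_identical(tokenize("GAU"), "GAU")
  expect_identical(tokenize("GAUUA"), c("GAU", "AUU", "UUA"))
  expect_error(tokenize("GA"), "shorter than k")
  ## property: count == L - k + 1 over random lengths
  withr::with_seed(4, {
    for (L in sample(3:80, 20)) {
      s <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                 collapse = "")
      expect_length(tokenize(s), L - 2L)
    }
  })
})

test_that("vocabulary indices are 0-based, gap-free and lexicographic", {
  v <- build_vocab(list(c("GAU", "AUU", "GAU", "UUA")))
  expect_identical(names(v$kmer_to_index), c("AUU", "GAU", "UUA"))
  expect_identical(unname(v$kmer_to_index), 0:2)
  expect_identical(unname(build_vocab(list("GAU"))$kmer_to_index), 0L)
  expect_error(build_vocab(list()), "empty")
  ## injective, consecutive
  big <- build_vocab(lapply(1:20, function(i) tokenize(random_window(i))))
  idx <- big$kmer_to_index
  expect_identical(sort(unname(idx)), seq_along(idx) - 1L)
})

test_that("unpadded corpora close at 64 types, padded windows at 105", {
  bases <- c("A", "C", "G", "U")
  fill <- function(n) substr(strrep("ACGU", ceiling(n / 4) + 1), 1, n)
  triples <- apply(expand.grid(bases, bases, bases,
                               stringsAsFactors = FALSE),
                   1, paste, collapse = "")
  ## 64: one unpadded window per triple
  pure <- lapply(triples, function(t) tokenize(paste0(t, fill(38))))
  expect_length(build_vocab(pure)$kmer_to_index, 64L)
  ## 105: add head- and tail-padded windows realizing every dash type
  pad_windows <- c(
    as.vector(outer(bases, bases,
                    function(x, y) paste0("-", x, y, fill(38)))),
    paste0("--", bases, fill(38)),
    paste0("---", fill(38)),
    as.vector(outer(bases, bases,
                    function(x, y) paste0(fill(38), y, x, "-"))),
    paste0(fill(38), bases, "--"),
    paste0(fill(38), "---"))
  corpus <- c(pure, lapply(pad_windows, tokenize))
  vocab <- build_vocab(corpus)
  expect_length(vocab$kmer_to_index, 105L)
  ## and the realized types are exactly the analytic enumeration
  expect_identical(names(vocab$kmer_to_index), oracle_padded_kmer_types())
  expect_length(oracle_padded_kmer_types(), 105L)
})

test_that("CBOW training is deterministic and shapes are honoured", {
  corpus <- lapply(1:15, function(i) tokenize(random_window(i)))
  cb1 <- train_cbow(corpus, d_embed = 12L, epochs = 3L, seed = 7L)
  cb2 <- train_cbow(corpus, d_embed = 12L, epochs = 3L, seed = 7L)
  expect_identical(cb1$table$vectors, cb2$table$vectors)
  cb3 <- train_cbow(corpus, d_embed = 12L, epochs = 3L, seed = 8L)
  expect_false(identical(cb1$table$vectors, cb3$table$vectors))
  expect_equal(ncol(cb1$table$vectors), 12L)
  expect_equal(nrow(cb1$table$vectors), length(cb1$vocab$kmer_to_index))
  expect_true(all(is.finite(cb1$table$vectors)))
  expect_error(train_cbow(corpus, d_embed = 0L), "d_embed")
  expect_error(train_cbow(list()), "empty")
})

test_that("tokens sharing contexts end up with similar vectors", {
  ## templates in which AAA and CCC appear in identical contexts
  others <- c("GGG", "UUU", "AGA", "CUC", "GUG", "UAU", "GCG", "CGC")
  corpus <- list()
  withr::with_seed(11, {
    for (r in 1:60) {
      ctx <- sample(others, 4, replace = TRUE)
      for (w in c("AAA", "CCC"))
        corpus[[length(corpus) + 1L]] <- c(ctx[1:2], w, ctx[3:4])
    }
  })
  cb <- train_cbow(corpus, d_embed = 16L, window = 2L, epochs = 40L,
                   seed = 3L)
  vec <- cb$table$vectors
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  target <- cosine(vec["AAA", ], vec["CCC", ])
  pairs <- utils::combn(others, 2)
  ref <- apply(pairs, 2, function(p) cosine(vec[p[1], ], vec[p[2], ]))
  expect_gt(target, stats::median(ref))
})

test_that("embedding produces one table row per token", {
  corpus <- lapply(1:10, function(i) tokenize(random_window(i)))
  cb <- train_cbow(corpus, d_embed = 10L, epochs = 2L, seed = 1L)
  M <- embed_tokens(tokenize(random_window(1)), cb$table)
  expect_identical(dim(M), c(39L, 10L))
  M21 <- embed_tokens(tokenize(substr(random_window(2), 1, 21)), cb$table)
  expect_identical(nrow(M21), 19L)
  tok <- rownames(cb$table$vectors)[[5]]
  expect_identical(drop(embed_tokens(tok, cb$table)),
                   cb$table$vectors[5, ])
  expect_error(embed_tokens("---", cb$table), "---")
  Z <- embed_tokens(c(tok, "---"), cb$table, oov = "zero")
  expect_identical(Z[2, ], rep(0, 10L))
})

test_that("word2vec text persistence round-trips", {
  corpus <- lapply(1:8, function(i) tokenize(random_window(i)))
  cb <- train_cbow(corpus, d_embed = 7L, epochs = 2L, seed = 2L)
  f <- tempfile(fileext = ".txt")
  save_embedding(cb$table, f)
  back <- load_embedding(f)
  expect_identical(rownames(back$vectors), rownames(cb$table$vectors))
  expect_equal(back$vectors, cb$table$vectors, tolerance = 1e-15,
               ignore_attr = TRUE)
  expect_equal(back$meta$window, cb$table$meta$window)
  expect_identical(back$meta$model, "CBOW")
})
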