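# k-mer tokenization and CBOW word embeddings.
#
# Sequences are treated as sentences and overlapping 3-mers as words.
# A 41-nt window yields 39 tokens; the closed vocabulary of head- or
# tail-dash-padded ACGU windows has 105 token types (64 pure ACGU
# triples, 20 dash-prefixed, 20 dash-suffixed, and '---').

#' Tokenize a sequence into overlapping k-mers
#'
#' Slides a window of size `k` with stride 1, so a sequence of length
#' `L` yields `L - k + 1` ordered tokens (39 for a 41-nt window with
#' `k = 3`).
#'
#' @param sequence character string.
#' @param k word size (default 3).
#' @return Character vector of tokens, in sequence order.
#' @examples
#' tokenize("GAUUA")   # "GAU" "AUU" "UUA"
#' @export
tokenize <- function(sequence, k = 3L) {
  L <- nchar(sequence)
  if (L < k) stopf("sequence length %d is shorter than k = %d", L, k)
  substring(sequence, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}

#' Build a k-mer vocabulary from a token corpus
#'
#' The vocabulary covers exactly the distinct tokens present in the
#' corpus, with deterministic 0-based indices assigned in lexicographic
#' order.
#'
#' @param corpus a list of token vectors (one per sequence).
#' @param k word size recorded in the vocabulary (default 3).
#' @return An object of class `kmer_vocab`: list with `kmer_to_index`
#'   (named integer vector, values `0 .. V-1`) and `k`.
#' @export
build_vocab <- function(corpus, k = 3L) {
  if (length(corpus) == 0L) stopf("corpus is empty")
  toks <- sort(unique(unlist(corpus, use.names = FALSE)))
  if (length(toks) == 0L) stopf("corpus contains no tokens")
  idx <- seq_along(toks) - 1L
  names(idx) <- toks
  structure(list(kmer_to_index = idx, k = as.integer(k)),
            class = "kmer_vocab")
}

#' @export
print.kmer_vocab <- function(x, ...) {
  cat(sprintf("<kmer_vocab: %d token types, k = %d>\n",
              length(x$kmer_to_index), x$k))
  invisible(x)
}

#' Train CBOW word embeddings on a token corpus
#'
#' Continuous-bag-of-words training with negative sampling.  For each
#' position the context vectors (a symmetric window, sentence-bounded)
#' are averaged and pushed toward the centre token and away from
#' `negative` noise tokens drawn from the unigram distribution raised to
#' 3/4.  Updates are batched per sentence (all positions of a sentence
#' share one parameter state), which vectorizes the inner loop while
#' keeping training bit-reproducible for a given corpus, parameter set
#' and seed.
#'
#' @param corpus a list of token vectors.
#' @param d_embed embedding dimension (default 100).
#' @param window one-sided context window (default 5).
#' @param epochs training epochs over the corpus (default 50).
#' @param seed integer seed for initialization and negative draws.
#' @param negative negative samples per position (default 5).
#' @param learning_rate SGD step size (default 0.05).
#' @param min_count tokens observed fewer times are dropped (default 1,
#'   i.e. keep everything).
#' @return `list(vocab, table)` where `vocab` is a [build_vocab()]
#'   vocabulary over the retained tokens and `table` is a
#'   `kmer_embedding` object: list with `vectors` (V x d_embed matrix,
#'   row names = tokens) and `meta` (window, epochs, seed, model,
#'   negative, learning_rate).
#' @export
train_cbow <- function(corpus, d_embed = 100L, window = 5L, epochs = 50L,
                       seed = 1L, negative = 5L, learning_rate = 0.05,
                       min_count = 1L) {
  if (length(corpus) == 0L) stopf("corpus is empty")
  if (!is_count(d_embed) || d_embed < 1L) stopf("d_embed must be >= 1")
  counts <- table(unlist(corpus, use.names = FALSE))
  keep <- names(counts)[counts >= min_count]
  if (length(keep) == 0L) stopf("min_count removes every token")
  corpus <- lapply(corpus, function(s) s[s %in% keep])
  corpus <- corpus[vapply(corpus, length, 0L) > 0L]
  vocab <- build_vocab(corpus)
  V <- length(vocab$kmer_to_index)
  noise <- as.numeric(counts[names(vocab$kmer_to_index)])^0.75
  noise <- noise / sum(noise)
  ## sentences as 1-based index vectors
  sent <- lapply(corpus, function(s)
    unname(vocab$kmer_to_index[s]) + 1L)

  W_in <- W_out <- NULL
  withr::with_seed(as.integer(seed), {
    W_in <- matrix(stats::runif(V * d_embed, -0.5, 0.5) / d_embed,
                   V, d_embed)
    W_out <- matrix(0, V, d_embed)
    offs <- c(-(window:1), 1:window)
    for (ep in seq_len(epochs)) {
      for (ids in sent) {
        n <- length(ids)
        ## context sums per position (sentence-bounded window)
        S <- matrix(0, n, d_embed)
        cnt <- numeric(n)
        for (off in offs) {
          t0 <- max(1L, 1L - off)
          t1 <- min(n, n - off)
          if (t0 > t1) next
          tt <- t0:t1
          S[tt, ] <- S[tt, , drop = FALSE] +
            W_in[ids[tt + off], , drop = FALSE]
          cnt[tt] <- cnt[tt] + 1
        }
        use <- which(cnt > 0)
        if (length(use) == 0L) next
        H <- S[use, , drop = FALSE] / cnt[use]
        nu <- length(use)
        targets <- cbind(ids[use],
                         matrix(sample.int(V, nu * negative, replace = TRUE,
                                           prob = noise),
                                nu, negative))
        lab <- c(1, numeric(negative))
        dH <- matrix(0, nu, d_embed)
        tgt_idx <- integer(0)
        tgt_grad <- vector("list", ncol(targets))
        for (j in seq_len(ncol(targets))) {
          rows <- targets[, j]
          Wt <- W_out[rows, , drop = FALSE]
          g <- (sigmoid(rowSums(H * Wt)) - lab[[j]]) * learning_rate
          dH <- dH + g * Wt
          tgt_grad[[j]] <- g * H
          tgt_idx <- c(tgt_idx, rows)
        }
        G <- do.call(rbind, tgt_grad)
        upd <- rowsum(G, tgt_idx)
        ui <- as.integer(rownames(upd))
        W_out[ui, ] <- W_out[ui, , drop = FALSE] - upd
        ## distribute dH back to the context input rows
        dHn <- dH / cnt[use]
        ctx_idx <- integer(0)
        ctx_grad <- vector("list", length(offs))
        ci <- 0L
        for (off in offs) {
          t0 <- max(1L, 1L - off)
          t1 <- min(n, n - off)
          if (t0 > t1) next
          tt <- intersect(t0:t1, use)
          if (length(tt) == 0L) next
          ci <- ci + 1L
          pos_in_use <- match(tt, use)
          ctx_grad[[ci]] <- dHn[pos_in_use, , drop = FALSE]
          ctx_idx <- c(ctx_idx, ids[tt + off])
        }
        if (ci > 0L) {
          Gc <- do.call(rbind, ctx_grad[seq_len(ci)])
          updc <- rowsum(Gc, ctx_idx)
          uic <- as.integer(rownames(updc))
          W_in[uic, ] <- W_in[uic, , drop = FALSE] - updc
        }
      }
    }
  })
  rownames(W_in) <- names(vocab$kmer_to_index)
  table <- structure(
    list(vectors = W_in,
         meta = list(model = "CBOW", window = as.integer(window),
                     epochs = as.integer(epochs), seed = as.integer(seed),
                     negative = as.integer(negative),
                     learning_rate = learning_rate)),
    class = "kmer_embedding")
  list(vocab = vocab, table = table)
}

#' @export
print.kmer_embedding <- function(x, ...) {
  cat(sprintf("<kmer_embedding: %d x %d (%s, window %d, %d epochs, seed %d)>\n",
              nrow(x$vectors), ncol(x$vectors), x$meta$model,
              x$meta$window, x$meta$epochs, x$meta$seed))
  invisible(x)
}

#' Embed a token list as a real-valued matrix
#'
#' Row `i` of the result is the embedding-table row for token `i`, so a
#' 41-nt window tokenized at `k = 3` becomes a 39 x d matrix.
#'
#' @param tokens ordered token vector.
#' @param table a `kmer_embedding` from [train_cbow()].
#' @param oov out-of-vocabulary policy: `"error"` (default, names the
#'   offending token) or `"zero"` (maps unseen tokens to the zero
#'   vector).
#' @return A `length(tokens) x d_embed` numeric matrix.
#' @export
embed_tokens <- function(tokens, table, oov = c("error", "zero")) {
  oov <- match.arg(oov)
  hit <- match(tokens, rownames(table$vectors))
  if (anyNA(hit)) {
    if (oov == "error")
      stopf("out-of-vocabulary token '%s'", tokens[is.na(hit)][[1L]])
    M <- matrix(0, length(tokens), ncol(table$vectors))
    ok <- !is.na(hit)
    M[ok, ] <- table$vectors[hit[ok], , drop = FALSE]
    return(M)
  }
  table$vectors[hit, , drop = FALSE]
}

## ---- persistence ----------------------------------------------------

#' Save embeddings in plain-text word2vec format
#'
#' Writes the standard header line `V d` followed by one
#' `token v1 ... vd` line per vocabulary entry, plus a JSON metadata
#' sidecar `<path>.meta.json` recording the training parameters.
#'
#' @param table a `kmer_embedding`.
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
save_embedding <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  V <- nrow(table$vectors)
  d <- ncol(table$vectors)
  writeLines(sprintf("%d %d", V, d), con)
  for (i in seq_len(V))
    writeLines(paste(rownames(table$vectors)[i],
                     paste(formatC(table$vectors[i, ], format = "g",
                                   digits = 17), collapse = " ")), con)
  jsonlite::write_json(table$meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' Load embeddings saved by [save_embedding()]
#'
#' @param path text file in word2vec format.
#' @return A `kmer_embedding` object (metadata restored from the
#'   sidecar when present).
#' @export
load_embedding <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[[1]], " ")[[1]])
  V <- hdr[[1]]; d <- hdr[[2]]
  M <- matrix(0, V, d)
  toks <- character(V)
  for (i in seq_len(V)) {
    parts <- strsplit(lines[[i + 1L]], " ")[[1]]
    toks[[i]] <- parts[[1]]
    M[i, ] <- as.numeric(parts[-1])
  }
  rownames(M) <- toks
  meta_path <- paste0(path, ".meta.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(list(vectors = M, meta = meta), class = "kmer_embedding")
}
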