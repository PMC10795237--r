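# Independent brute-force oracles.  These deliberately avoid the
# package's vectorized code paths: plain double loops and literal
# formula transcriptions, used to pin down the fast implementations.

## scaled dot-product attention, double loop
oracle_attention <- function(Q, K, V) {
  m_q <- nrow(Q); m_s <- nrow(K); dk <- ncol(Q)
  W <- matrix(0, m_q, m_s)
  out <- matrix(0, m_q, ncol(V))
  for (i in seq_len(m_q)) {
    sc <- numeric(m_s)
    for (j in seq_len(m_s)) sc[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    e <- exp(sc - max(sc))
    w <- e / sum(e)
    W[i, ] <- w
    for (j in seq_len(m_s)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  list(output = out, weights = W)
}

## multi-scale attention sublayer: every head and branch computed
## independently with explicit sub-matrix extraction, then concatenated
## and projected
oracle_msca <- function(x, aux, lp, config) {
  branches <- variant_branches(config$variant)
  h <- config$heads; dk <- config$d_k
  m_q <- nrow(x)
  heads <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * dk + 1L):(i * dk)
    acc <- matrix(0, m_q, dk)
    for (b in branches) {
      src <- if (b == "self") x else aux[[b]]
      Wq_i <- lp$attn[[b]]$Wq[, cols, drop = FALSE]
      Wk_i <- lp$attn[[b]]$Wk[, cols, drop = FALSE]
      Wv_i <- lp$attn[[b]]$Wv[, cols, drop = FALSE]
      att <- oracle_attention(x %*% Wq_i, src %*% Wk_i, src %*% Wv_i)
      acc <- acc + att$output
    }
    heads[[i]] <- acc
  }
  do.call(cbind, heads) %*% lp$Wo
}

## feed-forward network, row by row
oracle_ffn <- function(x, W1, b1, W2, b2) {
  out <- matrix(0, nrow(x), length(b2))
  for (i in seq_len(nrow(x))) {
    inner <- pmax(as.numeric(x[i, , drop = FALSE] %*% W1) + b1, 0)
    out[i, ] <- as.numeric(inner %*% W2) + b2
  }
  out
}

## sinusoidal positional encoding, scalar loop over the closed form
oracle_pe <- function(m, d) {
  PE <- matrix(0, m, d)
  for (pos in 0:(m - 1L)) {
    for (i in 0:(d / 2 - 1L)) {
      a <- pos / 10000^(2 * i / d)
      PE[pos + 1L, 2L * i + 1L] <- sin(a)
      PE[pos + 1L, 2L * i + 2L] <- cos(a)
    }
  }
  PE
}

## classification head by scalar arithmetic
oracle_classify <- function(encoded, w, b) {
  z <- numeric(ncol(encoded))
  for (j in seq_len(ncol(encoded))) z[j] <- mean(encoded[, j])
  1 / (1 + exp(-(sum(z * w) + b)))
}

## threshold metrics by literal substitution into the defining formulas
oracle_metrics <- function(TP, TN, FP, FN) {
  list(
    Sen = TP / (TP + FN),
    Spe = TN / (TN + FP),
    Acc = (TP + TN) / (TP + TN + FP + FN),
    Pre = TP / (TP + FP),
    F1 = 2 * (TP / (TP + FP)) * (TP / (TP + FN)) /
      (TP / (TP + FP) + TP / (TP + FN)),
    MCC = (TP * TN - FP * FN) /
      sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)))
}

## AUROC over all positive x negative pairs
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

## average precision by a literal walk over distinct thresholds
oracle_ap <- function(labels, scores) {
  npos <- sum(labels == 1)
  th <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_rec <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    prec <- tp / (tp + fp)
    rec <- tp / npos
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

## brute-force enumeration of the legal 3-mer types over the padded
## window alphabet: dashes must form a contiguous run at the head or
## the tail of the token (or fill it entirely)
oracle_padded_kmer_types <- function() {
  chars <- c("A", "C", "G", "U", "-")
  all3 <- expand.grid(chars, chars, chars, stringsAsFactors = FALSE)
  toks <- apply(all3, 1, paste, collapse = "")
  ok <- grepl("^-*[ACGU]+$|^[ACGU]+-*$|^-+$", toks)
  sort(toks[ok])
}
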