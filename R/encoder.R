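# The multi-scale self- and cross-attention encoder.
#
# A 41-nt window is represented at three centred scales (default 21,
# 41, 31 nt).  The first scale in `scale_order` is the query stream;
# the remaining two re-enter every encoder layer as key/value sources
# for two cross-attention branches.  Each of N layers holds a
# multi-scale attention sublayer (per-head, per-branch projections;
# branch outputs summed per head; heads concatenated and projected by
# W^O) and a position-wise feed-forward sublayer, both wrapped in
# dropout + residual + post-layer-normalization.  A mean-pool + linear
# + sigmoid head yields the site probability.
#
# Ablation variants mask branches:
#   MSCAN  self + cross(scale 2) + cross(scale 3)
#   SCAN   self + cross(scale 2)
#   SAN    self only (single-scale transformer baseline)
#   MCAN   both crosses, no self
#   CAN    cross(scale 2) only

VARIANTS <- c("MSCAN", "SCAN", "SAN", "MCAN", "CAN")

#' Branches of an encoder variant
#'
#' @param variant one of `MSCAN`, `SCAN`, `SAN`, `MCAN`, `CAN`.
#' @return Character vector drawn from `"self"`, `"c1"` (cross toward
#'   the second scale in `scale_order`), `"c2"` (cross toward the
#'   third).
#' @export
variant_branches <- function(variant) {
  switch(variant,
         MSCAN = c("self", "c1", "c2"),
         SCAN  = c("self", "c1"),
         SAN   = "self",
         MCAN  = c("c1", "c2"),
         CAN   = "c1",
         stopf("unknown variant '%s' (expected one of %s)", variant,
               paste(VARIANTS, collapse = ", ")))
}

## which scales (positions in scale_order) a variant consumes
variant_scales <- function(variant) {
  b <- variant_branches(variant)
  sort(unique(c(1L, ifelse(b == "self", 1L, ifelse(b == "c1", 2L, 3L)))))
}

#' Architecture configuration
#'
#' Defaults are the reference architecture: `d_model = 64`, `h = 8`
#' heads with `d_k = d_v = d_model / h = 8`, feed-forward inner width
#' `d_ff = 256`, `N = 3` stacked layers, dropout 0.2, scales
#' `(21, 41, 31)` with the 21-nt window as the query stream, and 100-d
#' word embeddings bridged to `d_model` by a learned affine projection
#' per scale.
#'
#' @param d_model encoder width.
#' @param heads number of attention heads `h`.
#' @param d_ff feed-forward inner width.
#' @param layers number of stacked encoder layers `N`.
#' @param dropout dropout rate in `[0, 1)`.
#' @param scale_order ordered triple of odd window lengths `<= 41`,
#'   pairwise distinct; the first is the query scale.
#' @param d_embed word-embedding dimension entering the projection.
#' @param variant one of `MSCAN`, `SCAN`, `SAN`, `MCAN`, `CAN`.
#' @return A list of class `mscan_config`.  `d_k` and `d_v` are derived
#'   as `d_model / heads`; configurations where that division is not
#'   exact are rejected.
#' @export
model_config <- function(d_model = 64L, heads = 8L, d_ff = 256L,
                         layers = 3L, dropout = 0.2,
                         scale_order = c(21L, 41L, 31L), d_embed = 100L,
                         variant = "MSCAN") {
  variant_branches(variant)  # validates
  if (d_model %% heads != 0L)
    stopf("d_model (%d) must be an exact multiple of heads (%d)",
          d_model, heads)
  if (length(scale_order) != 3L || anyDuplicated(scale_order) ||
      any(scale_order %% 2L != 1L) || any(scale_order > 41L) ||
      any(scale_order < 3L))
    stopf("scale_order must be three distinct odd window lengths in [3, 41]")
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  structure(list(
    d_model = as.integer(d_model), heads = as.integer(heads),
    d_k = as.integer(d_model %/% heads), d_v = as.integer(d_model %/% heads),
    d_ff = as.integer(d_ff), layers = as.integer(layers),
    dropout = dropout, scale_order = as.integer(scale_order),
    d_embed = as.integer(d_embed), variant = variant),
    class = "mscan_config")
}

#' Extract the centred sub-windows of a 41-nt window
#'
#' Returns the 21-nt and 31-nt substrings centred on the middle base
#' (0-based indices `[10, 31)` and `[5, 36)`).
#'
#' @param sequence a 41-character string.
#' @return `list(s21 = <21-nt>, s31 = <31-nt>)`.
#' @export
extract_subsequences <- function(sequence) {
  if (nchar(sequence) != 41L)
    stopf("expected a 41-character sequence, got %d", nchar(sequence))
  list(s21 = substr(sequence, 11L, 31L), s31 = substr(sequence, 6L, 36L))
}

## centred window of odd length s from a 41-nt sequence
scale_window <- function(sequence, s) {
  L <- nchar(sequence)
  start <- (L - s) %/% 2L + 1L
  substr(sequence, start, start + s - 1L)
}

#' Sinusoidal positional encoding
#'
#' Entry `(pos, 2i)` is `sin(pos / 10000^(2i/d_model))` and entry
#' `(pos, 2i + 1)` is `cos(pos / 10000^(2i/d_model))` (0-based), the
#' fixed non-learned encoding of the original transformer.
#'
#' @param m number of positions.
#' @param d_model encoding width (even).
#' @return An `m x d_model` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(m, d_model) {
  if (m < 1L) stopf("m must be >= 1")
  if (d_model %% 2L != 0L) stopf("d_model must be even")
  key <- sprintf("%d_%d", m, d_model)
  hit <- .pe_cache[[key]]
  if (!is.null(hit)) return(hit)
  pos <- 0:(m - 1L)
  i2 <- 2 * ((0:(d_model - 1L)) %/% 2L)      # 0,0,2,2,4,4,...
  ang <- outer(pos, 10000^(-i2 / d_model))
  PE <- matrix(0, m, d_model)
  odd_cols <- seq(1L, d_model, by = 2L)      # 0-based even -> sin
  even_cols <- seq(2L, d_model, by = 2L)     # 0-based odd  -> cos
  PE[, odd_cols] <- sin(ang[, odd_cols, drop = FALSE])
  PE[, even_cols] <- cos(ang[, even_cols, drop = FALSE])
  .pe_cache[[key]] <- PE
  PE
}

## memo cache for the (deterministic) positional encodings
.pe_cache <- new.env(parent = emptyenv())

#' Project word embeddings to the encoder width
#'
#' A learned affine map applied row-wise, bridging the `d_embed`-wide
#' word vectors to `d_model`.
#'
#' @param x `m x d_embed` matrix.
#' @param W `d_embed x d_model` weight matrix.
#' @param b length-`d_model` bias.
#' @return `m x d_model` matrix `x W + b`.
#' @export
project_embedding <- function(x, W, b) {
  if (ncol(x) != nrow(W))
    stopf("embedding width %d does not match projection input %d",
          ncol(x), nrow(W))
  add_rowvec(x %*% W, b)
}

#' Scaled dot-product attention
#'
#' `softmax(Q K' / sqrt(d_k)) V`, with the softmax taken row-wise over
#' the key axis.
#'
#' @param Q `m_q x d_k` query matrix.
#' @param K `m_s x d_k` key matrix.
#' @param V `m_s x d_v` value matrix.
#' @return `list(output = m_q x d_v matrix, weights = m_q x m_s
#'   attention matrix)`; every weight row sums to 1.
#' @export
scaled_dot_attention <- function(Q, K, V) {
  if (!all(is.finite(Q), is.finite(K), is.finite(V)))
    stopf("non-finite attention inputs")
  if (ncol(Q) != ncol(K)) stopf("Q and K widths differ")
  if (nrow(K) != nrow(V)) stopf("K and V row counts differ")
  P <- row_softmax(tcrossprod(Q, K) / sqrt(ncol(Q)))
  list(output = P %*% V, weights = P)
}

#' Multi-scale self- and cross-attention sublayer
#'
#' For each head, the active branches are computed independently with
#' per-head, per-branch query/key/value projections and summed:
#' self-attention on the query stream, and cross-attention with queries
#' from the query stream and keys/values from each auxiliary scale.
#' Head outputs are concatenated and projected by `W^O`.
#'
#' @param x `m_q x d_model` query-stream matrix.
#' @param aux list with elements `c1` and/or `c2`: auxiliary-scale
#'   matrices (`m_s x d_model`), as required by the variant.
#' @param lp layer parameters: `lp$attn[[branch]]` holds `Wq`, `Wk`,
#'   `Wv` (`d_model x d_model`, heads packed in column blocks) and
#'   `lp$Wo` is `d_model x d_model`.
#' @param config an [model_config()].
#' @param keep_cache keep intermediates for backpropagation.
#' @return `m_q x d_model` matrix (with attribute `"cache"` when
#'   requested).
#' @export
msca_sublayer <- function(x, aux, lp, config, keep_cache = FALSE) {
  branches <- variant_branches(config$variant)
  h <- config$heads; dk <- config$d_k
  m_q <- nrow(x)
  H <- matrix(0, m_q, config$d_model)
  cache <- if (keep_cache) list(branches = list()) else NULL
  for (b in branches) {
    src <- if (b == "self") x else aux[[b]]
    if (is.null(src)) stopf("variant %s needs auxiliary scale '%s'",
                            config$variant, b)
    Q <- x %*% lp$attn[[b]]$Wq
    K <- src %*% lp$attn[[b]]$Wk
    V <- src %*% lp$attn[[b]]$Wv
    P_heads <- if (keep_cache) vector("list", h) else NULL
    sq <- sqrt(dk)
    for (i in seq_len(h)) {
      cols <- ((i - 1L) * dk + 1L):(i * dk)
      ## scaled dot-product attention, inlined for speed (the exported
      ## scaled_dot_attention() is the validated reference path)
      P <- row_softmax(tcrossprod(Q[, cols, drop = FALSE],
                                  K[, cols, drop = FALSE]) / sq)
      H[, cols] <- H[, cols, drop = FALSE] + P %*% V[, cols, drop = FALSE]
      if (keep_cache) P_heads[[i]] <- P
    }
    if (keep_cache)
      cache$branches[[b]] <- list(Q = Q, K = K, V = V, P = P_heads,
                                  src = src)
  }
  out <- H %*% lp$Wo
  if (keep_cache) {
    cache$H <- H
    attr(out, "cache") <- cache
  }
  out
}

#' Position-wise feed-forward network
#'
#' `max(0, x W1 + b1) W2 + b2` applied row-wise; the inner width is
#' `d_ff`.
#'
#' @param x `m x d_model` matrix.
#' @param W1,b1,W2,b2 parameters (`d_model x d_ff`, `d_ff`,
#'   `d_ff x d_model`, `d_model`).
#' @return `m x d_model` matrix.
#' @export
ffn <- function(x, W1, b1, W2, b2) {
  h <- add_rowvec(x %*% W1, b1)
  add_rowvec(pmax(h, 0) %*% W2, b2)
}

#' Row-wise layer normalization
#'
#' Each row is standardized to mean 0 and (population) variance 1, then
#' rescaled by `gamma` and shifted by `beta`.
#'
#' @param x `m x d` matrix.
#' @param gamma,beta length-`d` scale and shift.
#' @param eps variance floor (default `1e-5`).
#' @param keep_cache keep intermediates for backpropagation.
#' @return Normalized `m x d` matrix (attribute `"cache"` when
#'   requested).
#' @export
layer_norm <- function(x, gamma, beta, eps = 1e-5, keep_cache = FALSE) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- add_rowvec(sweep(xhat, 2L, gamma, `*`), beta)
  if (keep_cache) attr(out, "cache") <- list(xhat = xhat, inv = inv)
  out
}

#' Classification head
#'
#' Mean-pools the encoder output over positions, applies a linear map
#' to a single logit, and squashes with the sigmoid.
#'
#' @param encoded `m_q x d_model` encoder output.
#' @param w length-`d_model` weight vector.
#' @param b scalar bias.
#' @return Probability in `(0, 1)`.
#' @export
classify_encoded <- function(encoded, w, b) {
  if (nrow(encoded) < 1L) stopf("empty encoder output")
  sigmoid(sum(colMeans(encoded) * w) + b)
}

## ---- parameter initialization ---------------------------------------

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

init_params <- function(config) {
  d <- config$d_model
  branches <- variant_branches(config$variant)
  scales <- variant_scales(config$variant)
  proj <- vector("list", 3L)
  for (s in scales)
    proj[[s]] <- list(W = glorot(config$d_embed, d), b = numeric(d))
  layers <- vector("list", config$layers)
  for (l in seq_len(config$layers)) {
    attn <- list()
    for (b in branches)
      attn[[b]] <- list(Wq = glorot(d, d), Wk = glorot(d, d),
                        Wv = glorot(d, d))
    layers[[l]] <- list(
      attn = attn, Wo = glorot(d, d),
      ln1_g = rep(1, d), ln1_b = numeric(d),
      W1 = glorot(d, config$d_ff), b1 = numeric(config$d_ff),
      W2 = glorot(config$d_ff, d), b2 = numeric(d),
      ln2_g = rep(1, d), ln2_b = numeric(d))
  }
  list(proj = proj, layers = layers,
       clf = list(w = glorot(d, 1L)[, 1L], b = 0))
}

#' Build an initialized encoder variant
#'
#' @param variant one of `MSCAN`, `SCAN`, `SAN`, `MCAN`, `CAN`.
#' @param config an [model_config()] (its `variant` field is
#'   overridden).
#' @param seed integer seed; identical seeds give bitwise-identical
#'   initial parameters (Glorot-uniform weights, zero biases, unit
#'   layer-norm gains).
#' @return A list of class `mscan_net` with elements `config` and
#'   `params`.  Variants that do not consume a scale carry no
#'   parameters for it (SAN consumes only the query scale).
#' @export
build_variant <- function(variant, config = model_config(), seed = 1L) {
  config$variant <- variant
  variant_branches(variant)  # validates
  params <- withr::with_seed(as.integer(seed), init_params(config))
  structure(list(config = config, params = params), class = "mscan_net")
}

#' Number of trainable parameters
#'
#' @param net an `mscan_net` (or a bare parameter list).
#' @return Total count of scalar parameters.
#' @export
count_parameters <- function(net) {
  p <- if (!is.null(net$params)) net$params else net
  sum(unlist(rapply(p, length, how = "unlist")))
}

#' @export
print.mscan_net <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<mscan_net %s: d_model=%d h=%d N=%d d_ff=%d scales=(%s), %d parameters>\n",
    cfg$variant, cfg$d_model, cfg$heads, cfg$layers, cfg$d_ff,
    paste(cfg$scale_order, collapse = ","), count_parameters(x)))
  invisible(x)
}

## ---- full forward pass ----------------------------------------------

## Dropout masks are pre-drawn (inverted dropout): mask entries are
## 0 or 1/(1-p).  In evaluation mode masks are NULL and dropout is the
## identity.
draw_mask <- function(m, d, p) {
  matrix((stats::runif(m * d) >= p) / (1 - p), m, d)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

#' Run the encoder on a scale bundle
#'
#' Applies the per-scale embedding projection, adds the sinusoidal
#' positional encoding, and runs the `N` stacked layers.  Only the
#' query stream is re-encoded across layers; auxiliary scales re-enter
#' every layer as their projected, position-encoded embeddings.  In
#' evaluation mode (`masks = NULL`) the forward pass is a pure,
#' deterministic function.
#'
#' @param X list of up to three `m_s x d_embed` token-embedding
#'   matrices, ordered as `config$scale_order` (query scale first).
#'   Scales the variant does not consume may be `NULL`.
#' @param params parameter list from [build_variant()].
#' @param config an [model_config()].
#' @param masks dropout masks from training, or `NULL` for evaluation.
#' @param keep_cache keep all intermediates (used by the training
#'   backward pass).
#' @return `m_q x d_model` encoded query stream; with `keep_cache` the
#'   full cache is attached as attribute `"cache"`.
#' @export
encoder_forward <- function(X, params, config, masks = NULL,
                            keep_cache = FALSE) {
  scales <- variant_scales(config$variant)
  E <- vector("list", 3L)
  cache <- if (keep_cache) list(E = list(), layers = list()) else NULL
  for (s in scales) {
    if (is.null(X[[s]]))
      stopf("variant %s needs scale %d of the bundle", config$variant, s)
    P <- project_embedding(X[[s]], params$proj[[s]]$W, params$proj[[s]]$b)
    Ps <- P + positional_encoding(nrow(P), config$d_model)
    E[[s]] <- apply_mask(Ps, msk(masks, "emb", s))
  }
  aux <- list(c1 = E[[2L]], c2 = E[[3L]])
  x <- E[[1L]]
  if (keep_cache) cache$E <- E
  for (l in seq_len(config$layers)) {
    lp <- params$layers[[l]]
    lcache <- if (keep_cache) list(x0 = x) else NULL
    M <- msca_sublayer(x, aux, lp, config, keep_cache = keep_cache)
    if (keep_cache) lcache$att <- attr(M, "cache")
    M <- apply_mask(as.matrix(M), msk(masks, "layers", l, "m1"))
    y1 <- layer_norm(x + M, lp$ln1_g, lp$ln1_b, keep_cache = keep_cache)
    if (keep_cache) {
      lcache$ln1 <- attr(y1, "cache")
      lcache$a1 <- x + M
    }
    y1 <- as.matrix(y1)
    h1 <- add_rowvec(y1 %*% lp$W1, lp$b1)
    r <- pmax(h1, 0)
    F_ <- add_rowvec(r %*% lp$W2, lp$b2)
    Fd <- apply_mask(F_, msk(masks, "layers", l, "m2"))
    y2 <- layer_norm(y1 + Fd, lp$ln2_g, lp$ln2_b, keep_cache = keep_cache)
    if (keep_cache) {
      lcache$ln2 <- attr(y2, "cache")
      lcache$y1 <- y1; lcache$h1 <- h1; lcache$r <- r
      cache$layers[[l]] <- lcache
    }
    x <- as.matrix(y2)
  }
  if (keep_cache) {
    cache$x_out <- x
    attr(x, "cache") <- cache
  }
  x
}

## Forward to a probability; used by prediction and training.
forward_prob <- function(X, params, config, masks = NULL,
                         keep_cache = FALSE) {
  enc <- encoder_forward(X, params, config, masks = masks,
                         keep_cache = keep_cache)
  z <- colMeans(enc)
  logit <- sum(z * params$clf$w) + params$clf$b
  p <- sigmoid(logit)
  if (keep_cache)
    list(prob = p, logit = logit, z = z, cache = attr(enc, "cache"))
  else p
}
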