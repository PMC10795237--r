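# Reverse-mode gradients for the encoder, written against the cached
# forward pass in encoder_forward()/forward_prob().  Gradients flow
# through the classification head, the N layers (attention and FFN
# sublayers with post-layer-norm residuals), into the query stream and,
# via the cross branches of every layer, into the auxiliary streams and
# their embedding projections.

## structural helpers over nested parameter lists (NULL slots allowed) --

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

leaf_list <- function(p) {
  out <- vector("list", 256L)
  n <- 0L
  rec <- function(x) {
    if (is.list(x)) {
      for (i in seq_along(x)) if (!is.null(x[[i]])) rec(x[[i]])
    } else {
      n <<- n + 1L
      out[[n]] <<- x
    }
  }
  rec(p)
  out[seq_len(n)]
}

set_leaves <- function(p, leaves) {
  i <- 0L
  rec <- function(x) {
    if (is.list(x)) {
      for (j in seq_along(x)) if (!is.null(x[[j]])) x[[j]] <- rec(x[[j]])
      x
    } else {
      i <<- i + 1L
      leaves[[i]]
    }
  }
  rec(p)
}

## safe nested lookup into a (possibly NULL) mask structure
msk <- function(m, ...) {
  for (k in list(...)) {
    if (is.null(m)) return(NULL)
    m <- m[[k]]
  }
  m
}

## layer-norm backward: dy -> (dx, dgamma, dbeta)
ln_backward <- function(dy, gamma, cache) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2L, gamma, `*`)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) *
    cache$inv
  list(dx = dx, dg = dg, db = db)
}

## Gradient of the loss w.r.t. all parameters for one sample.
## fp: result of forward_prob(..., keep_cache = TRUE); dlogit: upstream
## gradient at the logit; X: raw embedding bundle (for the projection
## gradients); masks: the dropout masks used in the forward pass.
backward_sample <- function(fp, X, params, config, masks, dlogit) {
  g <- zero_like(params)
  cache <- fp$cache
  d <- config$d_model
  h <- config$heads
  dk <- config$d_k
  branches <- variant_branches(config$variant)
  scales <- variant_scales(config$variant)

  g$clf$w <- dlogit * fp$z
  g$clf$b <- dlogit
  m_q <- nrow(cache$x_out)
  dx <- matrix(dlogit * params$clf$w / m_q, m_q, d, byrow = TRUE)

  dE <- vector("list", 3L)  # grads at the (masked) per-scale streams
  for (l in rev(seq_len(config$layers))) {
    lp <- params$layers[[l]]
    lc <- cache$layers[[l]]
    ## FFN sublayer (post-norm residual)
    bn2 <- ln_backward(dx, lp$ln2_g, lc$ln2)
    g$layers[[l]]$ln2_g <- bn2$dg
    g$layers[[l]]$ln2_b <- bn2$db
    da2 <- bn2$dx
    dy1 <- da2
    dF <- apply_mask(da2, msk(masks, "layers", l, "m2"))
    g$layers[[l]]$W2 <- crossprod(lc$r, dF)
    g$layers[[l]]$b2 <- colSums(dF)
    dh1 <- tcrossprod(dF, lp$W2) * (lc$h1 > 0)
    g$layers[[l]]$W1 <- crossprod(lc$y1, dh1)
    g$layers[[l]]$b1 <- colSums(dh1)
    dy1 <- dy1 + tcrossprod(dh1, lp$W1)
    ## attention sublayer
    bn1 <- ln_backward(dy1, lp$ln1_g, lc$ln1)
    g$layers[[l]]$ln1_g <- bn1$dg
    g$layers[[l]]$ln1_b <- bn1$db
    da1 <- bn1$dx
    dx0 <- da1
    dM <- apply_mask(da1, msk(masks, "layers", l, "m1"))
    g$layers[[l]]$Wo <- crossprod(lc$att$H, dM)
    dH <- tcrossprod(dM, lp$Wo)
    for (b in branches) {
      bc <- lc$att$branches[[b]]
      dQ <- matrix(0, nrow(bc$Q), d)
      dK <- matrix(0, nrow(bc$K), d)
      dV <- matrix(0, nrow(bc$V), d)
      for (i in seq_len(h)) {
        cols <- ((i - 1L) * dk + 1L):(i * dk)
        datt <- dH[, cols, drop = FALSE]
        P <- bc$P[[i]]
        dV[, cols] <- crossprod(P, datt)
        dP <- tcrossprod(datt, bc$V[, cols, drop = FALSE])
        dS <- ((dP - rowSums(dP * P)) * P) / sqrt(dk)
        dQ[, cols] <- dS %*% bc$K[, cols, drop = FALSE]
        dK[, cols] <- crossprod(dS, bc$Q[, cols, drop = FALSE])
      }
      g$layers[[l]]$attn[[b]]$Wq <- crossprod(lc$x0, dQ)
      dx0 <- dx0 + tcrossprod(dQ, lp$attn[[b]]$Wq)
      g$layers[[l]]$attn[[b]]$Wk <- crossprod(bc$src, dK)
      g$layers[[l]]$attn[[b]]$Wv <- crossprod(bc$src, dV)
      dsrc <- tcrossprod(dK, lp$attn[[b]]$Wk) +
        tcrossprod(dV, lp$attn[[b]]$Wv)
      if (b == "self") {
        dx0 <- dx0 + dsrc
      } else {
        s <- if (b == "c1") 2L else 3L
        dE[[s]] <- if (is.null(dE[[s]])) dsrc else dE[[s]] + dsrc
      }
    }
    dx <- dx0
  }
  dE[[1L]] <- if (is.null(dE[[1L]])) dx else dE[[1L]] + dx
  for (s in scales) {
    if (is.null(dE[[s]])) next
    dP <- apply_mask(dE[[s]], msk(masks, "emb", s))
    g$proj[[s]]$W <- crossprod(X[[s]], dP)
    g$proj[[s]]$b <- colSums(dP)
  }
  g
}

## Pre-draw the dropout masks for one sample (fixed order: embedding
## streams in scale order, then per layer m1, m2).
make_masks <- function(config, m_by_scale) {
  p <- config$dropout
  if (p <= 0) return(NULL)
  d <- config$d_model
  emb <- vector("list", 3L)
  for (s in variant_scales(config$variant))
    emb[[s]] <- draw_mask(m_by_scale[[s]], d, p)
  m_q <- m_by_scale[[1L]]
  layers <- lapply(seq_len(config$layers), function(l)
    list(m1 = draw_mask(m_q, d, p), m2 = draw_mask(m_q, d, p)))
  list(emb = emb, layers = layers)
}
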