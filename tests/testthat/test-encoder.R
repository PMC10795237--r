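# multiscale_encoder: subsequences, positional encoding, attention,
# sublayers, forward pass, variants.

test_that("subsequence extraction is centred and length-correct", {
  w <- random_window(3)
  sub <- extract_subsequences(w)
  expect_equal(nchar(sub$s21), 21L)
  expect_equal(nchar(sub$s31), 31L)
  expect_identical(substr(sub$s21, 11, 11), substr(w, 21, 21))
  expect_identical(substr(sub$s31, 16, 16), substr(w, 21, 21))
  expect_identical(sub$s21, substr(w, 11, 31))
  expect_identical(sub$s31, substr(w, 6, 36))
  marked <- paste0(strrep("A", 20), "G", strrep("A", 20))
  expect_identical(substr(extract_subsequences(marked)$s21, 11, 11), "G")
  expect_error(extract_subsequences(strrep("A", 40)), "41")
})

test_that("positional encoding matches the closed form", {
  for (dims in list(c(5L, 8L), c(19L, 64L), c(1L, 4L))) {
    PE <- positional_encoding(dims[1], dims[2])
    expect_equal(PE, oracle_pe(dims[1], dims[2]), tolerance = 1e-12)
    expect_true(all(PE >= -1 & PE <= 1))
  }
  PE <- positional_encoding(4L, 6L)
  expect_equal(PE[1, c(1, 3, 5)], c(0, 0, 0))       # sin 0
  expect_equal(PE[1, c(2, 4, 6)], c(1, 1, 1))       # cos 0
  expect_equal(PE[2, 1], sin(1), tolerance = 1e-12) # ~0.8415
  expect_error(positional_encoding(3L, 5L), "even")
})

test_that("scaled dot-product attention: degenerate and oracle cases", {
  withr::with_seed(21, {
    ## single key/value row: weights collapse to 1
    Q <- matrix(rnorm(6), 3, 2); K <- matrix(rnorm(2), 1, 2)
    V <- matrix(rnorm(2), 1, 2)
    att <- scaled_dot_attention(Q, K, V)
    expect_equal(unname(att$weights), matrix(1, 3, 1))
    expect_equal(att$output, matrix(V, 3, 2, byrow = TRUE))
    ## orthogonal queries: uniform weights, column-mean output
    K2 <- matrix(rnorm(8), 4, 2)
    V2 <- matrix(rnorm(8), 4, 2)
    att2 <- scaled_dot_attention(matrix(0, 2, 2), K2, V2)
    expect_equal(unname(att2$weights), matrix(0.25, 2, 4))
    expect_equal(att2$output[1, ], colMeans(V2))
    ## random case against the double-loop oracle
    for (r in 1:20) {
      Q <- matrix(rnorm(6), 3, 2); K <- matrix(rnorm(10), 5, 2)
      V <- matrix(rnorm(15), 5, 3)
      got <- scaled_dot_attention(Q, K, V)
      want <- oracle_attention(Q, K, V)
      expect_equal(got$output, want$output, tolerance = 1e-10)
      expect_equal(got$weights, want$weights, tolerance = 1e-10)
      expect_equal(rowSums(got$weights), rep(1, 3), tolerance = 1e-6)
    }
  })
  expect_error(scaled_dot_attention(matrix(NaN, 1, 2), matrix(0, 1, 2),
                                    matrix(0, 1, 2)), "non-finite")
})

test_that("msca_sublayer honours shapes, variants and linearity", {
  cfg <- tiny_config()
  lp <- tiny_layer_params(cfg, seed = 2L)
  bun <- random_bundle_dm(cfg, seed = 3L)
  for (v in c("MSCAN", "SCAN", "SAN", "MCAN", "CAN")) {
    cfg_v <- tiny_config(variant = v)
    lp_v <- tiny_layer_params(cfg_v, seed = 2L)
    out <- msca_sublayer(bun$x, bun$aux, lp_v, cfg_v)
    expect_identical(dim(out), c(3L, 8L))
  }
  ## zero value projections null the output
  lp0 <- lp
  for (b in names(lp0$attn)) lp0$attn[[b]]$Wv <- lp0$attn[[b]]$Wv * 0
  expect_equal(msca_sublayer(bun$x, bun$aux, lp0, cfg),
               matrix(0, 3, 8))
  expect_error(variant_branches("XCAN"), "unknown variant")
})

test_that("msca_sublayer matches the per-head brute-force oracle", {
  variants <- c("MSCAN", "SCAN", "SAN", "MCAN", "CAN")
  for (r in 1:25) {
    v <- variants[(r %% 5) + 1]
    cfg <- tiny_config(variant = v)
    lp <- tiny_layer_params(cfg, seed = r)
    bun <- random_bundle_dm(cfg, seed = r + 50L,
                            m = sample(3:6, 3, replace = TRUE))
    expect_equal(msca_sublayer(bun$x, bun$aux, lp, cfg),
                 oracle_msca(bun$x, bun$aux, lp, cfg),
                 tolerance = 1e-8)
  }
})

test_that("joint K/V row permutation of an aux scale is a no-op", {
  cfg <- tiny_config(variant = "MSCAN")
  lp <- tiny_layer_params(cfg, seed = 4L)
  bun <- random_bundle_dm(cfg, seed = 5L)
  base <- msca_sublayer(bun$x, bun$aux, lp, cfg)
  withr::with_seed(6, {
    for (r in 1:5) {
      perm <- sample(nrow(bun$aux$c1))
      aux_p <- bun$aux
      aux_p$c1 <- aux_p$c1[perm, , drop = FALSE]
      expect_equal(msca_sublayer(bun$x, aux_p, lp, cfg), base,
                   tolerance = 1e-12)
    }
  })
})

test_that("ffn matches its oracle and its closed forms", {
  ## identity-like weights on nonnegative input pass through
  x <- matrix(abs(rnorm(12)), 3, 4)
  I4 <- diag(4)
  expect_equal(ffn(x, I4, numeric(4), I4, numeric(4)), x)
  ## all-negative inner activations leave only the output bias
  W1 <- diag(4); b1 <- rep(-100, 4)
  b2 <- c(1, 2, 3, 4)
  expect_equal(ffn(x * 0, W1, b1, diag(4), b2),
               matrix(b2, 3, 4, byrow = TRUE))
  withr::with_seed(31, {
    for (r in 1:20) {
      x <- matrix(rnorm(8), 2, 4)
      W1 <- matrix(rnorm(32), 4, 8); b1 <- rnorm(8)
      W2 <- matrix(rnorm(32), 8, 4); b2 <- rnorm(4)
      expect_equal(ffn(x, W1, b1, W2, b2),
                   oracle_ffn(x, W1, b1, W2, b2), tolerance = 1e-10)
    }
  })
})

test_that("layer normalization standardizes rows", {
  withr::with_seed(41, {
    x <- matrix(rnorm(60, sd = 3), 5, 12)
    y <- layer_norm(x, rep(1, 12), numeric(12))
    expect_equal(rowMeans(y), numeric(5), tolerance = 1e-10)
    expect_equal(apply(y, 1, function(r) mean(r^2)), rep(1, 5),
                 tolerance = 1e-4)
  })
})

test_that("classification head: closed forms and range", {
  enc <- matrix(c(1, 3, 2, 4), 2, 2)
  expect_equal(classify_encoded(enc, numeric(2), 0), 0.5)
  w <- c(0.5, -1); b <- 0.25
  expect_equal(classify_encoded(enc, w, b),
               1 / (1 + exp(-(0.5 * 2 - 1 * 3 + 0.25))),
               tolerance = 1e-12)
  withr::with_seed(51, {
    for (r in 1:20) {
      enc <- matrix(rnorm(12, sd = 5), 3, 4)
      w <- rnorm(4, sd = 5); b <- rnorm(1)
      p <- classify_encoded(enc, w, b)
      expect_true(p > 0 && p < 1)
      expect_equal(p, oracle_classify(enc, w, b), tolerance = 1e-12)
    }
  })
})

test_that("config invariants are enforced", {
  expect_error(model_config(d_model = 64L, heads = 7L), "multiple")
  expect_error(model_config(scale_order = c(20L, 41L, 31L)), "odd")
  expect_error(model_config(scale_order = c(21L, 21L, 31L)), "distinct")
  expect_error(model_config(scale_order = c(21L, 43L, 31L)), "41")
  cfg <- model_config()
  expect_identical(cfg$d_k, 8L)
  expect_identical(cfg$d_v, 8L)
  expect_identical(cfg$d_k * cfg$heads, cfg$d_model)
})

test_that("build_variant: deterministic init and analytic size", {
  cfg <- model_config()           # reference architecture
  net1 <- build_variant("MSCAN", cfg, seed = 17L)
  net2 <- build_variant("MSCAN", cfg, seed = 17L)
  expect_identical(net1$params, net2$params)
  expect_false(identical(net1$params,
                         build_variant("MSCAN", cfg, seed = 18L)$params))
  ## closed-form parameter count per variant
  for (v in c("MSCAN", "SCAN", "SAN", "MCAN", "CAN")) {
    n_br <- length(variant_branches(v))
    n_sc <- length(mscan:::variant_scales(v))
    d <- cfg$d_model
    expected <- n_sc * (cfg$d_embed * d + d) +                 # projections
      cfg$layers * (n_br * 3L * d * d + d * d + 2L * d +       # attention
                    d * cfg$d_ff + cfg$d_ff + cfg$d_ff * d + d +
                    2L * d) +                                   # ffn + norms
      d + 1L                                                    # head
    expect_equal(count_parameters(build_variant(v, cfg, seed = 1L)),
                 expected)
  }
})

test_that("SAN consumes only the query scale", {
  cfg <- tiny_config(variant = "SAN")
  net <- build_variant("SAN", cfg, seed = 9L)
  withr::with_seed(10, {
    X <- list(matrix(rnorm(3 * 8), 3, 8), matrix(rnorm(7 * 8), 7, 8),
              matrix(rnorm(5 * 8), 5, 8))
    base <- encoder_forward(X, net$params, cfg)
    X2 <- X
    X2[[2]] <- X2[[2]] * 100
    X2[[3]] <- NULL
    expect_identical(encoder_forward(X2, net$params, cfg), base)
  })
})

test_that("encoder forward: empty stack, determinism, normalized output", {
  cfg0 <- tiny_config(layers = 0L)
  net0 <- build_variant("MSCAN", cfg0, seed = 1L)
  withr::with_seed(12, {
    X <- list(matrix(rnorm(3 * 8), 3, 8), matrix(rnorm(7 * 8), 7, 8),
              matrix(rnorm(5 * 8), 5, 8))
    out0 <- encoder_forward(X, net0$params, cfg0)
    manual <- project_embedding(X[[1]], net0$params$proj[[1]]$W,
                                net0$params$proj[[1]]$b) +
      positional_encoding(3L, 8L)
    expect_equal(out0, manual, tolerance = 1e-12)
    ## evaluation mode is a pure function
    cfg <- tiny_config(layers = 2L, dropout = 0.2)  # rate ignored in eval
    net <- build_variant("MSCAN", cfg, seed = 2L)
    o1 <- encoder_forward(X, net$params, cfg)
    o2 <- encoder_forward(X, net$params, cfg)
    expect_identical(o1, o2)
    ## post-norm output rows are standardized before the affine rescale
    lnp <- net$params$layers[[2]]
    expect_equal(lnp$ln2_g, rep(1, 8))   # fresh init: gain 1, shift 0
    expect_equal(rowMeans(o1), numeric(3), tolerance = 1e-4)
    expect_equal(apply(o1, 1, function(r) mean(r^2)), rep(1, 3),
                 tolerance = 1e-3)
  })
})
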