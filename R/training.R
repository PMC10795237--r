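# Mini-batch Adam training with binary cross-entropy, the end-to-end
# fitting pipeline (CBOW embeddings -> encoder -> classifier), and the
# exhaustive grid-search harness.

#' Optimization configuration
#'
#' Defaults are the reference hyperparameters: 100 epochs, learning
#' rate 5e-4 (Adam), batch size 10, dropout 0.2.
#'
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size; the last partial batch is kept.
#' @param dropout dropout rate (overrides the model config during
#'   training).
#' @param seed integer seed covering shuffling, dropout and parameter
#'   initialization in [mscan_fit()].
#' @param optimizer only `"adam"` is implemented.
#' @param pos_weight optional weight on positive-class samples in the
#'   loss (default 1 = plain BCE).
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100L, learning_rate = 5e-4,
                         batch_size = 10L, dropout = 0.2, seed = 1L,
                         optimizer = "adam", pos_weight = 1) {
  if (learning_rate < 0) stopf("learning_rate must be >= 0")
  if (!is_count(batch_size) || batch_size < 1L)
    stopf("batch_size must be >= 1")
  if (!is_count(epochs) || epochs < 1L) stopf("epochs must be >= 1")
  if (!identical(optimizer, "adam"))
    stopf("unsupported optimizer '%s'", optimizer)
  structure(list(epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), dropout = dropout,
                 seed = as.integer(seed), optimizer = optimizer,
                 pos_weight = pos_weight),
            class = "train_config")
}

#' Train an encoder on pre-embedded inputs
#'
#' Minimizes (optionally weighted) binary cross-entropy by mini-batch
#' Adam.  Per-epoch shuffling and all dropout draws run under the
#' configuration seed, so training is bit-reproducible on one machine.
#'
#' @param net an `mscan_net` from [build_variant()].
#' @param inputs list of scale bundles, one per sample: each a list of
#'   `m_s x d_embed` matrices ordered as `scale_order` (unused scales
#'   may be `NULL`).
#' @param labels 0/1 vector, both classes present.
#' @param tc a [train_config()].
#' @return `list(net, history)` where `history$loss` holds the mean
#'   training loss per epoch.
#' @export
train_model <- function(net, inputs, labels, tc = train_config()) {
  n <- length(inputs)
  if (n == 0L) stopf("empty training set")
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stopf("training requires both classes to be present")
  config <- net$config
  config$dropout <- tc$dropout
  params <- net$params
  m_by_scale <- lapply(inputs[[1L]], function(M)
    if (is.null(M)) NULL else nrow(M))
  leaves <- leaf_list(params)
  mstate <- lapply(leaves, function(x) x * 0)
  vstate <- lapply(leaves, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  t_step <- 0L
  losses <- numeric(tc$epochs)
  withr::with_seed(tc$seed, {
    for (ep in seq_len(tc$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      starts <- seq(1L, n, by = tc$batch_size)
      for (st in starts) {
        batch <- ord[st:min(st + tc$batch_size - 1L, n)]
        gacc <- NULL
        for (idx in batch) {
          masks <- make_masks(config, m_by_scale)
          fp <- forward_prob(inputs[[idx]], params, config,
                             masks = masks, keep_cache = TRUE)
          y <- labels[[idx]]
          p <- min(max(fp$prob, 1e-12), 1 - 1e-12)
          w <- if (y == 1L) tc$pos_weight else 1
          ep_loss <- ep_loss - w * (y * log(p) + (1 - y) * log(1 - p))
          dlogit <- w * (fp$prob - y)
          gs <- leaf_list(backward_sample(fp, inputs[[idx]], params,
                                          config, masks, dlogit))
          gacc <- if (is.null(gacc)) gs
                  else Map(`+`, gacc, gs)
        }
        t_step <- t_step + 1L
        scale <- 1 / length(batch)
        lr_t <- tc$learning_rate * sqrt(1 - b2^t_step) / (1 - b1^t_step)
        pl <- leaf_list(params)
        for (i in seq_along(pl)) {
          gi <- gacc[[i]] * scale
          mstate[[i]] <- b1 * mstate[[i]] + (1 - b1) * gi
          vstate[[i]] <- b2 * vstate[[i]] + (1 - b2) * gi^2
          pl[[i]] <- pl[[i]] - lr_t * mstate[[i]] /
            (sqrt(vstate[[i]]) + eps)
        }
        params <- set_leaves(params, pl)
      }
      losses[[ep]] <- ep_loss / n
      if (!is.finite(losses[[ep]]))
        stopf("non-finite training loss at epoch %d", ep)
    }
  })
  net$params <- params
  list(net = net, history = list(loss = losses))
}

## Build per-sample scale bundles (token-embedding matrices) from raw
## 41-nt windows.
prepare_inputs <- function(sequences, config, table,
                           oov = c("zero", "error")) {
  oov <- match.arg(oov)
  scales <- variant_scales(config$variant)
  lapply(sequences, function(s) {
    bundle <- vector("list", 3L)
    for (sc in scales) {
      win <- scale_window(s, config$scale_order[[sc]])
      bundle[[sc]] <- embed_tokens(tokenize(win), table, oov = oov)
    }
    bundle
  })
}

#' Fit the full pipeline on a labelled dataset
#'
#' Tokenizes the training windows into 3-mers, trains CBOW embeddings
#' on that corpus only (no information from later test data), builds
#' the requested encoder variant, and optimizes it with mini-batch
#' Adam.  The returned model carries everything needed for prediction:
#' configuration, vocabulary, embedding table and encoder parameters.
#'
#' @param dataset a [methyl_dataset()] with both classes present.
#' @param config an [model_config()].
#' @param tc a [train_config()]; its seed also seeds the parameter
#'   initialization and, by default, the CBOW trainer.
#' @param embed_window,embed_epochs,embed_seed CBOW training
#'   parameters (see [train_cbow()]); `embed_seed` defaults to the
#'   training seed.
#' @param oov out-of-vocabulary policy at prediction time
#'   (`"zero"` maps unseen 3-mers to the zero vector).
#' @return An object of class `mscan_model`.
#' @seealso [predict.mscan_model()], [evaluate_model()]
#' @export
mscan_fit <- function(dataset, config = model_config(),
                      tc = train_config(), embed_window = 5L,
                      embed_epochs = 50L, embed_seed = tc$seed,
                      oov = "zero") {
  seqs <- dataset$samples$sequence
  corpus <- lapply(seqs, tokenize)
  cb <- train_cbow(corpus, d_embed = config$d_embed,
                   window = embed_window, epochs = embed_epochs,
                   seed = embed_seed)
  inputs <- prepare_inputs(seqs, config, cb$table, oov = oov)
  net <- build_variant(config$variant, config, seed = tc$seed)
  res <- train_model(net, inputs, dataset$samples$label, tc)
  structure(list(config = res$net$config, train_config = tc,
                 vocab = cb$vocab, embedding = cb$table,
                 params = res$net$params, history = res$history,
                 oov = oov),
            class = "mscan_model")
}

#' @export
print.mscan_model <- function(x, ...) {
  cat(sprintf("<mscan_model %s: %d parameters, trained %d epochs (final loss %.4f)>\n",
              x$config$variant, count_parameters(x),
              length(x$history$loss),
              utils::tail(x$history$loss, 1L)))
  invisible(x)
}

#' Predict site probabilities
#'
#' @param object an `mscan_model` from [mscan_fit()].
#' @param newdata a [methyl_dataset()] or a character vector of 41-nt
#'   windows.
#' @param ... unused.
#' @return Numeric vector of probabilities in `(0, 1)`; evaluation-mode
#'   forward passes are deterministic.
#' @export
predict.mscan_model <- function(object, newdata, ...) {
  seqs <- if (inherits(newdata, "methyl_dataset"))
    newdata$samples$sequence else as.character(newdata)
  cfg <- object$config
  cfg$dropout <- 0
  inputs <- prepare_inputs(seqs, cfg, object$embedding, oov = object$oov)
  vapply(inputs, function(X)
    forward_prob(X, object$params, cfg), numeric(1))
}

#' Exhaustive hyperparameter grid search
#'
#' Evaluates the full Cartesian product of the candidate lists by
#' stratified k-fold cross-validation, scoring each cell by mean
#' validation AUPRC.  Ties are broken by higher mean AUROC, then by
#' first-listed order.
#'
#' @param space named list of candidate vectors over [train_config()]
#'   fields (`epochs`, `learning_rate`, `batch_size`, `dropout`).
#' @param dataset a [methyl_dataset()].
#' @param k folds (default 5).
#' @param seed seed for the fold split and all training runs.
#' @param config an [model_config()].
#' @param base_tc baseline [train_config()] supplying fields not in
#'   `space`.
#' @param embed_epochs CBOW epochs used in every cell.
#' @return `list(best = train_config, table = data.frame)` where the
#'   table holds one row per cell with its mean AUPRC and AUROC.
#' @export
grid_search <- function(space, dataset, k = 5L, seed = 1L,
                        config = model_config(),
                        base_tc = train_config(),
                        embed_epochs = 10L) {
  if (length(space) == 0L) stopf("empty search space")
  if (any(vapply(space, length, 0L) == 0L))
    stopf("empty candidate list in search space")
  bad <- setdiff(names(space), c("epochs", "learning_rate", "batch_size",
                                 "dropout"))
  if (length(bad) > 0L) stopf("unknown hyperparameter '%s'", bad[[1L]])
  grid <- expand.grid(space, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  folds <- kfold_split(dataset, k, seed = seed)
  auprc_m <- auroc_m <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    tc <- base_tc
    for (nm in names(space)) tc[[nm]] <- grid[[nm]][[gi]]
    tc <- do.call(train_config, tc[c("epochs", "learning_rate",
                                     "batch_size", "dropout", "seed",
                                     "optimizer", "pos_weight")])
    pr <- ro <- numeric(length(folds))
    for (fi in seq_along(folds)) {
      tr <- dataset_subset(dataset, folds[[fi]]$train)
      va <- dataset_subset(dataset, folds[[fi]]$validation)
      fit <- mscan_fit(tr, config = config, tc = tc,
                       embed_epochs = embed_epochs)
      probs <- predict(fit, va)
      pr[[fi]] <- auprc(va$samples$label, probs)
      ro[[fi]] <- auroc(va$samples$label, probs)
    }
    auprc_m[[gi]] <- mean(pr)
    auroc_m[[gi]] <- mean(ro)
  }
  tab <- cbind(grid, mean_auprc = auprc_m, mean_auroc = auroc_m)
  best_i <- order(-auprc_m, -auroc_m, seq_len(nrow(grid)))[[1L]]
  best <- base_tc
  for (nm in names(space)) best[[nm]] <- grid[[nm]][[best_i]]
  best <- do.call(train_config, best[c("epochs", "learning_rate",
                                       "batch_size", "dropout", "seed",
                                       "optimizer", "pos_weight")])
  list(best = best, table = tab)
}
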