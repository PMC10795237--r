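# Model persistence: one JSON archive holding the configuration, the
# embedding table and all named parameter tensors (schema version 1).
# JSON keeps checkpoints plain-text and diffable; numeric precision is
# full double precision.

serialize_array <- function(x) {
  if (is.matrix(x))
    list(dim = dim(x), data = as.numeric(x),
         rownames = rownames(x) %||% NULL)
  else list(dim = length(x), data = as.numeric(x))
}

deserialize_array <- function(a) {
  if (length(a$dim) == 2L) {
    M <- matrix(a$data, a$dim[[1L]], a$dim[[2L]])
    if (!is.null(a$rownames)) rownames(M) <- a$rownames
    M
  } else as.numeric(a$data)
}

ser_tree <- function(p) {
  if (is.list(p)) lapply(p, function(x) if (is.null(x)) NULL else ser_tree(x))
  else serialize_array(p)
}

deser_tree <- function(p) {
  if (!is.null(p$data) && !is.null(p$dim)) deserialize_array(p)
  else lapply(p, function(x) if (is.null(x) || length(x) == 0L) NULL
              else deser_tree(x))
}

#' Save a fitted model to a JSON checkpoint
#'
#' @param model an `mscan_model` from [mscan_fit()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  obj <- list(
    schema = 1L,
    config = unclass(model$config),
    train_config = unclass(model$train_config),
    oov = model$oov,
    vocab = list(kmer_to_index = as.list(model$vocab$kmer_to_index),
                 k = model$vocab$k),
    embedding = list(vectors = serialize_array(model$embedding$vectors),
                     meta = model$embedding$meta),
    params = ser_tree(model$params),
    history = model$history)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a model checkpoint written by [save_model()]
#'
#' @param path checkpoint file.
#' @return An `mscan_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyMatrix = FALSE,
                             simplifyDataFrame = FALSE)
  if (!identical(as.integer(obj$schema), 1L))
    stopf("unsupported checkpoint schema '%s'", obj$schema)
  cfg <- obj$config
  config <- model_config(cfg$d_model, cfg$heads, cfg$d_ff, cfg$layers,
                         cfg$dropout, unlist(cfg$scale_order),
                         cfg$d_embed, cfg$variant)
  tc <- obj$train_config
  train_cfg <- train_config(tc$epochs, tc$learning_rate, tc$batch_size,
                            tc$dropout, tc$seed, tc$optimizer,
                            tc$pos_weight)
  k2i <- unlist(obj$vocab$kmer_to_index)
  vocab <- structure(list(kmer_to_index = k2i,
                          k = as.integer(obj$vocab$k)),
                     class = "kmer_vocab")
  emb <- obj$embedding
  vec <- list(dim = unlist(emb$vectors$dim),
              data = unlist(emb$vectors$data),
              rownames = unlist(emb$vectors$rownames))
  table <- structure(list(vectors = deserialize_array(vec),
                          meta = emb$meta),
                     class = "kmer_embedding")
  params <- deser_tree(obj$params)
  structure(list(config = config, train_config = train_cfg,
                 vocab = vocab, embedding = table, params = params,
                 history = lapply(obj$history, unlist),
                 oov = obj$oov %||% "zero"),
            class = "mscan_model")
}
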