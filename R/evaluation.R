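# Threshold metrics, ranking metrics (AUROC / AUPRC), replicated
# t-test comparison, and the cross-modification validation matrix.

#' Confusion counts at a probability threshold
#'
#' A sample is called positive when its probability is greater than or
#' equal to the threshold (ties predict positive).
#'
#' @param labels 0/1 vector.
#' @param probabilities vector in `[0, 1]`, same length.
#' @param threshold decision threshold (default 0.5).
#' @return Named list with integer `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) != length(probabilities))
    stopf("labels and probabilities differ in length (%d vs %d)",
          length(labels), length(probabilities))
  if (any(probabilities < 0 | probabilities > 1))
    stopf("probabilities must lie in [0, 1]")
  pred <- as.integer(probabilities >= threshold)
  y <- as.integer(labels)
  list(TP = sum(pred == 1L & y == 1L), TN = sum(pred == 0L & y == 0L),
       FP = sum(pred == 1L & y == 0L), FN = sum(pred == 0L & y == 1L))
}

#' Threshold classification metrics from confusion counts
#'
#' Sensitivity (recall) = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/total, precision = TP/(TP+FP),
#' F1 = 2 * precision * recall / (precision + recall), and the Matthews
#' correlation coefficient
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' Degenerate denominators return defined sentinels: precision 0 when
#' no positive calls, F1 0 when precision + recall is 0, MCC 0 when any
#' marginal is empty; sensitivity/specificity are 0 when their class is
#' absent.
#'
#' @param c confusion counts from [confusion()].
#' @return Named list: `Sen`, `Spe`, `Acc`, `Pre`, `F1`, `MCC`.
#' @export
threshold_metrics <- function(c) {
  TP <- c$TP; TN <- c$TN; FP <- c$FP; FN <- c$FN
  total <- TP + TN + FP + FN
  if (total == 0L) stopf("no evaluated samples")
  sen <- if (TP + FN > 0) TP / (TP + FN) else 0
  spe <- if (TN + FP > 0) TN / (TN + FP) else 0
  acc <- (TP + TN) / total
  pre <- if (TP + FP > 0) TP / (TP + FP) else 0
  f1 <- if (pre + sen > 0) 2 * pre * sen / (pre + sen) else 0
  denom <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (denom > 0)
    (TP * TN - FP * FN) / sqrt(denom) else 0
  list(Sen = sen, Spe = spe, Acc = acc, Pre = pre, F1 = f1, MCC = mcc)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney statistic: the probability that a
#' random positive scores above a random negative, counting ties as
#' one half.  Invariant under any strictly monotone transform of the
#' scores.
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores numeric vector.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  y <- as.integer(labels)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stopf("AUROC needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' The step-wise (rank-walk) average-precision convention: walking down
#' the ranking, precision is accumulated at every increase in recall,
#' with tied scores treated as one group.  Trapezoidal interpolation is
#' deliberately not used, as it overestimates PR area.
#'
#' @param labels 0/1 vector with at least one positive.
#' @param scores numeric vector.
#' @return AUPRC in `(0, 1]`.  A constant score vector with positive
#'   fraction `pi` gives `pi`.
#' @export
auprc <- function(labels, scores) {
  y <- as.integer(labels)
  n_pos <- sum(y == 1L)
  if (n_pos == 0L) stopf("AUPRC needs at least one positive")
  o <- order(scores, decreasing = TRUE)
  y <- y[o]; s <- scores[o]
  grp_last <- cumsum(rle(s)$lengths)   # last index of each tie group
  tp <- cumsum(y)[grp_last]
  fp <- grp_last - tp
  prec <- tp / (tp + fp)
  recall <- tp / n_pos
  d_recall <- diff(c(0, recall))
  sum(prec * d_recall)
}

#' Two-sample Student's t-test on replicated metric values
#'
#' Two-sided, pooled-variance by default (classic Student), with the
#' Welch unequal-variance form available.  Degenerate data (zero
#' pooled variance) returns t = 0, p = 1 when the means are equal, and
#' infinite t with p = 0 otherwise.
#'
#' @param a,b numeric vectors of replicate metric values (length >= 2).
#' @param welch use the Welch form (default `FALSE`).
#' @return `list(statistic, p.value, df)`.
#' @export
ttest_compare <- function(a, b, welch = FALSE) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stopf("each sample needs >= 2 replicates")
  m1 <- mean(a); m2 <- mean(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
      return(list(statistic = t, p.value = as.numeric(m1 == m2),
                  df = NA_real_))
    }
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    df <- n1 + n2 - 2
    if (sp2 == 0) {
      t <- if (m1 == m2) 0 else sign(m1 - m2) * Inf
      return(list(statistic = t, p.value = as.numeric(m1 == m2),
                  df = df))
    }
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  list(statistic = t, p.value = 2 * stats::pt(-abs(t), df), df = df)
}

#' Full metrics report for scored samples
#'
#' @param labels 0/1 vector.
#' @param probabilities vector in `[0, 1]`.
#' @param threshold decision threshold for the confusion-based metrics.
#' @return Named list: `Sen`, `Spe`, `Acc`, `Pre`, `F1`, `MCC`,
#'   `AUROC`, `AUPRC`.
#' @export
evaluate_probs <- function(labels, probabilities, threshold = 0.5) {
  tm <- threshold_metrics(confusion(labels, probabilities, threshold))
  c(tm, list(AUROC = auroc(labels, probabilities),
             AUPRC = auprc(labels, probabilities)))
}

#' Score a fitted model on a labelled dataset
#'
#' @param model an `mscan_model`.
#' @param dataset a [methyl_dataset()].
#' @param threshold decision threshold (default 0.5).
#' @return A metrics report as from [evaluate_probs()].
#' @export
evaluate_model <- function(model, dataset, threshold = 0.5) {
  evaluate_probs(dataset$samples$label, predict(model, dataset),
                 threshold)
}

#' Cross-modification validation matrix
#'
#' Scores every model against every test set: cell `(test = i,
#' model = j)` is the metrics report of model `j` on test set `i`, so
#' the diagonal holds the matched model/test pairs and off-diagonal
#' cells reveal shared sequence structure between modifications.
#'
#' @param models named list of `mscan_model` objects (names =
#'   modification tags).
#' @param testsets named list of [methyl_dataset()] objects; every test
#'   tag must have a model.
#' @return An object of class `crossmod_matrix`: list with matrices
#'   `AUROC`, `AUPRC`, `Acc` (rows = test tag, columns = model tag) and
#'   `reports`, the full per-cell metric lists.
#' @export
cross_modification_matrix <- function(models, testsets) {
  missing_tags <- setdiff(names(testsets), names(models))
  if (length(missing_tags) > 0L)
    stopf("no model for test tag '%s'", missing_tags[[1L]])
  tags_t <- names(testsets)
  tags_m <- names(models)
  mk <- function() matrix(NA_real_, length(tags_t), length(tags_m),
                          dimnames = list(test = tags_t, model = tags_m))
  out <- list(AUROC = mk(), AUPRC = mk(), Acc = mk(), reports = list())
  for (ti in tags_t) {
    out$reports[[ti]] <- list()
    for (mj in tags_m) {
      rep_ <- evaluate_model(models[[mj]], testsets[[ti]])
      out$AUROC[ti, mj] <- rep_$AUROC
      out$AUPRC[ti, mj] <- rep_$AUPRC
      out$Acc[ti, mj] <- rep_$Acc
      out$reports[[ti]][[mj]] <- rep_
    }
  }
  structure(out, class = "crossmod_matrix")
}

#' @export
print.crossmod_matrix <- function(x, ...) {
  cat("Cross-modification AUROC (rows = test set, cols = model):\n")
  print(round(x$AUROC, 4))
  invisible(x)
}

#' Write a cross-modification matrix as TSV (and optionally a heatmap)
#'
#' @param x a `crossmod_matrix`.
#' @param path TSV output for the AUROC matrix.
#' @param heatmap optional image file (requires the pheatmap package).
#' @return `path`, invisibly.
#' @export
write_crossmod <- function(x, path, heatmap = NULL) {
  utils::write.table(x$AUROC, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  if (!is.null(heatmap)) {
    if (!requireNamespace("pheatmap", quietly = TRUE))
      stopf("heatmap output requires the pheatmap package")
    grDevices::png(heatmap, width = 800, height = 700)
    pheatmap::pheatmap(x$AUROC, cluster_rows = FALSE,
                       cluster_cols = FALSE, display_numbers = TRUE,
                       main = "Cross-modification AUROC")
    grDevices::dev.off()
  }
  invisible(path)
}

#' Replicated retraining for reliability comparison
#'
#' Retrains the pipeline `R` times with distinct seeds on the same
#' training data and scores each replicate on the same test data,
#' emulating a replicated-experiment design whose replicate metric
#' vectors feed [ttest_compare()].
#'
#' @param train_ds,test_ds training and test [methyl_dataset()]s.
#' @param config an [model_config()].
#' @param tc a [train_config()]; replicate `r` runs with seed
#'   `tc$seed + r - 1`.
#' @param R number of replicates.
#' @param metric `"AUPRC"` (default) or `"AUROC"`.
#' @param embed_epochs CBOW epochs per replicate.
#' @return Numeric vector of length `R`.
#' @export
replicate_metric <- function(train_ds, test_ds, config = model_config(),
                             tc = train_config(), R = 10L,
                             metric = c("AUPRC", "AUROC"),
                             embed_epochs = 10L) {
  metric <- match.arg(metric)
  vapply(seq_len(R), function(r) {
    tcr <- tc
    tcr$seed <- tc$seed + r - 1L
    fit <- mscan_fit(train_ds, config = config, tc = tcr,
                     embed_epochs = embed_epochs)
    probs <- predict(fit, test_ds)
    if (metric == "AUPRC") auprc(test_ds$samples$label, probs)
    else auroc(test_ds$samples$label, probs)
  }, numeric(1))
}
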