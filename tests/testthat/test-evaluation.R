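# evaluation: confusion, threshold metrics, AUROC/AUPRC, t-test.

test_that("confusion counts with the >= tie rule", {
  cc <- confusion(c(1, 0), c(0.9, 0.1))
  expect_identical(cc, list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))
  ## probabilities equal to the threshold predict positive
  cc <- confusion(c(1, 0, 1), c(0.5, 0.5, 0.5))
  expect_identical(cc, list(TP = 2L, TN = 0L, FP = 1L, FN = 0L))
  expect_error(confusion(c(1, 0), 0.5), "length")
  expect_error(confusion(1, 1.2), "\\[0, 1\\]")
  ## naive loop oracle
  withr::with_seed(61, {
    y <- rbinom(50, 1, 0.4); p <- runif(50)
    cc <- confusion(y, p, 0.3)
    tp <- tn <- fp <- fn <- 0L
    for (i in 1:50) {
      pred <- p[i] >= 0.3
      if (pred && y[i] == 1) tp <- tp + 1L
      if (!pred && y[i] == 0) tn <- tn + 1L
      if (pred && y[i] == 0) fp <- fp + 1L
      if (!pred && y[i] == 1) fn <- fn + 1L
    }
    expect_identical(cc, list(TP = tp, TN = tn, FP = fp, FN = fn))
  })
})

test_that("threshold metrics: closed cases and formula oracle", {
  m <- threshold_metrics(list(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  expect_equal(m$Acc, 0.5)
  expect_equal(m$MCC, 0)
  m <- threshold_metrics(list(TP = 4L, TN = 7L, FP = 0L, FN = 0L))
  expect_equal(unlist(m), c(Sen = 1, Spe = 1, Acc = 1, Pre = 1, F1 = 1,
                            MCC = 1))
  m <- threshold_metrics(list(TP = 3L, TN = 5L, FP = 1L, FN = 1L))
  expect_equal(m$Sen, 0.75)
  expect_equal(m$Spe, 5 / 6, tolerance = 1e-12)
  expect_equal(m$Pre, 0.75)
  expect_equal(m$Acc, 0.8)
  expect_equal(m$F1, 0.75)
  expect_equal(m$MCC, 7 / 12, tolerance = 1e-12)
  ## random tables against direct substitution
  withr::with_seed(62, {
    for (r in 1:200) {
      tb <- as.list(rpois(4, 8) + 1L)
      names(tb) <- c("TP", "TN", "FP", "FN")
      want <- oracle_metrics(tb$TP, tb$TN, tb$FP, tb$FN)
      expect_equal(threshold_metrics(tb), want, tolerance = 1e-12)
    }
  })
})

test_that("degenerate confusion tables return the sentinel values", {
  m <- threshold_metrics(list(TP = 0L, TN = 5L, FP = 0L, FN = 3L))
  expect_equal(m$Pre, 0)    # no positive calls
  expect_equal(m$F1, 0)
  expect_equal(m$MCC, 0)    # empty marginal
  m <- threshold_metrics(list(TP = 0L, TN = 5L, FP = 0L, FN = 0L))
  expect_equal(m$Sen, 0)    # no positives at all
  expect_equal(m$Acc, 1)
})

test_that("MCC is negated by inverting the predictions", {
  withr::with_seed(63, {
    y <- rbinom(60, 1, 0.5)
    p <- runif(60)
    p[p == 0.5] <- 0.51
    m1 <- threshold_metrics(confusion(y, p))
    m2 <- threshold_metrics(confusion(y, 1 - p, threshold = 0.500001))
    expect_equal(m2$MCC, -m1$MCC, tolerance = 1e-12)
    expect_true(abs(m1$MCC) <= 1)
  })
})

test_that("AUROC equals the pairwise Mann-Whitney oracle", {
  expect_equal(auroc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auroc(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  expect_error(auroc(c(1, 1), c(0.1, 0.2)), "both classes")
  withr::with_seed(64, {
    for (r in 1:50) {
      y <- c(1, 0, rbinom(18, 1, 0.5))
      s <- round(runif(20), 2)     # rounded scores force some ties
      expect_equal(auroc(y, s), oracle_auroc(y, s), tolerance = 1e-12)
      expect_equal(auroc(y, s) + auroc(y, -s), 1, tolerance = 1e-12)
      ## invariance under strictly monotone transforms
      expect_equal(auroc(y, s), auroc(y, exp(3 * s) + 2),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUPRC equals the rank-walk oracle", {
  expect_equal(auprc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auprc(c(1, 0, 0, 0), rep(0.3, 4)), 0.25)  # constant -> pi
  expect_error(auprc(c(0, 0), c(0.1, 0.2)), "positive")
  withr::with_seed(65, {
    for (r in 1:50) {
      y <- c(1, rbinom(19, 1, 0.3))
      s <- round(runif(20), 2)
      expect_equal(auprc(y, s), oracle_ap(y, s), tolerance = 1e-12)
    }
  })
})

test_that("Student's t-test comparison behaves and matches stats::t.test", {
  a <- c(0.7, 0.71, 0.72, 0.69)
  same <- ttest_compare(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  withr::with_seed(66, {
    b <- rnorm(20, 5); c_ <- rnorm(20, 0)
    expect_lt(ttest_compare(b, c_)$p.value, 1e-6)
    expect_equal(ttest_compare(b, c_)$p.value,
                 ttest_compare(c_, b)$p.value, tolerance = 1e-15)
    ## pooled variant against R's own implementation
    ref <- stats::t.test(b, c_, var.equal = TRUE)
    got <- ttest_compare(b, c_)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
    refw <- stats::t.test(b, c_)
    gotw <- ttest_compare(b, c_, welch = TRUE)
    expect_equal(gotw$statistic, unname(refw$statistic), tolerance = 1e-12)
    expect_equal(gotw$p.value, refw$p.value, tolerance = 1e-12)
  })
  ## zero variance, equal means -> p = 1 by convention
  expect_equal(ttest_compare(c(1, 1), c(1, 1))$p.value, 1)
  expect_error(ttest_compare(1, c(1, 2)), ">= 2")
})

test_that("cross-modification matrix has the contract shape", {
  ds_a <- tiny_dataset(8L, 8L, seed = 71L)
  ds_b <- tiny_dataset(8L, 8L, seed = 72L)
  cfg <- tiny_config()
  tc <- train_config(epochs = 2L, batch_size = 4L, dropout = 0,
                     seed = 1L)
  fit_a <- mscan_fit(ds_a, config = cfg, tc = tc, embed_epochs = 2L)
  fit_b <- mscan_fit(ds_b, config = cfg, tc = tc, embed_epochs = 2L)
  cm <- cross_modification_matrix(list(A = fit_a, B = fit_b),
                                  list(A = ds_a, B = ds_b))
  expect_identical(dim(cm$AUROC), c(2L, 2L))
  expect_identical(rownames(cm$AUROC), c("A", "B"))
  expect_identical(colnames(cm$AUROC), c("A", "B"))
  expect_equal(cm$AUROC["A", "A"],
               evaluate_model(fit_a, ds_a)$AUROC)
  expect_equal(cm$AUROC["B", "A"],
               auroc(ds_b$samples$label, predict(fit_a, ds_b)))
  expect_error(cross_modification_matrix(list(A = fit_a),
                                         list(A = ds_a, B = ds_b)),
               "no model for test tag 'B'")
  ## TSV export round-trips the AUROC matrix
  f <- tempfile(fileext = ".tsv")
  write_crossmod(cm, f)
  back <- as.matrix(utils::read.delim(f, row.names = 1))
  expect_equal(unname(back), unname(cm$AUROC), tolerance = 1e-6)
})
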