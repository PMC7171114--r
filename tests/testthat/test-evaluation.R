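test_that("confusion counts match a per-element tally", {
  cc <- confusion_counts(c(1, 0, 1, 0), c(1, 0, 1, 0))
  expect_equal(unclass(cc)[c("TP", "FP", "TN", "FN")],
               list(TP = 2L, FP = 0L, TN = 2L, FN = 0L))
  cc2 <- confusion_counts(c(1, 0), c(1, 1))
  expect_equal(cc2$TP, 1L); expect_equal(cc2$FP, 1L)
  expect_equal(cc2$TN, 0L); expect_equal(cc2$FN, 0L)

  set.seed(60)
  y <- rbinom(100, 1, 0.5); p <- rbinom(100, 1, 0.5)
  cc3 <- confusion_counts(y, p)
  tally <- table(factor(y, 0:1), factor(p, 0:1))
  expect_equal(cc3$TP, unname(tally["1", "1"]))
  expect_equal(cc3$FP, unname(tally["0", "1"]))
  expect_equal(cc3$TN, unname(tally["0", "0"]))
  expect_equal(cc3$FN, unname(tally["1", "0"]))
  expect_equal(cc3$TP + cc3$FP + cc3$TN + cc3$FN, 100L)
  expect_error(confusion_counts(c(1, 0), 1), "equal length")
})

test_that("metrics evaluate the four formulas exactly", {
  perfect <- classification_metrics(confusion_counts(rep(c(1, 0), 50),
                                                     rep(c(1, 0), 50)))
  expect_equal(unname(perfect), c(1, 1, 1, 1))

  m <- classification_metrics(
    structure(list(TP = 90L, FP = 10L, TN = 90L, FN = 10L),
              class = "confusion_counts")
  )
  expect_equal(m[["accuracy"]], 0.9)
  expect_equal(m[["sensitivity"]], 0.9)
  expect_equal(m[["precision"]], 0.9)
  expect_equal(m[["mcc"]], 0.8)

  # random counts against direct formula evaluation
  set.seed(61)
  for (rep in 1:20) {
    v <- as.list(rpois(4, 20) + 1L)
    names(v) <- c("TP", "FP", "TN", "FN")
    m <- classification_metrics(structure(v, class = "confusion_counts"))
    expect_equal(m[["accuracy"]], (v$TP + v$TN) / Reduce(`+`, v), tolerance = 1e-12)
    expect_equal(m[["sensitivity"]], v$TP / (v$TP + v$FN), tolerance = 1e-12)
    expect_equal(m[["precision"]], v$TP / (v$TP + v$FP), tolerance = 1e-12)
    expect_equal(m[["mcc"]],
                 (v$TP * v$TN - v$FP * v$FN) /
                   sqrt((v$TP + v$FP) * (v$TP + v$FN) * (v$TN + v$FP) * (v$TN + v$FN)),
                 tolerance = 1e-12)
  }
})

test_that("truth-independent predictions give near-zero MCC", {
  set.seed(62)
  y <- rep(c(0, 1), 500)
  p <- rbinom(1000, 1, 0.5)
  m <- classification_metrics(confusion_counts(y, p))
  expect_lt(abs(m[["mcc"]]), 0.12)  # within sampling error of 0
})

test_that("undefined metrics are NA, never coerced to zero", {
  m <- classification_metrics(confusion_counts(c(1, 1), c(0, 0)))
  expect_true(is.na(m[["precision"]]))  # TP + FP = 0
  expect_true(is.na(m[["mcc"]]))
  expect_equal(m[["sensitivity"]], 0)
  expect_error(
    classification_metrics(structure(list(TP = 0L, FP = 0L, TN = 0L, FN = 0L),
                                     class = "confusion_counts")),
    "no samples"
  )
})

test_that("AUC equals the exhaustive pairwise concordance count", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(1, 0, 1, 0))$auc, 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.3, 4))$auc, 0.5)
  set.seed(63)
  for (rep in 1:100) {
    n <- sample(5:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    s <- sample(round(runif(n), 2), n)   # rounded scores force ties
    expect_equal(roc_auc(y, s)$auc, auc_bruteforce(y, s), tolerance = 1e-12)
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.4)), "both classes")
})

test_that("AUC and ROC endpoints agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(64)
  y <- rbinom(200, 1, 0.4)
  s <- rnorm(200) + y
  ours <- roc_auc(y, s)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(ours$auc, ref, tolerance = 1e-12)
  expect_equal(ours$roc[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(ours$roc[nrow(ours$roc), ]), c(fpr = 1, tpr = 1),
               ignore_attr = TRUE)
})

test_that("stratified folds partition the samples and balance classes", {
  set.seed(65)
  y <- rep(c(0, 1), c(400, 870))  # 1270 samples
  folds <- make_folds(y, k = 5, seed = 1)
  expect_equal(sort(unique(folds)), 1:5)
  expect_equal(unname(table(folds)), rep(254L, 5), ignore_attr = TRUE)
  for (f in 1:5) {
    expect_equal(sum(y[folds == f] == 1), 174L)  # 870 / 5
  }
  expect_error(make_folds(c(0, 1, 1, 1, 1, 1), k = 5), "class 0 has 1")
  # unstratified folds still partition
  folds2 <- make_folds(y, k = 5, seed = 1, stratified = FALSE)
  expect_equal(unname(table(folds2)), rep(254L, 5), ignore_attr = TRUE)
})

test_that("cross-validation recovers a planted separable signal", {
  blobs <- separable_blobs(n_per_class = 30, seed = 66)
  ds <- list(x = blobs$x, y = blobs$y)
  report <- kfold_cv(ds, rotation_forest_config(K = 1, L = 5, seed = 1),
                     k = 5, seed = 2)
  expect_s3_class(report, "metric_report")
  expect_equal(nrow(report$per_fold), 5L)
  expect_gte(report$mean[["accuracy"]], 0.95)
  # summaries recompute exactly from the fold table
  expect_equal(report$mean[["auc"]], mean(report$per_fold$auc), tolerance = 1e-12)
  expect_equal(report$sd[["accuracy"]], sd(report$per_fold$accuracy),
               tolerance = 1e-12)
  # out-of-fold scores cover every sample exactly once
  expect_equal(sort(report$oof$index), seq_along(ds$y))
})

test_that("metric reports serialize to TSV and JSON", {
  per_fold <- data.frame(fold = 1:3, accuracy = c(0.9, 0.8, 1.0),
                         auc = c(0.95, 0.85, 1.0))
  report <- metric_report(per_fold)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_metric_report(report, tsv)
  back <- utils::read.table(tsv, sep = "\t", header = TRUE)
  expect_equal(nrow(back), 5L)
  expect_equal(back$accuracy[4], 0.9, tolerance = 1e-12)        # Average row
  expect_equal(back$accuracy[5], 0.1, tolerance = 1e-12)        # sd row
  json <- withr::local_tempfile(fileext = ".json")
  write_metric_report(report, json)
  parsed <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(parsed$mean$accuracy, 0.9, tolerance = 1e-12)
})

test_that("grid search reports a consistent, reproducible surface", {
  blobs <- separable_blobs(n_per_class = 15, seed = 67)
  ds <- list(x = blobs$x, y = blobs$y)
  surface <- grid_search(ds, K_values = 1:2, L_values = c(2, 4), k = 3, seed = 5)
  expect_equal(dim(surface$accuracy), c(2L, 2L))
  # cells equal independent kfold_cv calls at the same seeds
  for (i in 1:2) for (j in 1:2) {
    config <- rotation_forest_config(K = i, L = c(2, 4)[j], seed = 5)
    expect_equal(surface$accuracy[i, j],
                 kfold_cv(ds, config, k = 3, seed = 5)$mean[["accuracy"]],
                 tolerance = 1e-12)
  }
  best <- surface$best
  expect_equal(surface$accuracy[as.character(best[["K"]]), paste(best[["L"]])],
               max(surface$accuracy))
  # bit-exact reproducibility
  surface2 <- grid_search(ds, 1:2, c(2, 4), k = 3, seed = 5)
  expect_identical(surface$accuracy, surface2$accuracy)
  # 1x1 grid: best is the only cell; ties break to smallest K then L
  s1 <- grid_search(ds, 2, 3, k = 3, seed = 5)
  expect_equal(s1$best, c(K = 2L, L = 3L))
  expect_error(grid_search(ds, integer(0), 1, k = 3, seed = 1), "empty grid")
})

test_that("model comparison matches the closed-form paired t-test", {
  tab <- rbind(model_a = c(0.91, 0.89, 0.87, 0.80),
               model_b = c(0.88, 0.86, 0.88, 0.75))
  res <- compare_models(tab, method = "paired_t")
  d <- tab[1, ] - tab[2, ]
  t_stat <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * stats::pt(-abs(t_stat), df = length(d) - 1)
  expect_equal(unname(res$statistic), t_stat, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)

  # swapping the models negates t and keeps p
  swapped <- compare_models(tab[2:1, ], method = "paired_t")
  expect_equal(unname(swapped$statistic), -t_stat, tolerance = 1e-12)
  expect_equal(swapped$p_value, res$p_value, tolerance = 1e-12)

  # identical rows: no difference to test
  same <- compare_models(rbind(tab[1, ], tab[1, ]))
  expect_equal(same$p_value, 1)
  # constant nonzero differences are degenerate
  expect_error(compare_models(rbind(tab[1, ], tab[1, ] - 0.1)), "zero-variance")
  # wilcoxon variant runs on the same table
  expect_lt(compare_models(tab, method = "wilcoxon")$p_value, 1)
  expect_error(compare_models(tab[, 1, drop = FALSE]), "at least 2")
})
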