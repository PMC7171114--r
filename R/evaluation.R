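#' Confusion counts
#'
#' Tallies true/false positives and negatives of a binary prediction.
#'
#' @param y_true,y_pred equal-length binary vectors (0/1).
#' @return a `confusion_counts` list with integers `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) stop("labels must be binary 0/1")
  structure(
    list(TP = sum(y_true == 1L & y_pred == 1L),
         FP = sum(y_true == 0L & y_pred == 1L),
         TN = sum(y_true == 0L & y_pred == 0L),
         FN = sum(y_true == 1L & y_pred == 0L)),
    class = "confusion_counts"
  )
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy `(TP+TN)/(TP+TN+FP+FN)`, sensitivity `TP/(TP+FN)`,
#' precision `TP/(TP+FP)` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.  A metric whose
#' denominator is zero is undefined for that sample and reported as `NA`
#' rather than coerced to 0.
#'
#' @param counts a [confusion_counts()].
#' @return named numeric vector `accuracy`, `sensitivity`, `precision`,
#'   `mcc` (entries `NA` where undefined).
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (total == 0L) stop("no samples to evaluate")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  c(
    accuracy = (tp + tn) / total,
    sensitivity = safe_div(tp, tp + fn),
    precision = safe_div(tp, tp + fp),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  )
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score threshold, records (FPR, TPR) points and
#' integrates the curve with the trapezoidal rule.  For tied scores this
#' equals the rank-statistic form `U / (n1 * n0)` counting concordant
#' score pairs with half credit for ties.
#'
#' @param y_true binary labels, both classes present.
#' @param scores numeric scores, higher = more positive.
#' @return list with `auc` and data.frame `roc` (columns `fpr`, `tpr`,
#'   threshold-sorted from (0,0) to (1,1)).
#' @export
roc_auc <- function(y_true, scores) {
  y_true <- as.integer(y_true)
  if (length(y_true) != length(scores)) stop("labels and scores must have equal length")
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  y <- y_true[ord]; s <- scores[ord]
  # cumulative counts at each distinct threshold (ties collapse to one point)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1L)[last_of_tie]
  fp <- cumsum(y == 0L)[last_of_tie]
  roc <- data.frame(fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
  list(auc = auc, roc = roc)
}

#' Stratified k-fold assignment
#'
#' @param y binary labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @param stratified keep per-fold class proportions equal (default); set
#'   `FALSE` for a plain random partition.
#' @return integer vector of fold ids in `1..k`, one per sample.
#' @export
make_folds <- function(y, k = 5L, seed = 1L, stratified = TRUE) {
  y <- as.integer(y)
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  folds <- integer(length(y))
  with_seed(seed, {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        if (length(idx) < k) {
          stop(sprintf("class %d has %d members; need at least k = %d",
                       cls, length(idx), k))
        }
        folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
    } else {
      folds <- sample(rep_len(seq_len(k), length(y)))
    }
  })
  folds
}

#' k-fold cross-validation of the Rotation Forest pipeline
#'
#' Splits the dataset into k stratified folds, trains on k-1 folds and
#' evaluates on the held-out fold, with no index shared between a test fold
#' and its training set.  Per-fold accuracy, sensitivity, precision, MCC and
#' AUC are reported together with their mean and sample (n-1) standard
#' deviation; folds where a metric is undefined are excluded from that
#' metric's averaging with a warning.
#'
#' @param dataset a `dataset_matrix` from [assemble_feature_matrix()], or any
#'   list with matrix `x` and binary `y`.
#' @param config a [rotation_forest_config()]; its seed drives model fitting.
#' @param k number of folds.
#' @param seed seed for the fold assignment (distinct from the model seed).
#' @param stratified see [make_folds()].
#' @return a `metric_report`: list with data.frame `per_fold`, and matrices
#'   `mean` / `sd` summarising each metric.
#' @export
kfold_cv <- function(dataset, config = rotation_forest_config(), k = 5L,
                     seed = 1L, stratified = TRUE) {
  x <- dataset$x; y <- as.integer(dataset$y)
  folds <- make_folds(y, k = k, seed = seed, stratified = stratified)
  per_fold <- vector("list", k)
  oof <- vector("list", k)
  for (f in seq_len(k)) {
    train <- folds != f; test <- !train
    stopifnot(!any(which(test) %in% which(train)))  # leakage audit
    model <- fit_rotation_forest(x[train, , drop = FALSE], y[train], config)
    scores <- predict_proba(model, x[test, , drop = FALSE])
    pred <- as.integer(scores >= 0.5)
    m <- classification_metrics(confusion_counts(y[test], pred))
    auc <- roc_auc(y[test], scores)$auc
    per_fold[[f]] <- data.frame(fold = f, t(m), auc = auc)
    oof[[f]] <- data.frame(index = which(test), fold = f, y = y[test],
                           score = scores)
  }
  report <- metric_report(do.call(rbind, per_fold))
  report$oof <- do.call(rbind, oof)  # out-of-fold scores, e.g. for pooled ROC
  report
}

#' Build a metric report from per-fold results
#'
#' @param per_fold data.frame with a `fold` column and one column per metric.
#' @return a `metric_report` with `per_fold`, `mean` and `sd` (sample sd,
#'   n-1 denominator); `NA` fold metrics are dropped from the summaries with
#'   a warning.
#' @export
metric_report <- function(per_fold) {
  metrics <- setdiff(names(per_fold), "fold")
  if (anyNA(per_fold[metrics])) {
    warning("undefined metric value(s) in some folds; excluded from averaging")
  }
  structure(
    list(
      per_fold = per_fold,
      mean = vapply(per_fold[metrics], mean, numeric(1), na.rm = TRUE),
      sd = vapply(per_fold[metrics], stats::sd, numeric(1), na.rm = TRUE)
    ),
    class = "metric_report"
  )
}

#' @export
print.metric_report <- function(x, ...) {
  cat("Cross-validation over", nrow(x$per_fold), "folds:\n")
  summary <- rbind(Average = x$mean, `Standard deviation` = x$sd)
  print(round(summary, 4))
  invisible(x)
}

#' Write / read a metric report
#'
#' TSV layout mirrors the per-fold table followed by `Average` and
#' `Standard deviation` rows; `write_metric_report` also accepts `.json`.
#'
#' @param report a `metric_report`.
#' @param path output path (`.tsv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(
      list(per_fold = report$per_fold, mean = as.list(report$mean),
           sd = as.list(report$sd)),
      path, auto_unbox = TRUE, digits = NA
    )
    return(invisible(path))
  }
  per_fold <- report$per_fold
  per_fold$fold <- as.character(per_fold$fold)
  summary <- data.frame(
    fold = c("Average", "Standard deviation"),
    rbind(report$mean, report$sd)
  )
  names(summary) <- names(per_fold)
  utils::write.table(rbind(per_fold, summary), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write ROC points as a two-column TSV
#'
#' @param roc data.frame with `fpr` and `tpr` columns (from [roc_auc()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roc_points <- function(roc, path) {
  utils::write.table(roc[, c("fpr", "tpr")], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Grid search over Rotation Forest hyperparameters
#'
#' Evaluates cross-validated mean accuracy for every (K, L) combination and
#' reports the full accuracy surface with the best cell; ties resolve to the
#' smallest K, then the smallest L.  Every cell uses the same fold assignment
#' and model seed, so surfaces are reproducible and cells are comparable.
#'
#' @param dataset as in [kfold_cv()].
#' @param K_values,L_values integer vectors of candidate values.
#' @param k folds per evaluation.
#' @param seed seed shared by fold assignment and model fitting.
#' @param bootstrap_fraction passed to each configuration.
#' @return a `grid_search_surface`: list with `K_values`, `L_values`,
#'   `accuracy` matrix (rows = K, columns = L) and `best` (named vector).
#' @export
grid_search <- function(dataset, K_values, L_values, k = 5L, seed = 1L,
                        bootstrap_fraction = 0.75) {
  if (!length(K_values) || !length(L_values)) stop("empty grid")
  acc <- matrix(NA_real_, length(K_values), length(L_values),
                dimnames = list(K = K_values, L = L_values))
  for (i in seq_along(K_values)) {
    for (j in seq_along(L_values)) {
      config <- rotation_forest_config(K = K_values[i], L = L_values[j],
                                       bootstrap_fraction = bootstrap_fraction,
                                       seed = seed)
      acc[i, j] <- kfold_cv(dataset, config, k = k, seed = seed)$mean[["accuracy"]]
    }
  }
  best_flat <- which(acc == max(acc), arr.ind = TRUE)
  best_flat <- best_flat[order(best_flat[, 1], best_flat[, 2]), , drop = FALSE][1, ]
  structure(
    list(K_values = as.integer(K_values), L_values = as.integer(L_values),
         accuracy = acc,
         best = c(K = as.integer(K_values[best_flat[1]]),
                  L = as.integer(L_values[best_flat[2]]))),
    class = "grid_search_surface"
  )
}

#' @export
print.grid_search_surface <- function(x, ...) {
  cat(sprintf("Grid search: best accuracy %.4f at K = %d, L = %d\n",
              max(x$accuracy), x$best[["K"]], x$best[["L"]]))
  invisible(x)
}

#' Paired comparison of a model against competitors
#'
#' Tests whether the first row of a models x datasets performance table
#' differs from the pooled competitor rows: for each dataset the difference
#' between model 1 and the competitor mean is formed, and the paired
#' differences are tested two-sided with a paired t-test (default) or a
#' Wilcoxon signed-rank test.
#'
#' @param metric_table numeric matrix, rows = models (first row = the model
#'   of interest), columns = datasets; at least 2 of each.
#' @param method `"paired_t"` or `"wilcoxon"`.
#' @return list with `p_value`, `statistic` and `differences`.
#' @export
compare_models <- function(metric_table, method = c("paired_t", "wilcoxon")) {
  method <- match.arg(method)
  metric_table <- as.matrix(metric_table)
  if (nrow(metric_table) < 2L || ncol(metric_table) < 2L) {
    stop("need at least 2 models and 2 datasets")
  }
  competitors <- colMeans(metric_table[-1, , drop = FALSE])
  diffs <- metric_table[1, ] - competitors
  if (all(diffs == 0)) {
    # no difference on any dataset: nothing to test
    return(list(p_value = 1, statistic = 0, differences = diffs))
  }
  if (stats::sd(diffs) == 0) {
    stop("zero-variance paired differences; the test statistic is undefined")
  }
  if (method == "paired_t") {
    ht <- stats::t.test(diffs)
  } else {
    ht <- stats::wilcox.test(diffs, exact = TRUE)
  }
  list(p_value = unname(ht$p.value), statistic = unname(ht$statistic),
       differences = diffs)
}
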