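#' Rotation Forest configuration
#'
#' @param K number of disjoint feature subsets per tree; each subset gets its
#'   own PCA rotation block.  Must not exceed the feature count.
#' @param L number of trees in the ensemble.
#' @param bootstrap_fraction fraction of the selected classes' rows drawn
#'   (without replacement) before fitting each subset's PCA.
#' @param seed integer master seed; all per-tree randomness derives from it.
#' @return a `rotation_forest_config` list.
#' @export
rotation_forest_config <- function(K = 21L, L = 42L, bootstrap_fraction = 0.75,
                                   seed = 1L) {
  stopifnot(K >= 1L, L >= 1L, bootstrap_fraction > 0, bootstrap_fraction <= 1)
  structure(
    list(K = as.integer(K), L = as.integer(L),
         bootstrap_fraction = bootstrap_fraction, seed = as.integer(seed)),
    class = "rotation_forest_config"
  )
}

# Fix eigenvector signs so each component's largest-magnitude entry is
# positive: eigen() signs are arbitrary and this makes rotations reproducible.
fix_signs <- function(v) {
  flip <- apply(v, 2, function(col) col[which.max(abs(col))] < 0)
  v[, flip] <- -v[, flip, drop = FALSE]
  v
}

#' Build one rearranged rotation for a tree
#'
#' The rotation construction at the heart of Rotation Forest: the d features
#' are split into K disjoint near-equal subsets by a shuffled round-robin;
#' for each subset a random nonempty subset of classes is selected, a
#' bootstrap sample of `bootstrap_fraction` of those classes' rows is drawn,
#' and PCA is fit on the subset's columns of that sample.  All principal
#' axes (including near-zero-variance ones) form one diagonal block of the
#' sparse rotation matrix; rearranging block rows back to the original
#' feature order gives the rotation the tree sees.  Every block is
#' orthonormal, so the full rotation preserves Euclidean norms.
#'
#' @param x numeric n x d feature matrix (n >= 2).
#' @param y class labels, length n.
#' @param K number of feature subsets (K <= d).
#' @param bootstrap_fraction fraction of rows bootstrapped per subset.
#' @return a `rotation` object: list with `subsets` (feature-index vectors)
#'   and `blocks` (orthonormal matrices, one per subset); use
#'   [rotation_matrix()] for the explicit d x d matrix and
#'   [apply_rotation()] to rotate data.  Randomness comes from the current
#'   RNG state; [fit_rotation_forest()] seeds one substream per tree.
#' @export
build_rotation <- function(x, y, K, bootstrap_fraction = 0.75) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < 2L) stop("need at least 2 rows to build a rotation")
  if (K > d) stop(sprintf("K = %d exceeds the number of features d = %d", K, d))
  classes <- unique(y)
  # shuffled round-robin: subset sizes differ by at most one
  assignment <- rep_len(seq_len(K), d)[sample.int(d)]
  subsets <- split(seq_len(d), assignment)
  blocks <- lapply(subsets, function(cols) {
    dk <- length(cols)
    # class subset drawn uniformly among the 2^c - 1 nonempty subsets,
    # then a 75% (by default) row bootstrap of those classes' rows
    n_cls <- length(classes)
    pick <- sample.int(2L^n_cls - 1L, 1L)
    chosen <- classes[bitwAnd(pick, bitwShiftL(1L, seq_len(n_cls) - 1L)) > 0L]
    rows <- which(y %in% chosen)
    n_boot <- max(2L, round(bootstrap_fraction * length(rows)))
    rows <- rows[sample.int(length(rows), min(n_boot, length(rows)))]
    xs <- x[rows, cols, drop = FALSE]
    cv <- stats::cov(xs)
    if (!all(is.finite(cv)) || sum(abs(cv)) < .Machine$double.eps * dk * dk) {
      return(diag(dk))  # zero-variance subset: identity block
    }
    fix_signs(eigen(cv, symmetric = TRUE)$vectors)
  })
  structure(list(subsets = unname(subsets), blocks = unname(blocks), d = d),
            class = "rotation")
}

#' Explicit rotation matrix
#'
#' Materializes the d x d rearranged rotation matrix: placing each subset's
#' PCA axes as a diagonal block and permuting block rows back to the original
#' feature order.  Columns are orthonormal.
#'
#' @param rotation a `rotation` from [build_rotation()].
#' @return d x d numeric matrix `R` such that rotated data is `x %*% R`.
#' @export
rotation_matrix <- function(rotation) {
  stopifnot(inherits(rotation, "rotation"))
  d <- rotation$d
  r <- matrix(0, d, d)
  col_at <- 0L
  for (k in seq_along(rotation$subsets)) {
    cols <- rotation$subsets[[k]]
    r[cols, col_at + seq_along(cols)] <- rotation$blocks[[k]]
    col_at <- col_at + length(cols)
  }
  r
}

#' Rotate a data matrix
#'
#' Computes `x %*% rotation_matrix(rotation)` blockwise, which is much
#' cheaper than the dense product when K is large.
#'
#' @param rotation a `rotation`.
#' @param x numeric matrix with `rotation$d` columns.
#' @return rotated matrix, same shape as `x`.
#' @export
apply_rotation <- function(rotation, x) {
  stopifnot(inherits(rotation, "rotation"))
  x <- as.matrix(x)
  if (ncol(x) != rotation$d) {
    stop(sprintf("x has %d columns; rotation expects %d", ncol(x), rotation$d))
  }
  out <- matrix(0, nrow(x), rotation$d)
  col_at <- 0L
  for (k in seq_along(rotation$subsets)) {
    cols <- rotation$subsets[[k]]
    out[, col_at + seq_along(cols)] <- x[, cols, drop = FALSE] %*% rotation$blocks[[k]]
    col_at <- col_at + length(cols)
  }
  out
}

#' Fit a Rotation Forest
#'
#' Trains the ensemble: L independent rotations (each from its own seeded RNG
#' substream) and one unpruned CART decision tree per rotation, fit on the
#' rotated training data.  Trees are grown to purity (no cost-complexity
#' pruning) with Gini impurity, the standard base learner for Rotation
#' Forest, so individual trees are low-bias and the rotations supply the
#' diversity.  Fitting is deterministic for a fixed `config$seed`.
#'
#' @param x numeric n x d matrix of training features.
#' @param y binary labels (0/1, logical, or a 2-level factor), both classes
#'   present.
#' @param config a [rotation_forest_config()].
#' @return a `rotation_forest` model: `config`, `rotations`, `trees`,
#'   `classes`, `d`.
#' @export
fit_rotation_forest <- function(x, y, config = rotation_forest_config()) {
  stopifnot(inherits(config, "rotation_forest_config"))
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 training rows")
  y <- as.integer(as.factor(y)) - 1L  # 0/1 in sorted label order
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (config$K > ncol(x)) {
    stop(sprintf("K = %d exceeds the number of features d = %d", config$K, ncol(x)))
  }
  # one deterministic substream per tree, derived from the master seed
  tree_seeds <- with_seed(config$seed,
                          sample.int(.Machine$integer.max, config$L))
  rotations <- vector("list", config$L)
  trees <- vector("list", config$L)
  for (i in seq_len(config$L)) {
    rotations[[i]] <- with_seed(tree_seeds[i],
                                build_rotation(x, y, config$K, config$bootstrap_fraction))
    xr <- apply_rotation(rotations[[i]], x)
    df <- as.data.frame(xr)
    df$.y <- factor(y, levels = c(0L, 1L))
    tree <- rpart::rpart(
      .y ~ ., data = df, method = "class",
      control = rpart::rpart.control(cp = 0, minsplit = 2L, minbucket = 1L,
                                     xval = 0L, maxsurrogate = 0L,
                                     maxcompete = 0L)
    )
    # drop the fit-time environment and call so serialized models are small
    # and byte-stable; predict() only needs terms with a neutral environment
    tree$call <- quote(rpart::rpart())
    environment(tree$terms) <- baseenv()
    trees[[i]] <- tree
  }
  structure(
    list(config = config, rotations = rotations, trees = trees,
         classes = c(0L, 1L), d = ncol(x)),
    class = "rotation_forest"
  )
}

#' @export
print.rotation_forest <- function(x, ...) {
  cat(sprintf("Rotation Forest: L = %d trees, K = %d subsets, d = %d features\n",
              x$config$L, x$config$K, x$d))
  invisible(x)
}

#' Positive-class scores from a Rotation Forest
#'
#' The ensemble score of a sample is the mean over the L trees of the
#' positive-class leaf proportion at the rotated input (soft voting).  With
#' `vote = "majority"` each tree contributes its hard 0/1 vote instead.
#'
#' @param model a fitted `rotation_forest`.
#' @param x numeric matrix with the training dimensionality.
#' @param vote `"soft"` (mean posterior, default) or `"majority"`.
#' @return numeric vector of scores in `[0, 1]`, one per row of `x`.
#' @export
predict_proba <- function(model, x, vote = c("soft", "majority")) {
  stopifnot(inherits(model, "rotation_forest"))
  vote <- match.arg(vote)
  x <- as.matrix(x)
  if (ncol(x) != model$d) {
    stop(sprintf("x has %d columns; model was trained on %d", ncol(x), model$d))
  }
  scores <- matrix(0, nrow(x), length(model$trees))
  for (i in seq_along(model$trees)) {
    xr <- as.data.frame(apply_rotation(model$rotations[[i]], x))
    p <- stats::predict(model$trees[[i]], newdata = xr, type = "prob")[, "1"]
    scores[, i] <- if (vote == "soft") p else as.numeric(p >= 0.5)
  }
  rowMeans(scores)
}

#' Predicted labels from a Rotation Forest
#'
#' @inheritParams predict_proba
#' @param threshold decision threshold; scores at or above it (ties
#'   included) map to the positive class.
#' @param type `"class"` for 0/1 labels or `"prob"` for scores.
#' @param ... unused.
#' @return integer labels or numeric scores.
#' @export
predict.rotation_forest <- function(object, x, type = c("class", "prob"),
                                    threshold = 0.5, vote = "soft", ...) {
  type <- match.arg(type)
  p <- predict_proba(object, x, vote = vote)
  if (type == "prob") p else as.integer(p >= threshold)
}

#' Save / load a Rotation Forest model
#'
#' Serializes the model (config, rotations, trees and a format version tag)
#' with R's native serialization.  A loaded model reproduces the saved
#' model's predictions exactly.
#'
#' @param model a `rotation_forest`.
#' @param path file path (conventionally `.rds`).
#' @return `save_rotation_forest` returns `path` invisibly;
#'   `load_rotation_forest` returns the model.
#' @export
save_rotation_forest <- function(model, path) {
  stopifnot(inherits(model, "rotation_forest"))
  saveRDS(list(format = "rotadti/rotation_forest", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_rotation_forest
#' @export
load_rotation_forest <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "rotadti/rotation_forest")) {
    stop("not a serialized rotation forest: ", path)
  }
  obj$model
}
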