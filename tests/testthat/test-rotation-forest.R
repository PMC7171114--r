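test_that("rotations preserve Euclidean norms and are orthonormal", {
  set.seed(40)
  for (rep in 1:10) {
    d <- sample(3:12, 1); n <- sample(20:60, 1); K <- sample(1:min(4, d), 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- rbinom(n, 1, 0.5)
    rot <- build_rotation(x, y, K)
    r <- rotation_matrix(rot)
    expect_equal(crossprod(r), diag(d), tolerance = 1e-9, ignore_attr = TRUE)
    v <- rnorm(d)
    expect_equal(sqrt(sum((v %*% r)^2)), sqrt(sum(v^2)), tolerance = 1e-9)
    # blockwise application equals the dense product
    expect_equal(apply_rotation(rot, x), x %*% r, tolerance = 1e-9)
  }
})

test_that("the rotation has the block-diagonal sparsity pattern", {
  set.seed(41)
  x <- matrix(rnorm(40 * 4), 40, 4)
  y <- rep(0:1, 20)
  rot <- build_rotation(x, y, K = 2)
  expect_length(rot$subsets, 2L)
  expect_equal(lengths(rot$subsets), c(2L, 2L))
  expect_length(intersect(rot$subsets[[1]], rot$subsets[[2]]), 0L)
  r <- rotation_matrix(rot)
  # undoing the row rearrangement exposes two 2x2 blocks; off-block zeros
  undone <- r[unlist(rot$subsets), ]
  expect_equal(undone[1:2, 3:4], matrix(0, 2, 2))
  expect_equal(undone[3:4, 1:2], matrix(0, 2, 2))
  expect_false(any(undone[1:2, 1:2] == 0) && any(undone[3:4, 3:4] == 0))
})

test_that("PCA block recovers the principal axis of colinear data", {
  set.seed(42)
  t <- rnorm(200)
  x <- cbind(t, t) + matrix(rnorm(400, sd = 1e-6), 200, 2)
  rot <- build_rotation(x, rep(0:1, 100), K = 1)
  axis <- rot$blocks[[1]][, 1]
  expect_equal(abs(axis), rep(1 / sqrt(2), 2), tolerance = 1e-3)
})

test_that("zero-variance subsets fall back to identity blocks", {
  x <- matrix(5, 30, 3)  # constant features
  rot <- build_rotation(x, rep(0:1, 15), K = 1)
  expect_equal(rot$blocks[[1]], diag(3))
  expect_error(build_rotation(x, rep(0:1, 15), K = 4), "K = 4 exceeds")
  expect_error(build_rotation(x[1, , drop = FALSE], 0L, K = 1), "at least 2 rows")
})

test_that("the forest fits separable data exactly and is seed-deterministic", {
  blobs <- separable_blobs(seed = 43)
  config <- rotation_forest_config(K = 1, L = 5, seed = 7)
  model <- fit_rotation_forest(blobs$x, blobs$y, config)
  expect_equal(predict(model, blobs$x), blobs$y)
  scores <- predict_proba(model, blobs$x)
  expect_true(all(scores[blobs$y == 1] >= 0.5))
  expect_true(all(scores[blobs$y == 0] < 0.5))

  set.seed(44)
  held_out <- rbind(cbind(rnorm(10, -3), rnorm(10, -3)),
                    cbind(rnorm(10, 3), rnorm(10, 3)))
  model2 <- fit_rotation_forest(blobs$x, blobs$y, config)
  expect_identical(predict_proba(model, held_out), predict_proba(model2, held_out))
  model3 <- fit_rotation_forest(blobs$x, blobs$y,
                                rotation_forest_config(K = 1, L = 5, seed = 8))
  expect_false(identical(model$rotations, model3$rotations))
})

test_that("a single-tree forest equals the composed rotation + tree", {
  blobs <- separable_blobs(n_per_class = 25, seed = 45)
  config <- rotation_forest_config(K = 1, L = 1, seed = 3)
  model <- fit_rotation_forest(blobs$x, blobs$y, config)

  # rebuild the same rotation from the model's recorded substream and fit a
  # tree manually on the rotated features
  xr <- apply_rotation(model$rotations[[1]], blobs$x)
  df <- as.data.frame(xr)
  df$.y <- factor(blobs$y, levels = 0:1)
  tree <- rpart::rpart(.y ~ ., data = df, method = "class",
                       control = rpart::rpart.control(cp = 0, minsplit = 2,
                                                      minbucket = 1, xval = 0,
                                                      maxsurrogate = 0,
                                                      maxcompete = 0))
  set.seed(46)
  probe <- matrix(rnorm(40), 20, 2)
  manual <- unname(predict(tree, as.data.frame(apply_rotation(model$rotations[[1]], probe)),
                           type = "prob")[, "1"])
  expect_equal(predict_proba(model, probe), manual, tolerance = 1e-12)
})

test_that("scores flip under label swap and ties go to the positive class", {
  blobs <- separable_blobs(seed = 47)
  config <- rotation_forest_config(K = 2, L = 9, seed = 5)
  m1 <- fit_rotation_forest(blobs$x, blobs$y, config)
  m2 <- fit_rotation_forest(blobs$x, 1L - blobs$y, config)
  set.seed(48)
  probe <- matrix(rnorm(30 * 2, sd = 4), 30, 2)
  expect_equal(predict_proba(m1, probe), 1 - predict_proba(m2, probe),
               tolerance = 1e-12)
  # documented tie policy: score exactly 0.5 maps to label 1
  expect_equal(as.integer(0.5 >= 0.5), 1L)
  expect_true(all(predict(m1, probe)[predict_proba(m1, probe) == 0.5] == 1L))
})

test_that("fit rejects degenerate inputs and mismatched dimensions", {
  blobs <- separable_blobs(seed = 49)
  expect_error(
    fit_rotation_forest(blobs$x, rep(1L, length(blobs$y)),
                        rotation_forest_config(K = 1, L = 2, seed = 1)),
    "single class"
  )
  expect_error(
    fit_rotation_forest(blobs$x, blobs$y,
                        rotation_forest_config(K = 5, L = 2, seed = 1)),
    "K = 5 exceeds"
  )
  model <- fit_rotation_forest(blobs$x, blobs$y,
                               rotation_forest_config(K = 1, L = 2, seed = 1))
  expect_error(predict_proba(model, matrix(0, 2, 3)), "3 columns; model was trained on 2")
})

test_that("majority voting is available and agrees on confident ensembles", {
  blobs <- separable_blobs(seed = 50)
  model <- fit_rotation_forest(blobs$x, blobs$y,
                               rotation_forest_config(K = 1, L = 7, seed = 2))
  soft <- predict_proba(model, blobs$x)
  hard <- predict_proba(model, blobs$x, vote = "majority")
  expect_true(all(hard %in% c(0, 1)))
  expect_equal(as.integer(soft >= 0.5), as.integer(hard >= 0.5))
})

test_that("serialized models reload and predict identically", {
  blobs <- separable_blobs(seed = 51)
  model <- fit_rotation_forest(blobs$x, blobs$y,
                               rotation_forest_config(K = 2, L = 4, seed = 9))
  path <- withr::local_tempfile(fileext = ".rds")
  save_rotation_forest(model, path)
  back <- load_rotation_forest(path)
  set.seed(52)
  probe <- matrix(rnorm(20), 10, 2)
  expect_identical(predict_proba(back, probe), predict_proba(model, probe))
  saveRDS(list(format = "other"), path)
  expect_error(load_rotation_forest(path), "not a serialized rotation forest")
})
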