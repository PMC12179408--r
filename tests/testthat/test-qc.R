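test_that("a separable table is classified perfectly on the held-out split", {
  d <- separable_table(200, seed = 1)
  m <- train_qc(d, seed = 1)
  expect_equal(m$training_meta$metrics$accuracy, 1)
  expect_equal(m$training_meta$metrics$f1, 1)
})

test_that("standard scaling uses training-split statistics only", {
  d <- separable_table(200, seed = 2)
  m <- train_qc(d, seed = 2)
  idx_train <- setdiff(seq_len(nrow(d)), m$training_meta$test_idx)
  X <- as.matrix(d[idx_train, qc_feature_names()])
  Z <- scale(X, center = m$scaler_mean, scale = m$scaler_sd)
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(apply(Z, 2, sd) - 1) < 1e-9))
  expect_true(all(m$scaler_sd > 0))
})

test_that("training is bit-reproducible under a fixed seed", {
  d <- separable_table(160, seed = 3)
  m1 <- train_qc(d, seed = 5)
  m2 <- train_qc(d, seed = 5)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$training_meta, m2$training_meta)
})

test_that("stored held-out metrics are reproduced exactly by evaluate_qc", {
  d <- separable_table(200, seed = 4)
  m <- train_qc(d, seed = 4)
  again <- evaluate_qc(m, d[m$training_meta$test_idx, ])
  expect_identical(m$training_meta$metrics, again)
})

test_that("classify preserves order, handles empty tables and centroids", {
  d <- separable_table(200, seed = 6)
  m <- train_qc(d, seed = 6)
  empty <- d[0, qc_feature_names()]
  expect_equal(nrow(classify(m, empty)), 0)
  out <- classify(m, d)
  expect_equal(out$area_um2, d$area_um2)
  # centroid of the qualified class must be classified as qualified
  centroid <- as.data.frame(t(colMeans(
    d[d$label == 1, qc_feature_names()])))
  expect_equal(classify(m, centroid)$qualified, 1L)
  centroid0 <- as.data.frame(t(colMeans(
    d[d$label == 0, qc_feature_names()])))
  expect_equal(classify(m, centroid0)$qualified, 0L)
})

test_that("a persisted model reloads to identical predictions", {
  d <- separable_table(200, seed = 7)
  m <- train_qc(d, seed = 7)
  path <- file.path(withr::local_tempdir(), "model.json")
  save_qc_model(m, path)
  m2 <- load_qc_model(path)
  expect_identical(classify(m, d)$qualified, classify(m2, d)$qualified)
  expect_equal(evaluate_qc(m2, d[m$training_meta$test_idx, ]),
               m$training_meta$metrics)
})

test_that("predictions are invariant to affine feature rescaling", {
  d <- separable_table(200, seed = 8)
  m <- train_qc(d, seed = 8)
  d2 <- d
  d2$area_um2 <- d2$area_um2 * 4
  d2$perimeter_um <- d2$perimeter_um * 2 + 10
  m2 <- train_qc(d2, seed = 8)
  expect_identical(classify(m, d)$qualified, classify(m2, d2)$qualified)
})

test_that("evaluation metrics match their closed forms", {
  d <- separable_table(100, seed = 9)
  m <- train_qc(d, seed = 9)
  # force an always-positive classifier via the threshold
  m_allpos <- m
  m_allpos$threshold <- 0
  ev <- evaluate_qc(m_allpos, d)
  expect_equal(ev$precision, 0.5)
  expect_equal(ev$recall, 1.0)
  expect_equal(ev$f1, 2 / 3)
  # and brute-force confusion counts agree with the reported ones
  pred <- classify(m, d)$qualified
  y <- d$label
  ev2 <- evaluate_qc(m, d)
  expect_equal(ev2$tp, sum(pred == 1 & y == 1))
  expect_equal(ev2$fp, sum(pred == 1 & y == 0))
  expect_equal(ev2$tn, sum(pred == 0 & y == 0))
  expect_equal(ev2$fn, sum(pred == 0 & y == 1))
  expect_equal(ev2$accuracy, mean(pred == y))
})

test_that("degenerate training inputs are rejected with clear errors", {
  d <- separable_table(200, seed = 10)
  expect_error(train_qc(d[1:20, ], seed = 1), "at least 50")
  d1 <- d; d1$label <- 1L
  expect_error(train_qc(d1, seed = 1), "both classes")
  d2 <- d; d2$solidity <- 0.98
  expect_error(train_qc(d2, seed = 1), "solidity")
  d3 <- d[, setdiff(names(d), "roundness")]
  expect_error(train_qc(d3, seed = 1), "roundness")
  expect_error(classify(train_qc(d, seed = 1),
                        d[, setdiff(names(d), "circularity")]),
               "circularity")
})

test_that("the synthetic benchmark labels follow ground-truth classes", {
  b <- synth_benchmark(n_cells = 60, seed = 7)
  expect_equal(nrow(b), 60)
  expect_true(all(b$label[b$cell_class == "intact_rod"] == 1))
  expect_true(all(b$label[b$cell_class != "intact_rod"] == 0))
  # benchmark mix is exact
  expect_equal(sum(b$cell_class == "intact_rod"), 42)
})

test_that("qualified fraction tracks a 97 percent rod composition", {
  b <- synth_benchmark(n_cells = 260, seed = 21,
                       class_proportions = c(intact_rod = 0.97,
                                             rounded = 0.02,
                                             fragment = 0.01))
  m <- train_qc(synth_benchmark(n_cells = 300, seed = 22), seed = 22)
  frac <- mean(classify(m, b)$qualified)
  expect_lt(abs(frac - 0.97), 0.03)
})
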