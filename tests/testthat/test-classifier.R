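test_that("class weights are normalized inverse frequencies", {
  # uniform distribution gives unit weights
  expect_equal(unname(compute_class_weights(rep(1 / 6, 6))), rep(1, 6))
  # 3-class toy: (0.5, 0.25, 0.25) -> (2/3, 4/3, 4/3), expected weight 1
  w <- compute_class_weights(c(.5, .25, .25))
  expect_equal(unname(w), c(2 / 3, 4 / 3, 4 / 3))
  expect_equal(sum(c(.5, .25, .25) * w), 1)
  # normalization identity on random distributions
  set.seed(14)
  for (k in 1:25) {
    p <- runif(6) + 0.01
    p <- p / sum(p)
    expect_equal(sum(p * compute_class_weights(p)), 1, tolerance = 1e-9)
  }
  expect_error(compute_class_weights(c(.5, .5, 0)), "zero-frequency")
})

test_that("flip augmentation preserves values and is a seeded involution", {
  set.seed(6)
  tile <- array(runif(8 * 8 * 3), c(8, 8, 3))
  # explicit double horizontal flip restores the tile
  fh <- tile[, 8:1, , drop = FALSE]
  expect_identical(fh[, 8:1, , drop = FALSE], tile)
  # augment_tile: pixel multiset unchanged, seeded decisions reproducible
  set.seed(123)
  a1 <- augment_tile(tile)
  set.seed(123)
  a2 <- augment_tile(tile)
  expect_identical(a1, a2)
  expect_equal(sort(as.vector(a1)), sort(as.vector(tile)))
  # asymmetric marker: flipped position follows index arithmetic
  m <- array(0, c(8, 8, 3))
  m[2, 3, 1] <- 1
  set.seed(42)  # first two runif draws: H flip yes/no, V flip yes/no
  flips <- runif(2) < 0.5
  set.seed(42)
  am <- augment_tile(m)
  i <- if (flips[2]) 8 - 2 + 1 else 2
  j <- if (flips[1]) 8 - 3 + 1 else 3
  expect_equal(am[i, j, 1], 1)
  expect_equal(sum(am), 1)
})

test_that("build_model honors the output contract and seeded initialization", {
  cfg <- model_config(tile_size = 32, backbone = "small_cnn", seed = 9)
  m <- build_model(cfg)
  X <- matrix(runif(3 * 32 * 32 * 3), 3)
  pred <- predict_tiles(m, X)
  expect_equal(dim(pred$probs), c(3, 6))
  expect_equal(rowSums(pred$probs), rep(1, 3), tolerance = 1e-9)
  # same seed twice: identical initial parameters
  m2 <- build_model(cfg)
  expect_identical(m$params, m2$params)
  # different seed differs
  m3 <- build_model(model_config(tile_size = 32, backbone = "small_cnn",
                                 seed = 10))
  expect_false(identical(m$params, m3$params))
  # incompatible input size
  expect_error(build_model(model_config(tile_size = 40,
                                        backbone = "small_cnn")),
               "multiple of 16")
})

test_that("the VGG19-style full profile builds and emits (batch, 6) softmax rows", {
  m <- build_model(model_config(tile_size = 250, backbone = "vgg19_full",
                                seed = 1))
  # 16 conv layers + 5 pools + head
  types <- vapply(m$arch$layers, function(l) l$type, "")
  expect_equal(sum(types == "conv"), 16)
  expect_equal(sum(types == "pool"), 5)
  X <- matrix(runif(250 * 250 * 3), 1)
  p <- predict_tiles(m, X)
  expect_equal(dim(p$probs), c(1, 6))
  expect_equal(sum(p$probs), 1, tolerance = 1e-9)
})

test_that("training overfits a trivially separable six-class set", {
  set.seed(1)
  mk <- function(cls) {
    array(cls / 7 + rnorm(32 * 32 * 3, 0, 0.02), c(32, 32, 3))
  }
  tiles <- list(); y <- integer(0)
  for (cls in 1:6) for (r in 1:10) {
    tiles[[length(tiles) + 1L]] <- mk(cls)
    y <- c(y, cls)
  }
  X <- tiles_to_matrix(tiles)
  cfg <- model_config(tile_size = 32, backbone = "small_cnn", epochs = 30,
                      learning_rate = 2e-3, batch_size = 10, seed = 5)
  fit <- train(build_model(cfg), X, y)
  expect_true(fit$trained)
  # capacity far exceeds the task: perfect training accuracy
  pred <- predict_tiles(fit, X)
  expect_equal(mean(as.integer(pred$labels) == y), 1.0)
  # descent sanity: final loss well below initial
  expect_lt(tail(fit$history$train_loss, 1),
            fit$history$train_loss[1] / 2)
  # inference is a pure function: duplicated tile gives identical rows
  X2 <- X[c(1, 1, 5), ]
  p2 <- predict_tiles(fit, X2)
  expect_identical(p2$probs[1, ], p2$probs[2, ])
})

test_that("uniform class weights reproduce the unweighted loss exactly", {
  set.seed(3)
  X <- matrix(runif(12 * 32 * 32 * 3), 12)
  y <- rep(1:6, 2)
  cfg <- model_config(tile_size = 32, backbone = "small_cnn", epochs = 2,
                      batch_size = 6, seed = 8)
  f1 <- train(build_model(cfg), X, y, weights = rep(1, 6))
  f2 <- train(build_model(cfg), X, y,
              weights = unname(compute_class_weights(rep(1 / 6, 6))))
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("training contract errors are raised", {
  X <- matrix(runif(5 * 32 * 32 * 3), 5)
  cfg <- model_config(tile_size = 32, backbone = "small_cnn", epochs = 1)
  expect_error(train(build_model(cfg), X, c(1, 1, 2, 2, 3)), "missing")
  expect_error(predict_tiles(build_model(cfg), matrix(0, 2, 10)),
               "columns")
})
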