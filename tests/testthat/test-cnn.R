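# The convolutional classifier: architecture, gradients, training
# controls, prediction determinism.

test_that("forward pass yields calibrated softmax output", {
  m <- build_custom_cnn(c(78, 192, 1), seed = 3)
  expect_equal(vapply(m$weights[c(1, 3, 5)], ncol, numeric(1)),
               c(32, 64, 64))          # conv filter counts
  expect_equal(ncol(m$weights[[7]]), 128)
  expect_equal(ncol(m$weights[[9]]), 64)
  expect_equal(ncol(m$weights[[11]]), 8)
  set.seed(1)
  x <- array(rnorm(2 * 78 * 192), c(2, 78, 192, 1))
  p <- predict(m, x)
  expect_equal(dim(p$prob), c(2L, 8L))
  expect_true(all(p$prob >= 0 & p$prob <= 1))
  expect_equal(rowSums(p$prob), c(1, 1), tolerance = 1e-6)
  expect_error(build_custom_cnn(c(4, 4, 1)), "at least|too small|>= 8")
})

test_that("analytic gradients match finite differences in every layer", {
  set.seed(1)
  m <- build_custom_cnn(c(8, 10, 2), n_classes = 3, filters = c(2, 3, 2),
                        dense_units = c(5, 4), dropout = 0, seed = 2)
  n <- 4
  x <- array(rnorm(n * 8 * 10 * 2), c(n, 8, 10, 2))
  y <- c(0L, 1L, 2L, 0L)
  sw <- c(1, 2, 1, 0.5)
  X <- afdriverloc:::.tensors_to_matrix(x, m$spec)
  g <- afdriverloc:::.cnn_grad(m$spec, m$weights, X, y, sw)
  lossf <- function(wl)
    afdriverloc:::.cnn_loss_sum(m$spec, wl, X, y, sw) / n
  set.seed(42)
  for (k in seq_along(g)) {
    nel <- length(m$weights[[k]])
    for (idx in sample(nel, min(3, nel))) {
      # the network computes in single precision: finite differences need
      # a coarse step and tolerance scaled to float round-off
      eps <- 1e-3
      wp <- m$weights; wp[[k]][idx] <- wp[[k]][idx] + eps
      wm <- m$weights; wm[[k]][idx] <- wm[[k]][idx] - eps
      num <- (lossf(wp) - lossf(wm)) / (2 * eps)
      expect_lt(abs(g[[k]][idx] - num) /
                  max(0.05, abs(num) + abs(g[[k]][idx])), 0.05)
    }
  }
})

test_that("training fits separable toy data and is deterministic", {
  set.seed(2)
  n_per <- 4
  x <- array(rnorm(8 * n_per * 256, sd = 0.05), c(8 * n_per, 16, 16, 1))
  y <- integer(8 * n_per)
  for (c in 0:7) for (i in 1:n_per) {
    k <- c * n_per + i
    x[k, 2 * c + 1:2, , 1] <- x[k, 2 * c + 1:2, , 1] + 2  # class = stripe row
    y[k] <- c
  }
  m <- build_custom_cnn(c(16, 16, 1), filters = c(4, 8, 8),
                        dense_units = c(16, 16), dropout = 0.1, seed = 5)
  cfg <- train_config(max_epochs = 50, batch_size = 8, lr = 2e-3,
                      es_patience = 49, seed = 7)
  mt <- train_model(m, x, y, config = cfg)
  expect_equal(unname(predict(mt, x)$labels), y)  # fits separable data
  mt2 <- train_model(m, x, y, config = cfg)
  expect_identical(mt$history, mt2$history)
  expect_identical(mt$weights, mt2$weights)
  # checkpoint semantics: returned monitor equals the history minimum
  expect_equal(mt$best_monitor, min(mt$history$train_loss))
  expect_equal(mt$best_epoch, which.min(mt$history$train_loss))
})

test_that("training input validation works", {
  m <- build_custom_cnn(c(8, 8, 1), n_classes = 4, filters = c(2, 2, 2),
                        dense_units = c(4, 4), seed = 1)
  x <- array(rnorm(3 * 64), c(3, 8, 8, 1))
  expect_error(train_model(m, x, c(1L, 1L, 1L)), "single class")
  expect_error(train_model(m, x, c(0L, 1L, 9L)), "labels")
  bad <- array(rnorm(3 * 36), c(3, 6, 6, 1))
  expect_error(train_model(m, bad, c(0L, 1L, 2L)), "shape")
})

test_that("dropout is inference-silent and prediction repeatable", {
  m <- build_custom_cnn(c(8, 8, 1), n_classes = 3, filters = c(2, 2, 2),
                        dense_units = c(8, 8), dropout = 0.6, seed = 4)
  x <- array(rnorm(5 * 64), c(5, 8, 8, 1))
  p1 <- predict(m, x)
  p2 <- predict(m, x)
  expect_identical(p1$prob, p2$prob)
  pe <- predict(m, array(0, c(0, 8, 8, 1)))
  expect_equal(nrow(pe$prob), 0)
  expect_length(pe$labels, 0)
})

test_that("sample duplication equals integer class weights in total loss", {
  m <- build_custom_cnn(c(8, 8, 1), n_classes = 3, filters = c(2, 2, 2),
                        dense_units = c(6, 6), dropout = 0, seed = 9)
  set.seed(3)
  base <- array(rnorm(3 * 64), c(3, 8, 8, 1))
  y <- c(0L, 1L, 2L)
  k <- 3
  dup <- array(0, c(3 + k - 1, 8, 8, 1))
  dup[1:3, , , ] <- base
  for (i in seq_len(k - 1)) dup[3 + i, , , ] <- base[1, , , ]
  l_dup <- cnn_batch_loss(m, dup, c(y, rep(0L, k - 1)),
                          rep(1, 3 + k - 1))
  l_w <- cnn_batch_loss(m, base, y, c(k, 1, 1))
  expect_equal(l_dup, l_w, tolerance = 1e-6)
})

test_that("the network can memorize 64 random-label samples", {
  set.seed(11)
  x <- array(rnorm(64 * 12 * 12), c(64, 12, 12, 1))
  y <- sample(0:7, 64, TRUE)
  m <- build_custom_cnn(c(12, 12, 1), filters = c(8, 16, 16),
                        dense_units = c(64, 32), dropout = 0, seed = 2)
  cfg <- train_config(max_epochs = 400, batch_size = 16, lr = 2e-3,
                      lr_patience = 60, es_patience = 399, seed = 13)
  mt <- train_model(m, x, y, config = cfg)
  expect_equal(max(mt$history$train_acc), 1.0)
})
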