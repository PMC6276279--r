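test_that("backpropagation matches numerical gradients", {
  set.seed(1)
  arch <- cnn_architecture(filters = c(2L, 3L), dense = 4L, input = 12L)
  params <- credkit:::.init_params(arch)
  n <- 5L
  X <- array(runif(12 * 12 * n), c(12L, 12L, 1L, n))
  y <- c(0, 1, 1, 0, 1)
  loss_of <- function(p) {
    pr <- credkit:::.cnn_forward(p, X, dropout = 0, train = FALSE)$p
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    -mean(y * log(pr) + (1 - y) * log(1 - pr))
  }
  fwd <- credkit:::.cnn_forward(params, X, dropout = 0, train = TRUE)
  grads <- credkit:::.cnn_backward(params, fwd, y)
  eps <- 1e-6
  check <- function(get, set, g, k = 5L) {
    w <- get(params)
    ii <- sample(length(w), min(k, length(w)))
    for (i in ii) {
      p2 <- params; w2 <- w; w2[i] <- w[i] + eps; p2 <- set(p2, w2)
      p3 <- params; w3 <- w; w3[i] <- w[i] - eps; p3 <- set(p3, w3)
      num <- (loss_of(p2) - loss_of(p3)) / (2 * eps)
      expect_equal(as.numeric(g[i]), num, tolerance = 1e-4)
    }
  }
  check(function(p) p$conv[[1]]$W,
        function(p, w) { p$conv[[1]]$W[] <- w; p }, grads$conv[[1]]$W)
  check(function(p) p$conv[[2]]$W,
        function(p, w) { p$conv[[2]]$W[] <- w; p }, grads$conv[[2]]$W)
  check(function(p) p$conv[[2]]$b,
        function(p, w) { p$conv[[2]]$b[] <- w; p }, grads$conv[[2]]$b, 2L)
  check(function(p) p$d1$W, function(p, w) { p$d1$W[] <- w; p }, grads$d1$W)
  check(function(p) p$d2$W, function(p, w) { p$d2$W[] <- w; p }, grads$d2$W)
})

test_that("training is deterministic given a seed and learns separable data", {
  # small separable problem: bright top-left quadrant vs bright bottom-right
  gen <- function(n, seed) {
    set.seed(seed)
    x <- array(runif(24 * 24 * n, 0, 0.2), c(24L, 24L, n))
    y <- rep(0:1, length.out = n)
    for (i in seq_len(n)) {
      if (y[i] == 1) x[1:10, 1:10, i] <- x[1:10, 1:10, i] + 0.8
      else x[15:24, 15:24, i] <- x[15:24, 15:24, i] + 0.8
    }
    list(x = x, y = y)
  }
  tr <- gen(80, 10); te <- gen(40, 20)
  arch <- cnn_architecture(filters = c(4L), dense = 8L, input = 24L)
  m1 <- cred_cnn(tr$x, tr$y, architecture = arch, epochs = 6,
                 batch_size = 16, seed = 7)
  m2 <- cred_cnn(tr$x, tr$y, architecture = arch, epochs = 6,
                 batch_size = 16, seed = 7)
  expect_identical(m1$history$loss, m2$history$loss)  # reproducibility
  p <- predict(m1, te$x)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(mean((p > 0.5) == (te$y == 1)), 0.95)
  cls <- predict(m1, te$x, type = "class")
  expect_equal(cls, as.integer(p > 0.5))
  expect_output(print(m1), "conv blocks")
})

test_that("label-free noise trains to chance and interfaces validate", {
  set.seed(2)
  x <- array(runif(16 * 16 * 60), c(16L, 16L, 60L))
  y <- rep(0:1, 30)   # labels independent of content
  arch <- cnn_architecture(filters = c(2L), dense = 4L, input = 16L)
  m <- cred_cnn(x, y, architecture = arch, epochs = 3, batch_size = 15,
                seed = 3)
  xte <- array(runif(16 * 16 * 100), c(16L, 16L, 100L))
  p <- predict(m, xte)
  # no learnable signal: held-out accuracy against balanced labels ~ 0.5
  yte <- rep(0:1, 50)
  expect_equal(mean((p > 0.5) == (yte == 1)), 0.5, tolerance = 0.3)
  # single-class training set refused
  expect_error(cred_cnn(x, rep(1, 60), architecture = arch), "both classes")
  # wrong image size refused
  expect_error(predict(m, array(0, c(8, 8, 2))), "16x16")
  # single-image scoring helper
  s <- predict_score(m, xte[, , 1])
  expect_true(s >= 0 && s <= 1)
  # train/val calling convention records a validation trace
  mv <- train_classifier(list(x = x, y = y),
                         list(x = xte[, , 1:20], y = rep(0:1, 10)),
                         architecture = arch, epochs = 2, batch_size = 15,
                         seed = 4)
  expect_false(any(is.na(mv$history$val_accuracy)))
})
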