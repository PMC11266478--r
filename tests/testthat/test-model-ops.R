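test_that("the shape ledger tracks the default kernel stack", {
  cfg <- sst_config(n_classes = 14)
  expect_equal(cfg$shapes$conv3d_1[1:3], c(11, 11, 24))
  expect_equal(cfg$shapes$conv3d_2[1:3], c(9, 9, 20))
  expect_equal(cfg$shapes$conv3d_3, c(7, 7, 18, 32))
  expect_equal(cfg$shapes$merged_planes, 576)
  expect_equal(cfg$shapes$conv2d, c(5, 5, 1, 64))
  expect_equal(cfg$shapes$uv, 25)
  expect_error(sst_config(s = 7, b = 30, n_classes = 14), "conv2d")
  expect_error(sst_config(s = 13, b = 10, n_classes = 14), "conv3d layer 2")
})

test_that("the 3-D conv stack produces the ledger shapes on real patches", {
  set.seed(2)
  patch <- array(runif(13 * 13 * 30), c(13, 13, 30))
  kernels <- list(array(rnorm(3 * 3 * 7 * 1 * 8, sd = 0.1), c(3, 3, 7, 1, 8)),
                  array(rnorm(3 * 3 * 5 * 8 * 16, sd = 0.1), c(3, 3, 5, 8, 16)),
                  array(rnorm(3 * 3 * 3 * 16 * 32, sd = 0.1), c(3, 3, 3, 16, 32)))
  vol <- conv3d_stack(patch, kernels)
  expect_identical(dim(vol), c(7L, 7L, 18L, 32L))
  # zero weights (with ReLU) -> zero output
  zk <- lapply(kernels, function(k) k * 0)
  expect_true(all(conv3d_stack(patch, zk) == 0))
})

test_that("a single all-ones 3x3x7 kernel sums its receptive field", {
  c0 <- 0.37
  patch <- array(c0, c(5, 5, 9))
  k <- list(array(1, c(3, 3, 7, 1, 1)))
  out <- conv3d_stack(patch, k, biases = list(0.5), activation = "identity")
  expect_identical(dim(out), c(3L, 3L, 3L, 1L))
  expect_equal(as.vector(out), rep(3 * 3 * 7 * c0 + 0.5, 27))
  # hand evaluation of the quadruple sum on a non-constant patch
  set.seed(3)
  patch2 <- array(runif(5 * 5 * 9), c(5, 5, 9))
  out2 <- conv3d_stack(patch2, k, activation = "identity")
  expect_equal(out2[2, 3, 1, 1], sum(patch2[2:4, 3:5, 1:7]))
})

test_that("conv2d + CBAM flattens to the ledgered feature map", {
  set.seed(4)
  vol <- array(runif(7 * 7 * 18 * 32), c(7, 7, 18, 32))
  W <- array(rnorm(3 * 3 * 576 * 64, sd = 0.05), c(3, 3, 576, 64))
  g_plain <- conv2d_cbam(vol, W) # gates forced to 1
  expect_identical(dim(g_plain), c(25L, 64L))
  cb <- list(W1 = matrix(rnorm(4 * 64, sd = 0.3), 4, 64), b1 = numeric(4),
             W2 = matrix(rnorm(64 * 4, sd = 0.3), 64, 4), b2 = numeric(64),
             Wsp = matrix(rnorm(7 * 7 * 2, sd = 0.2), 98, 1), bsp = 0,
             spatial_kernel = 7)
  g_att <- conv2d_cbam(vol, W, cbam = cb)
  expect_identical(dim(g_att), c(25L, 64L))
  # sigmoid gates in (0,1): attended magnitudes never exceed the plain ones
  expect_true(all(abs(g_att) <= abs(g_plain) + 1e-12))
  expect_true(any(abs(g_att) < abs(g_plain) - 1e-9))
})

test_that("tokenizer pools feature rows through position softmax", {
  # identical rows are a fixed point regardless of Wa
  r <- c(0.3, -1.2, 0.5)
  g <- rbind(r, r, r, r)
  tk <- tokenize(g, matrix(rnorm(6), 3, 2))
  expect_equal(unname(tk), rbind(r, r), ignore_attr = TRUE, tolerance = 1e-12)
  # 2x2 hand fixture: softmax over positions of G Wa = I
  g2 <- diag(2)
  tk2 <- tokenize(g2, diag(2))
  a <- exp(1) / (exp(1) + 1) # softmax of (1, 0)
  expect_equal(unname(tk2), matrix(c(a, 1 - a, 1 - a, a), 2, 2),
               ignore_attr = TRUE, tolerance = 1e-12)
  # attention columns are distributions over positions
  set.seed(6)
  g3 <- matrix(rnorm(40), 10, 4)
  A <- attr(tokenize(g3, matrix(rnorm(12), 4, 3)), "attention")
  expect_equal(colSums(A), rep(1, 3))
  expect_true(all(A >= 0))
})

test_that("tokens lie in the convex hull of the feature-map rows", {
  set.seed(7)
  g <- matrix(rnorm(60), 12, 5)
  tk <- tokenize(g, matrix(rnorm(20), 5, 4))
  A <- attr(tk, "attention")
  expect_equal(unname(crossprod(A, g)), unname(unclass(tk)[, ]), tolerance = 1e-12)
  for (j in seq_len(ncol(g))) {
    expect_true(all(tk[, j] >= min(g[, j]) - 1e-12))
    expect_true(all(tk[, j] <= max(g[, j]) + 1e-12))
  }
})

test_that("one-token single-head attention is the identity on its value", {
  z <- 4
  x <- matrix(rnorm(z), 1, z)
  state <- list(Wq = diag(z), Wk = diag(z), Wv = diag(z), Wo = diag(z),
                bo = numeric(z), n_heads = 1)
  mlp <- list(W1 = matrix(0, z, 8), b1 = numeric(8),
              W2 = matrix(0, 8, z), b2 = numeric(z))
  out <- transformer_encode(x, state, mlp)
  xn <- (x - mean(x)) / sqrt(mean((x - mean(x))^2) + 1e-5)
  expect_equal(as.numeric(out), as.numeric(x + xn), tolerance = 1e-10)
  expect_equal(attr(out, "attention")[[1]][1, 1], 1) # softmax of a scalar
})

test_that("two-token attention matches an explicit spreadsheet evaluation", {
  x <- rbind(c(1, 0), c(0, 1))
  state <- list(Wq = diag(2), Wk = diag(2), Wv = diag(2), Wo = diag(2),
                bo = numeric(2), n_heads = 1)
  mlp <- list(W1 = matrix(0, 2, 4), b1 = numeric(4),
              W2 = matrix(0, 4, 2), b2 = numeric(2))
  out <- transformer_encode(x, state, mlp)
  # hand evaluation: layer-norm each row, scores = xn xn^T / sqrt(2),
  # row-softmax, weighted sum of values, residual
  xn <- t(apply(x, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5)))
  sc <- xn %*% t(xn) / sqrt(2)
  A <- exp(sc - apply(sc, 1, max)); A <- A / rowSums(A)
  expected <- x + A %*% xn
  expect_equal(unname(unclass(out)[, ]), unname(expected), tolerance = 1e-10)
})

test_that("the encoder preserves sequence shape and row-stochastic attention", {
  set.seed(9)
  z <- 8; w1 <- 5
  x <- matrix(rnorm(w1 * z), w1, z)
  state <- list(Wq = matrix(rnorm(z * z, sd = 0.3), z, z),
                Wk = matrix(rnorm(z * z, sd = 0.3), z, z),
                Wv = matrix(rnorm(z * z, sd = 0.3), z, z),
                Wo = matrix(rnorm(z * z, sd = 0.3), z, z),
                bo = rnorm(z), n_heads = 4)
  mlp <- list(W1 = matrix(rnorm(z * 16, sd = 0.3), z, 16), b1 = rnorm(16),
              W2 = matrix(rnorm(16 * z, sd = 0.3), 16, z), b2 = rnorm(z))
  out <- transformer_encode(x, state, mlp)
  expect_identical(dim(unclass(out)), dim(x))
  for (A in attr(out, "attention")) {
    expect_equal(rowSums(A), rep(1, w1), tolerance = 1e-12)
    expect_true(all(A >= 0))
  }
})

test_that("the classification head emits a full probability vector", {
  tk <- matrix(rnorm(12), 3, 4)
  p0 <- classify(tk, list(W = matrix(0, 4, 5), b = numeric(5)))
  expect_equal(as.numeric(p0), rep(1 / 5, 5)) # zero weights -> uniform
  set.seed(10)
  p <- classify(tk, list(W = matrix(rnorm(20), 4, 5), b = rnorm(5)))
  expect_equal(sum(p), 1)
  expect_length(as.numeric(p), 5)
  expect_identical(attr(p, "label"), unname(which.max(p)))
})

test_that("backpropagation matches finite differences on a tiny network", {
  expect_lt(grad_check(tiny_config()), 1e-4)
})

test_that("ablation branches backpropagate correctly too", {
  expect_lt(grad_check(tiny_config(use_cnn = FALSE)), 1e-4)
  expect_lt(grad_check(tiny_config(use_tokenizer = FALSE)), 1e-4)
  expect_lt(grad_check(tiny_config(use_cbam = FALSE)), 1e-4)
})
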