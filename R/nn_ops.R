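# Low-level neural-network operations.
#
# Convolutions are valid-mode, stride 1, implemented as an im2col gather
# followed by a BLAS matrix product; the gradient with respect to the input
# is a sparse scatter (Matrix::sparseMatrix built once per layer shape).
# Activations are stored batch-last: a batch is a (features x n) matrix whose
# feature ordering is the column-major flattening of (h, w, d, channel).

# Build a convolution plan for input shape (h, w, d, cin) and kernel
# (kh, kw, kd) with cout output channels.
conv_plan <- function(inshape, kshape, cout, layer_name = "conv") {
  h <- inshape[1]; w <- inshape[2]; d <- inshape[3]; cin <- inshape[4]
  kh <- kshape[1]; kw <- kshape[2]; kd <- kshape[3]
  oh <- h - kh + 1L; ow <- w - kw + 1L; od <- d - kd + 1L
  if (oh < 1 || ow < 1 || od < 1) {
    stop(sprintf("%s: kernel (%d,%d,%d) underflows input (%d,%d,%d)",
                 layer_name, kh, kw, kd, h, w, d))
  }
  npos <- oh * ow * od
  ksz <- kh * kw * kd * cin
  pos0 <- as.vector(outer(outer(seq_len(oh) - 1L, (seq_len(ow) - 1L) * h, "+"),
                          (seq_len(od) - 1L) * h * w, "+"))
  off0 <- as.vector(outer(outer(outer(seq_len(kh) - 1L, (seq_len(kw) - 1L) * h, "+"),
                                (seq_len(kd) - 1L) * h * w, "+"),
                          (seq_len(cin) - 1L) * h * w * d, "+"))
  idx <- outer(pos0, off0, "+") + 1L # npos x ksz, into length h*w*d*cin
  scatter <- Matrix::sparseMatrix(i = as.vector(idx), j = seq_along(idx), x = 1,
                                  dims = c(h * w * d * cin, npos * ksz))
  list(inshape = inshape, outshape = c(oh, ow, od, cout),
       npos = npos, ksz = ksz, cout = cout,
       idx = as.vector(idx), scatter = scatter, name = layer_name)
}

# X: (h*w*d*cin, n) -> list(y = (npos*n, cout), xg = im2col cache).
# Row order of y and xg is position-fastest within each sample; the gather
# and product run per sample so no transposition of the large im2col matrix
# is ever needed.
conv_forward <- function(X, plan, W, b) {
  n <- ncol(X)
  npos <- plan$npos; ksz <- plan$ksz
  y <- matrix(0, npos * n, plan$cout)
  xg <- vector("list", n)
  for (s in seq_len(n)) {
    xgs <- matrix(X[plan$idx, s], npos, ksz)
    xg[[s]] <- xgs
    y[(s - 1L) * npos + seq_len(npos), ] <- xgs %*% W
  }
  y <- y + rep(b, each = nrow(y))
  list(y = y, xg = xg)
}

# dY: (npos*n, cout) -> grads and dX (h*w*d*cin, n)
conv_backward <- function(dY, plan, W, xg, n, need_dx = TRUE) {
  db <- colSums(dY)
  dW <- matrix(0, plan$ksz, plan$cout)
  npos <- plan$npos
  Wt <- t(W)
  dX <- if (need_dx) matrix(0, prod(plan$inshape), n) else NULL
  for (s in seq_len(n)) {
    rows <- (s - 1L) * npos + seq_len(npos)
    dYs <- dY[rows, , drop = FALSE]
    dW <- dW + crossprod(xg[[s]], dYs)
    if (need_dx) {
      dxgs <- dYs %*% Wt # (npos, ksz)
      dX[, s] <- as.numeric(plan$scatter %*% as.vector(dxgs))
    }
  }
  list(dW = dW, db = db, dX = dX)
}

# (npos*n, cout) activation rows -> (npos*cout, n) input matrix of next layer
conv_to_input <- function(Y, npos, n, cout) {
  dim(Y) <- c(npos, n, cout)
  Y <- aperm(Y, c(1, 3, 2))
  dim(Y) <- c(npos * cout, n)
  Y
}

# inverse mapping for gradients
input_to_conv <- function(dX, npos, n, cout) {
  dim(dX) <- c(npos, cout, n)
  dX <- aperm(dX, c(1, 3, 2))
  dim(dX) <- c(npos * n, cout)
  dX
}

act_forward <- function(x, kind) {
  switch(kind,
         relu = pmax(x, 0),
         tanh = tanh(x),
         identity = x,
         stop(sprintf("unknown activation '%s'", kind)))
}

act_backward <- function(dy, x_pre, kind) {
  switch(kind,
         relu = dy * (x_pre > 0),
         tanh = dy * (1 - tanh(x_pre)^2),
         identity = dy,
         stop(sprintf("unknown activation '%s'", kind)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  e <- exp(x - apply(x, 1, max))
  e / rowSums(e)
}

softmax_cols <- function(x) {
  e <- exp(sweep(x, 2, apply(x, 2, max)))
  sweep(e, 2, colSums(e), "/")
}

# Batch normalisation over rows of x (rows = batch*positions, cols = channels).
bn_forward <- function(x, gamma, beta, state, training, eps = 1e-5,
                       momentum = 0.1) {
  if (training) {
    mu <- colMeans(x)
    xc <- sweep(x, 2, mu)
    v <- colMeans(xc^2)
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * v
  } else {
    mu <- state$mean; v <- state$var
    xc <- sweep(x, 2, mu)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, inv_sd, "*")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, xhat = xhat, inv_sd = inv_sd, state = state)
}

bn_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat; inv_sd <- cache$inv_sd
  m <- nrow(dy)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  dx <- sweep(dxhat - matrix(colMeans(dxhat), m, ncol(dy), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), m, ncol(dy), byrow = TRUE),
              2, inv_sd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Layer normalisation over the columns (feature axis) of each row.
ln_forward <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- xc * inv_sd
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  list(y = y, xhat = xhat, inv_sd = inv_sd)
}

ln_backward <- function(dy, cache, gamma) {
  xhat <- cache$xhat; inv_sd <- cache$inv_sd
  k <- ncol(dy)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv_sd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Adam optimiser step on a flat named list of parameter arrays.
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

# softmax cross-entropy: logits (n, Z), y integer labels 1..Z
softmax_ce <- function(logits, y) {
  p <- softmax_rows(logits)
  n <- nrow(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(n), y)] <- dlogits[cbind(seq_len(n), y)] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}
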