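# Single-sample, explicit-weights versions of the network stages. These are
# the inspectable building blocks (useful for hand-checking against the
# defining formulas); training uses the batched internals.

#' Apply a stack of valid-mode stride-1 3-D convolutions to one patch
#'
#' Each layer computes, at spatial-spectral position (alpha, beta, gamma) of
#' output cube j, `Phi( sum_k sum_h sum_w sum_r w[h,w,r,k,j] *
#' x[alpha+h, beta+w, gamma+r, k] + b[j] )`.
#'
#' @param patch S x S x B numeric array (a single-channel input cube).
#' @param kernels list of kernel arrays, each (kh, kw, kd, cin, cout) with
#'   `cin` matching the previous layer's `cout` (1 for the first layer).
#' @param biases list of per-layer bias vectors (length cout); defaults to
#'   zeros.
#' @param activation `"relu"` (default), `"tanh"`, or `"identity"`.
#' @return 4-D feature volume (h', w', d', cout) after the last layer.
#' @export
conv3d_stack <- function(patch, kernels, biases = NULL,
                         activation = c("relu", "tanh", "identity")) {
  activation <- match.arg(activation)
  if (length(dim(patch)) != 3) stop("patch must be an S x S x B array")
  cur <- patch
  dim(cur) <- c(dim(patch), 1)
  for (l in seq_along(kernels)) {
    k <- kernels[[l]]
    if (length(dim(k)) != 5) stop("kernel must be (kh, kw, kd, cin, cout)")
    kd <- dim(k)
    if (kd[4] != dim(cur)[4]) {
      stop(sprintf("layer %d: kernel cin %d does not match input channels %d",
                   l, kd[4], dim(cur)[4]))
    }
    plan <- conv_plan(dim(cur), kd[1:3], kd[5], paste0("conv3d_", l))
    W <- matrix(k, plan$ksz, kd[5])
    b <- if (is.null(biases)) numeric(kd[5]) else biases[[l]]
    X <- cur; dim(X) <- c(prod(dim(cur)), 1)
    y <- conv_forward(X, plan, W, b)$y
    y <- act_forward(y, activation)
    cur <- array(y, plan$outshape)
  }
  cur
}

#' 2-D convolution + CBAM over a feature volume, flattened to a feature map
#'
#' Merges the spectral and channel axes of a 4-D feature volume into planes,
#' applies one valid 3x3-type 2-D convolution, then (optionally) the
#' convolutional block attention module: a channel gate from a shared MLP
#' over global max- and average-pooled descriptors, followed by a spatial
#' gate from a kxk convolution over the channelwise max and mean maps, both
#' squashed through a sigmoid. Passing `cbam = NULL` forces both gates to 1
#' (the ablation path without attention).
#'
#' @param volume (h, w, d, c) feature volume.
#' @param conv_W kernel array (kh, kw, cin, cout) with `cin = d * c`.
#' @param conv_b bias vector (cout), default zeros.
#' @param cbam NULL, or list with `W1`, `b1`, `W2`, `b2` (channel MLP),
#'   `Wsp` ((k*k*2) x 1 spatial kernel), `bsp`, `spatial_kernel`.
#' @param activation activation after the convolution.
#' @return feature map G, a (u*v) x cout matrix of flattened spatial
#'   positions by channels.
#' @export
conv2d_cbam <- function(volume, conv_W, conv_b = NULL, cbam = NULL,
                        activation = c("relu", "tanh", "identity")) {
  activation <- match.arg(activation)
  dv <- dim(volume)
  if (length(dv) != 4) stop("volume must be a (h, w, d, c) array")
  planes <- dv[3] * dv[4]
  kd <- dim(conv_W)
  if (length(kd) != 4 || kd[3] != planes) {
    stop(sprintf("conv kernel cin %d must equal merged planes %d", kd[3], planes))
  }
  z <- kd[4]
  plan <- conv_plan(c(dv[1], dv[2], 1, planes), c(kd[1], kd[2], 1), z, "conv2d")
  W <- matrix(conv_W, plan$ksz, z)
  b <- if (is.null(conv_b)) numeric(z) else conv_b
  X <- volume; dim(X) <- c(prod(dv), 1)
  y <- act_forward(conv_forward(X, plan, W, b)$y, activation) # (uv, z)
  u <- plan$outshape[1]; v <- plan$outshape[2]
  if (is.null(cbam)) return(y)
  # channel gate
  avg_c <- colMeans(y); max_c <- apply(y, 2, max)
  mlp <- function(x) drop(cbam$W2 %*% act_forward(cbam$W1 %*% x + cbam$b1,
                                                  activation)) + cbam$b2
  gate_c <- sigmoid(mlp(avg_c) + mlp(max_c))
  yc <- sweep(y, 2, gate_c, "*")
  # spatial gate
  ksp <- cbam$spatial_kernel
  padw <- (ksp - 1) / 2
  ph <- u + 2 * padw; pw <- v + 2 * padw
  pad <- array(0, c(ph, pw, 1, 2))
  pad[padw + seq_len(u), padw + seq_len(v), 1, 1] <- matrix(rowMeans(yc), u, v)
  pad[padw + seq_len(u), padw + seq_len(v), 1, 2] <- matrix(apply(yc, 1, max), u, v)
  plan_sp <- conv_plan(c(ph, pw, 1, 2), c(ksp, ksp, 1), 1, "cbam_spatial")
  Xs <- pad; dim(Xs) <- c(prod(dim(pad)), 1)
  gate_s <- sigmoid(conv_forward(Xs, plan_sp, cbam$Wsp, cbam$bsp)$y)
  yc * as.vector(gate_s)
}

#' Gaussian-weighted feature tokenization
#'
#' Maps a flattened feature map to `w` semantic tokens:
#' `A = softmax_positions(G Wa)` (each of A's columns is a probability
#' distribution over the u*v spatial positions) and `T = t(A) G`, so every
#' token is a convex combination of the feature map's rows.
#'
#' @param g (u*v) x z feature map.
#' @param wa z x w weight matrix (Gaussian-initialised during training).
#' @return w x z token matrix with the attention matrix `A` attached as
#'   attribute `"attention"`.
#' @examples
#' g <- diag(2)
#' tokenize(g, diag(2))
#' @export
tokenize <- function(g, wa) {
  g <- as.matrix(g); wa <- as.matrix(wa)
  if (ncol(g) != nrow(wa)) stop("feature map channels and Wa rows differ")
  if (anyNA(wa) || any(!is.finite(wa))) stop("Wa must be finite")
  A <- softmax_cols(g %*% wa)
  tok <- crossprod(A, g)
  attr(tok, "attention") <- A
  tok
}

#' One pre-norm transformer encoder block on a token sequence
#'
#' `x' = x + MSA(LN(x)); out = x' + MLP(LN(x'))`. Multi-head self-attention
#' computes, per head, `softmax(Q K^T / sqrt(d_K)) V` with Q/K/V linear
#' projections of the normalised tokens; heads are concatenated and
#' projected back to the channel width so input and output shapes agree.
#'
#' @param tokens (w+1) x z matrix (classification token first, position
#'   embeddings already added).
#' @param state list with projections `Wq`, `Wk`, `Wv` (z x z), output
#'   projection `Wo` (z x z), `bo`, head count `n_heads`, and layer-norm
#'   parameters `ln1_g`, `ln1_b`, `ln2_g`, `ln2_b` (all optional; defaults
#'   gamma 1 / beta 0).
#' @param mlp list with `W1`, `b1`, `W2`, `b2` and optionally `activation`.
#' @return encoded (w+1) x z matrix; per-head row-stochastic attention
#'   matrices are attached as attribute `"attention"`.
#' @export
transformer_encode <- function(tokens, state, mlp) {
  x <- as.matrix(tokens)
  z <- ncol(x); h <- state$n_heads
  if (z %% h != 0) stop("head count must divide the token width")
  dK <- z / h
  g1 <- state$ln1_g %||% rep(1, z); b1 <- state$ln1_b %||% numeric(z)
  g2 <- state$ln2_g %||% rep(1, z); b2 <- state$ln2_b %||% numeric(z)
  xn <- ln_forward(x, g1, b1)$y
  Q <- xn %*% state$Wq; K <- xn %*% state$Wk; V <- xn %*% state$Wv
  O <- matrix(0, nrow(x), z)
  attn <- vector("list", h)
  for (hd in seq_len(h)) {
    cols <- (hd - 1) * dK + seq_len(dK)
    A <- softmax_rows(tcrossprod(Q[, cols, drop = FALSE],
                                 K[, cols, drop = FALSE]) / sqrt(dK))
    attn[[hd]] <- A
    O[, cols] <- A %*% V[, cols, drop = FALSE]
  }
  x1 <- x + O %*% state$Wo + matrix(state$bo %||% numeric(z), nrow(x), z,
                                    byrow = TRUE)
  xn2 <- ln_forward(x1, g2, b2)$y
  act <- mlp$activation %||% "relu"
  Hh <- act_forward(sweep(xn2 %*% mlp$W1, 2, mlp$b1, "+"), act)
  out <- x1 + sweep(Hh %*% mlp$W2, 2, mlp$b2, "+")
  attr(out, "attention") <- attn
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Class probabilities from the classification token
#'
#' A linear layer plus softmax on the encoded classification token (the
#' first row of the token sequence); the model reports a full per-class
#' probability vector, and the hard label is the argmax with ties broken to
#' the lowest class id.
#'
#' @param tokens_out encoded (w+1) x z token matrix.
#' @param head list with `W` (z x Z) and `b` (length Z).
#' @return numeric vector of Z class probabilities (sums to 1), with the
#'   predicted label attached as attribute `"label"`.
#' @examples
#' classify(matrix(rnorm(10), 2, 5), list(W = matrix(0, 5, 3), b = numeric(3)))
#' @export
classify <- function(tokens_out, head) {
  cls <- as.numeric(tokens_out[1, ])
  logits <- drop(cls %*% head$W) + head$b
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  attr(p, "label") <- which.max(p) # which.max ties -> lowest index
  p
}
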