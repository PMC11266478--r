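#' Spectral-spatial tokenized-transformer configuration
#'
#' Architecture of the hybrid CNN-transformer classifier: three valid-mode,
#' stride-1 3-D convolutions (kernel spectral depths 7 > 5 > 3, channel
#' widths 8/16/32 so each layer doubles the previous), a 64-kernel 3x3 2-D
#' convolution over the merged spectral-channel planes, a convolutional
#' block attention module (channel gate then spatial gate), a
#' Gaussian-initialised feature tokenizer, one pre-norm transformer encoder
#' block, and a linear classification head read from the classification
#' token.
#'
#' The constructor validates the shape ledger: with valid (no padding)
#' stride-1 convolutions the patch window `s` and band count `b` must
#' survive the kernel stack (the defaults give spatial 13 -> 11 -> 9 -> 7
#' -> 5 and spectral 30 -> 24 -> 20 -> 18), and an (s, b) pair that
#' underflows any layer is rejected with the offending layer named.
#'
#' @param s odd patch window size (default 13).
#' @param b reduced band count fed to the network (default 30).
#' @param n_classes number of treatment classes Z.
#' @param conv3d_channels 3-D conv widths (default 8, 16, 32).
#' @param conv3d_kernels list of (height, width, spectral) kernel sizes.
#' @param conv2d_channels,conv2d_kernel 2-D conv width and kernel.
#' @param cbam_reduction channel-attention bottleneck ratio (default 16).
#' @param cbam_spatial_kernel spatial-attention kernel (default 7).
#' @param n_tokens number of semantic tokens w (default 4).
#' @param n_heads attention heads h (default 4); must divide the channel
#'   width z.
#' @param mlp_dim transformer feed-forward width (default 4 z).
#' @param dropout dropout rate on the attention and feed-forward outputs.
#' @param activation `"relu"` (default) or `"tanh"`.
#' @param batchnorm batch-normalise after each convolution (default TRUE).
#' @param use_cnn,use_cbam,use_tokenizer ablation switches: disabling the
#'   CNN replaces it with a per-position linear projection of the raw patch;
#'   disabling CBAM fixes both gates at 1; disabling the tokenizer (and with
#'   it the transformer encoder) classifies from a two-layer fully connected
#'   head on the flattened feature map.
#' @return object of class `sst_config` with the resolved shape ledger in
#'   `$shapes`.
#' @export
sst_config <- function(s = 13, b = 30, n_classes,
                       conv3d_channels = c(8, 16, 32),
                       conv3d_kernels = list(c(3, 3, 7), c(3, 3, 5), c(3, 3, 3)),
                       conv2d_channels = 64, conv2d_kernel = c(3, 3),
                       cbam_reduction = 16, cbam_spatial_kernel = 7,
                       n_tokens = 4, n_heads = 4, mlp_dim = NULL,
                       dropout = 0, activation = c("relu", "tanh"),
                       batchnorm = TRUE,
                       use_cnn = TRUE, use_cbam = TRUE, use_tokenizer = TRUE) {
  activation <- match.arg(activation)
  if (missing(n_classes)) stop("n_classes is required")
  if (s %% 2 == 0) stop("patch window s must be odd")
  if (length(conv3d_channels) != length(conv3d_kernels)) {
    stop("one kernel size per 3-D conv layer required")
  }
  z <- conv2d_channels
  if (z %% n_heads != 0) stop("n_heads must divide the channel width z")
  if (is.null(mlp_dim)) mlp_dim <- 4L * z

  shapes <- list()
  if (use_cnn) {
    cur <- c(s, s, b, 1)
    for (l in seq_along(conv3d_kernels)) {
      k <- conv3d_kernels[[l]]
      nxt <- c(cur[1] - k[1] + 1, cur[2] - k[2] + 1, cur[3] - k[3] + 1,
               conv3d_channels[l])
      if (any(nxt[1:3] < 1)) {
        stop(sprintf("shape ledger: conv3d layer %d kernel (%d,%d,%d) underflows input (%d,%d,%d)",
                     l, k[1], k[2], k[3], cur[1], cur[2], cur[3]))
      }
      shapes[[paste0("conv3d_", l)]] <- nxt
      cur <- nxt
    }
    merged <- cur[3] * cur[4] # spectral x channel planes
    u <- cur[1] - conv2d_kernel[1] + 1
    v <- cur[2] - conv2d_kernel[2] + 1
    if (u < 1 || v < 1) {
      stop(sprintf("shape ledger: conv2d kernel (%d,%d) underflows input (%d,%d)",
                   conv2d_kernel[1], conv2d_kernel[2], cur[1], cur[2]))
    }
    shapes$conv2d <- c(u, v, 1, z)
    shapes$merged_planes <- merged
  } else {
    u <- s; v <- s
    shapes$proj <- c(u, v, 1, z)
  }
  shapes$uv <- u * v
  shapes$z <- z

  structure(list(s = s, b = b, n_classes = n_classes,
                 conv3d_channels = conv3d_channels,
                 conv3d_kernels = conv3d_kernels,
                 conv2d_channels = conv2d_channels,
                 conv2d_kernel = conv2d_kernel,
                 cbam_reduction = cbam_reduction,
                 cbam_spatial_kernel = cbam_spatial_kernel,
                 n_tokens = n_tokens, n_heads = n_heads, mlp_dim = mlp_dim,
                 dropout = dropout, activation = activation,
                 batchnorm = batchnorm,
                 use_cnn = use_cnn, use_cbam = use_cbam,
                 use_tokenizer = use_tokenizer,
                 shapes = shapes),
            class = "sst_config")
}

#' @export
print.sst_config <- function(x, ...) {
  cat(sprintf("<sst_config> s=%d b=%d z=%d tokens=%d heads=%d classes=%d [cnn=%s cbam=%s tokenizer/TE=%s]\n",
              x$s, x$b, x$shapes$z, x$n_tokens, x$n_heads, x$n_classes,
              x$use_cnn, x$use_cbam, x$use_tokenizer))
  invisible(x)
}

# Build convolution plans (geometry only; reused across batches).
sst_plans <- function(cfg) {
  plans <- list()
  if (cfg$use_cnn) {
    cur <- c(cfg$s, cfg$s, cfg$b, 1)
    for (l in seq_along(cfg$conv3d_kernels)) {
      plans[[paste0("conv", l)]] <- conv_plan(cur, cfg$conv3d_kernels[[l]],
                                              cfg$conv3d_channels[l],
                                              paste0("conv3d_", l))
      cur <- plans[[paste0("conv", l)]]$outshape
    }
    plans$conv2d <- conv_plan(c(cur[1], cur[2], 1, cur[3] * cur[4]),
                              c(cfg$conv2d_kernel, 1), cfg$conv2d_channels,
                              "conv2d")
    u <- plans$conv2d$outshape[1]; v <- plans$conv2d$outshape[2]
  } else {
    u <- cfg$s; v <- cfg$s
  }
  if (cfg$use_cbam) {
    ksp <- cfg$cbam_spatial_kernel
    padw <- (ksp - 1) / 2
    plans$cbam_sp <- conv_plan(c(u + 2 * padw, v + 2 * padw, 1, 2),
                               c(ksp, ksp, 1), 1, "cbam_spatial")
    plans$cbam_pad <- padw
  }
  plans$u <- u; plans$v <- v
  plans
}

he_init <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / fan_in)), nr, nc)
xavier_init <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)

sst_init <- function(cfg, seed = 1) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  plans <- sst_plans(cfg)
  z <- cfg$shapes$z; w <- cfg$n_tokens; uv <- cfg$shapes$uv
  p <- list(); bn_state <- list()
  if (cfg$use_cnn) {
    for (l in seq_along(cfg$conv3d_kernels)) {
      pl <- plans[[paste0("conv", l)]]
      p[[paste0("conv", l, "_W")]] <- he_init(pl$ksz, pl$cout, pl$ksz)
      p[[paste0("conv", l, "_b")]] <- numeric(pl$cout)
      if (cfg$batchnorm) {
        p[[paste0("bn", l, "_g")]] <- rep(1, pl$cout)
        p[[paste0("bn", l, "_b")]] <- numeric(pl$cout)
        bn_state[[paste0("bn", l)]] <- list(mean = numeric(pl$cout), var = rep(1, pl$cout))
      }
    }
    p$conv2d_W <- he_init(plans$conv2d$ksz, z, plans$conv2d$ksz)
    p$conv2d_b <- numeric(z)
    if (cfg$batchnorm) {
      p$bn2d_g <- rep(1, z); p$bn2d_b <- numeric(z)
      bn_state$bn2d <- list(mean = numeric(z), var = rep(1, z))
    }
  } else {
    p$proj_W <- he_init(cfg$b, z, cfg$b)
    p$proj_b <- numeric(z)
  }
  if (cfg$use_cbam) {
    hid <- max(1L, floor(z / cfg$cbam_reduction))
    p$cbam_W1 <- he_init(z, hid, z); p$cbam_b1 <- numeric(hid)
    p$cbam_W2 <- he_init(hid, z, hid); p$cbam_b2 <- numeric(z)
    p$cbam_Wsp <- he_init(plans$cbam_sp$ksz, 1, plans$cbam_sp$ksz)
    p$cbam_bsp <- 0
  }
  if (cfg$use_tokenizer) {
    p$tok_Wa <- matrix(stats::rnorm(z * w, sd = 1 / sqrt(z)), z, w) # Gaussian init
    p$cls <- stats::rnorm(z, sd = 0.02)
    p$posemb <- matrix(stats::rnorm((w + 1) * z, sd = 0.02), w + 1, z)
    p$ln1_g <- rep(1, z); p$ln1_b <- numeric(z)
    p$Wq <- xavier_init(z, z); p$Wk <- xavier_init(z, z); p$Wv <- xavier_init(z, z)
    p$Wo <- xavier_init(z, z); p$bo <- numeric(z)
    p$ln2_g <- rep(1, z); p$ln2_b <- numeric(z)
    p$mlp_W1 <- xavier_init(z, cfg$mlp_dim); p$mlp_b1 <- numeric(cfg$mlp_dim)
    p$mlp_W2 <- xavier_init(cfg$mlp_dim, z); p$mlp_b2 <- numeric(z)
    p$head_W <- xavier_init(z, cfg$n_classes); p$head_b <- numeric(cfg$n_classes)
  } else {
    hid <- 2L * z
    p$fc_W1 <- he_init(uv * z, hid, uv * z); p$fc_b1 <- numeric(hid)
    p$fc_W2 <- xavier_init(hid, cfg$n_classes); p$fc_b2 <- numeric(cfg$n_classes)
  }
  list(params = p, bn_state = bn_state, plans = plans)
}

# Forward pass. X: (s, s, b, n) array. Returns logits (n, Z) and cache.
sst_forward <- function(params, cfg, plans, bn_state, X, training = FALSE,
                        drop_masks = NULL) {
  n <- dim(X)[4]
  act <- cfg$activation
  cache <- list(n = n)
  Xm <- X; dim(Xm) <- c(cfg$s * cfg$s * cfg$b, n)

  if (cfg$use_cnn) {
    cur <- Xm
    for (l in seq_along(cfg$conv3d_kernels)) {
      pl <- plans[[paste0("conv", l)]]
      cf <- conv_forward(cur, pl, params[[paste0("conv", l, "_W")]],
                         params[[paste0("conv", l, "_b")]])
      y <- cf$y
      if (cfg$batchnorm) {
        bc <- bn_forward(y, params[[paste0("bn", l, "_g")]],
                         params[[paste0("bn", l, "_b")]],
                         bn_state[[paste0("bn", l)]], training)
        bn_state[[paste0("bn", l)]] <- bc$state
        cache[[paste0("bn", l)]] <- bc
        ypre <- bc$y
      } else ypre <- y
      a <- act_forward(ypre, act)
      cache[[paste0("conv", l)]] <- list(xg = cf$xg, ypre = ypre, npos = pl$npos)
      cur <- conv_to_input(a, pl$npos, n, pl$cout)
    }
    pl <- plans$conv2d
    cf <- conv_forward(cur, pl, params$conv2d_W, params$conv2d_b)
    y <- cf$y
    if (cfg$batchnorm) {
      bc <- bn_forward(y, params$bn2d_g, params$bn2d_b, bn_state$bn2d, training)
      bn_state$bn2d <- bc$state
      cache$bn2d <- bc
      ypre <- bc$y
    } else ypre <- y
    A4 <- act_forward(ypre, act) # (uv*n, z)
    cache$conv2d <- list(xg = cf$xg, ypre = ypre, npos = pl$npos)
    uv <- pl$npos
  } else {
    uv <- cfg$shapes$uv
    Xp <- Xm; dim(Xp) <- c(uv, cfg$b, n)
    Xp <- aperm(Xp, c(1, 3, 2)); dim(Xp) <- c(uv * n, cfg$b)
    A4 <- Xp %*% params$proj_W
    A4 <- A4 + rep(params$proj_b, each = nrow(A4))
    cache$proj <- list(xp = Xp)
  }
  z <- cfg$shapes$z

  if (cfg$use_cbam) {
    cb <- cbam_forward(params, cfg, plans, A4, uv, n, act)
    G2 <- cb$out
    cache$cbam <- cb
  } else {
    G2 <- A4
  }
  cache$A4 <- A4
  cache$uv <- uv

  if (cfg$use_tokenizer) {
    w <- cfg$n_tokens; w1 <- w + 1L
    S <- G2 %*% params$tok_Wa # (uv*n, w)
    dim(S) <- c(uv, n * w)
    A <- softmax_cols(S) # columns ordered sample-fastest then token
    TK <- array(0, c(w1, z, n))
    for (s_i in seq_len(n)) {
      Gs <- G2[(s_i - 1) * uv + seq_len(uv), , drop = FALSE]
      As <- A[, s_i + (seq_len(w) - 1) * n, drop = FALSE]
      TK[, , s_i] <- rbind(params$cls, crossprod(As, Gs)) + params$posemb
    }
    cache$tok <- list(A = A)
    TKm <- aperm(TK, c(1, 3, 2)); dim(TKm) <- c(w1 * n, z)

    l1 <- ln_forward(TKm, params$ln1_g, params$ln1_b)
    Q <- l1$y %*% params$Wq; K <- l1$y %*% params$Wk; V <- l1$y %*% params$Wv
    h <- cfg$n_heads; dK <- z / h
    O <- matrix(0, w1 * n, z)
    attn <- vector("list", n)
    for (s_i in seq_len(n)) {
      rows <- (s_i - 1) * w1 + seq_len(w1)
      attn[[s_i]] <- vector("list", h)
      for (hd in seq_len(h)) {
        cols <- (hd - 1) * dK + seq_len(dK)
        sc <- tcrossprod(Q[rows, cols, drop = FALSE],
                         K[rows, cols, drop = FALSE]) / sqrt(dK)
        Ah <- softmax_rows(sc)
        O[rows, cols] <- Ah %*% V[rows, cols, drop = FALSE]
        attn[[s_i]][[hd]] <- Ah
      }
    }
    msa <- O %*% params$Wo
    msa <- msa + rep(params$bo, each = nrow(msa))
    if (training && cfg$dropout > 0) {
      if (is.null(drop_masks)) {
        drop_masks <- list(
          msa = matrix(stats::rbinom(length(msa), 1, 1 - cfg$dropout) /
                         (1 - cfg$dropout), nrow(msa), ncol(msa)),
          mlp = matrix(stats::rbinom(w1 * n * z, 1, 1 - cfg$dropout) /
                         (1 - cfg$dropout), w1 * n, z))
      }
      msa <- msa * drop_masks$msa
    }
    x1 <- TKm + msa
    l2 <- ln_forward(x1, params$ln2_g, params$ln2_b)
    H1 <- l2$y %*% params$mlp_W1
    H1 <- H1 + rep(params$mlp_b1, each = nrow(H1))
    Ha <- act_forward(H1, act)
    M <- Ha %*% params$mlp_W2
    M <- M + rep(params$mlp_b2, each = nrow(M))
    if (training && cfg$dropout > 0) M <- M * drop_masks$mlp
    out <- x1 + M
    cls_rows <- (seq_len(n) - 1) * w1 + 1L
    cls_out <- out[cls_rows, , drop = FALSE]
    logits <- cls_out %*% params$head_W
    logits <- logits + rep(params$head_b, each = n)
    cache$te <- list(TKm = TKm, l1 = l1, Q = Q, K = K, V = V, O = O,
                     attn = attn, x1 = x1, l2 = l2, H1 = H1, Ha = Ha,
                     cls_out = cls_out, drop_masks = drop_masks)
  } else {
    Gf <- G2; dim(Gf) <- c(uv, n, z)
    Gf <- aperm(Gf, c(2, 1, 3)); dim(Gf) <- c(n, uv * z)
    F1 <- Gf %*% params$fc_W1
    F1 <- F1 + rep(params$fc_b1, each = n)
    Fa <- act_forward(F1, act)
    logits <- Fa %*% params$fc_W2
    logits <- logits + rep(params$fc_b2, each = n)
    cache$fc <- list(Gf = Gf, F1 = F1, Fa = Fa)
  }
  cache$G2 <- G2
  list(logits = logits, cache = cache, bn_state = bn_state)
}

cbam_forward <- function(params, cfg, plans, A4, uv, n, act) {
  z <- ncol(A4)
  m1 <- A4; dim(m1) <- c(uv, n * z)
  avg_c <- matrix(colMeans(m1), n, z)
  mxi <- max.col(t(m1), ties.method = "first")
  max_c <- matrix(m1[(seq_len(n * z) - 1) * uv + mxi], n, z)
  h_avg_pre <- avg_c %*% params$cbam_W1
  h_avg_pre <- h_avg_pre + rep(params$cbam_b1, each = n)
  h_avg <- act_forward(h_avg_pre, act)
  s_avg <- h_avg %*% params$cbam_W2
  h_max_pre <- max_c %*% params$cbam_W1
  h_max_pre <- h_max_pre + rep(params$cbam_b1, each = n)
  h_max <- act_forward(h_max_pre, act)
  s_max <- h_max %*% params$cbam_W2
  s_sum <- s_avg + s_max + rep(params$cbam_b2, each = n) * 2
  gate_c <- sigmoid(s_sum) # (n, z)
  gexp <- gate_c[rep(seq_len(n), each = uv), , drop = FALSE]
  A4c <- A4 * gexp
  # spatial attention on the channel-gated volume
  rmean <- rowMeans(A4c)
  ridx <- max.col(A4c, ties.method = "first")
  rmax <- A4c[cbind(seq_len(uv * n), ridx)]
  u <- plans$u; v <- plans$v; padw <- plans$cbam_pad
  ph <- u + 2 * padw; pw <- v + 2 * padw
  Xsp <- matrix(0, ph * pw * 2, n)
  interior <- as.vector(outer(padw + seq_len(u), (padw + seq_len(v) - 1) * ph, "+"))
  mean_map <- matrix(rmean, uv, n); max_map <- matrix(rmax, uv, n)
  Xsp[interior, ] <- mean_map
  Xsp[interior + ph * pw, ] <- max_map
  cf <- conv_forward(Xsp, plans$cbam_sp, params$cbam_Wsp, params$cbam_bsp)
  gate_s <- sigmoid(cf$y) # (uv*n, 1)
  out <- A4c * as.vector(gate_s)
  list(out = out, gate_c = gate_c, gexp = gexp, A4c = A4c, mxi = mxi,
       ridx = ridx, gate_s = gate_s, xg_sp = cf$xg, interior = interior,
       h_avg_pre = h_avg_pre, h_avg = h_avg, h_max_pre = h_max_pre,
       h_max = h_max, avg_c = avg_c, max_c = max_c)
}

cbam_backward <- function(dout, params, cfg, plans, cache, A4, uv, n, act,
                          grads) {
  cb <- cache
  z <- ncol(A4)
  gs <- as.vector(cb$gate_s)
  dA4c <- dout * gs
  dgs <- rowSums(dout * cb$A4c)
  dysp <- matrix(dgs * gs * (1 - gs), ncol = 1)
  cbk <- conv_backward(dysp, plans$cbam_sp, params$cbam_Wsp, cb$xg_sp, n)
  grads$cbam_Wsp <- grads$cbam_Wsp + cbk$dW
  grads$cbam_bsp <- grads$cbam_bsp + cbk$db
  ph <- plans$u + 2 * plans$cbam_pad; pw <- plans$v + 2 * plans$cbam_pad
  dmean_map <- cbk$dX[cb$interior, , drop = FALSE]
  dmax_map <- cbk$dX[cb$interior + ph * pw, , drop = FALSE]
  dA4c <- dA4c + as.vector(dmean_map) / z
  idx_max <- cbind(seq_len(uv * n), cb$ridx)
  dA4c[idx_max] <- dA4c[idx_max] + as.vector(dmax_map)
  # channel gate
  dA4 <- dA4c * cb$gexp
  tmp <- dA4c * A4; dim(tmp) <- c(uv, n * z)
  dgc <- matrix(colSums(tmp), n, z)
  dssum <- dgc * cb$gate_c * (1 - cb$gate_c)
  # two shared-MLP branches
  dh_avg <- act_backward(dssum %*% t(params$cbam_W2), cb$h_avg_pre, act)
  dh_max <- act_backward(dssum %*% t(params$cbam_W2), cb$h_max_pre, act)
  grads$cbam_W2 <- grads$cbam_W2 + crossprod(cb$h_avg, dssum) + crossprod(cb$h_max, dssum)
  grads$cbam_b2 <- grads$cbam_b2 + 2 * colSums(dssum)
  grads$cbam_W1 <- grads$cbam_W1 + crossprod(cb$avg_c, dh_avg) + crossprod(cb$max_c, dh_max)
  grads$cbam_b1 <- grads$cbam_b1 + colSums(dh_avg) + colSums(dh_max)
  davg <- dh_avg %*% t(params$cbam_W1)
  dmax_c <- dh_max %*% t(params$cbam_W1)
  dA4 <- dA4 + davg[rep(seq_len(n), each = uv), , drop = FALSE] / uv
  # scatter max-pool gradient to argmax positions
  dmx_flat <- as.vector(dmax_c) # (n*z)
  pos_flat <- (seq_len(n * z) - 1) * uv + cb$mxi # index into (uv, n*z)
  dA4_flat <- dA4; dim(dA4_flat) <- c(uv, n * z)
  dA4_flat[pos_flat] <- dA4_flat[pos_flat] + dmx_flat
  dim(dA4_flat) <- c(uv * n, z)
  list(dA4 = dA4_flat, grads = grads)
}

# Backward pass; returns grads (named like params).
sst_backward <- function(params, cfg, plans, cache, dlogits) {
  n <- cache$n
  act <- cfg$activation
  z <- cfg$shapes$z
  uv <- cache$uv
  grads <- lapply(params, function(x) x * 0)

  if (cfg$use_tokenizer) {
    te <- cache$te
    w <- cfg$n_tokens; w1 <- w + 1L
    h <- cfg$n_heads; dK <- z / h
    grads$head_W <- crossprod(te$cls_out, dlogits)
    grads$head_b <- colSums(dlogits)
    dout <- matrix(0, w1 * n, z)
    cls_rows <- (seq_len(n) - 1) * w1 + 1L
    dout[cls_rows, ] <- dlogits %*% t(params$head_W)
    # out = x1 + M
    dM <- dout
    if (!is.null(te$drop_masks)) dM <- dM * te$drop_masks$mlp
    grads$mlp_W2 <- crossprod(te$Ha, dM)
    grads$mlp_b2 <- colSums(dM)
    dHa <- dM %*% t(params$mlp_W2)
    dH1 <- act_backward(dHa, te$H1, act)
    grads$mlp_W1 <- crossprod(te$l2$y, dH1)
    grads$mlp_b1 <- colSums(dH1)
    dxn2 <- dH1 %*% t(params$mlp_W1)
    l2b <- ln_backward(dxn2, te$l2, params$ln2_g)
    grads$ln2_g <- l2b$dgamma; grads$ln2_b <- l2b$dbeta
    dx1 <- dout + l2b$dx
    # x1 = TKm + msa
    dmsa <- dx1
    if (!is.null(te$drop_masks)) dmsa <- dmsa * te$drop_masks$msa
    grads$Wo <- crossprod(te$O, dmsa)
    grads$bo <- colSums(dmsa)
    dO <- dmsa %*% t(params$Wo)
    dQ <- matrix(0, w1 * n, z); dKm <- matrix(0, w1 * n, z); dV <- matrix(0, w1 * n, z)
    for (s_i in seq_len(n)) {
      rows <- (s_i - 1) * w1 + seq_len(w1)
      for (hd in seq_len(h)) {
        cols <- (hd - 1) * dK + seq_len(dK)
        Ah <- te$attn[[s_i]][[hd]]
        dOh <- dO[rows, cols, drop = FALSE]
        Vh <- te$V[rows, cols, drop = FALSE]
        dAh <- tcrossprod(dOh, Vh)
        dV[rows, cols] <- crossprod(Ah, dOh)
        dsc <- (dAh - rowSums(dAh * Ah)) * Ah / sqrt(dK)
        dQ[rows, cols] <- dsc %*% te$K[rows, cols, drop = FALSE]
        dKm[rows, cols] <- crossprod(dsc, te$Q[rows, cols, drop = FALSE])
      }
    }
    grads$Wq <- crossprod(te$l1$y, dQ)
    grads$Wk <- crossprod(te$l1$y, dKm)
    grads$Wv <- crossprod(te$l1$y, dV)
    dxn1 <- dQ %*% t(params$Wq) + dKm %*% t(params$Wk) + dV %*% t(params$Wv)
    l1b <- ln_backward(dxn1, te$l1, params$ln1_g)
    grads$ln1_g <- l1b$dgamma; grads$ln1_b <- l1b$dbeta
    dTKm <- dx1 + l1b$dx
    # back to per-sample tokens
    dim(dTKm) <- c(w1, n, z)
    dTK <- aperm(dTKm, c(1, 3, 2)) # (w1, z, n)
    grads$posemb <- apply(dTK, c(1, 2), sum)
    grads$cls <- grads$posemb[1, ]
    grads$posemb <- grads$posemb # cls row of posemb gradient stays as is
    A <- cache$tok$A
    dG2 <- matrix(0, uv * n, z)
    G2 <- cache$G2
    for (s_i in seq_len(n)) {
      rowsG <- (s_i - 1) * uv + seq_len(uv)
      Gs <- G2[rowsG, , drop = FALSE]
      As <- A[, s_i + (seq_len(w) - 1) * n, drop = FALSE]
      dTs <- t(dTK[-1, , s_i, drop = TRUE]) # (z, w) -> transpose below
      if (w == 1) dTs <- matrix(dTK[2, , s_i], z, 1)
      dTs <- t(dTs) # (w, z)
      dG2[rowsG, ] <- As %*% dTs
      dAs <- Gs %*% t(dTs) # (uv, w)
      dS <- (dAs - matrix(colSums(dAs * As), uv, w, byrow = TRUE)) * As
      grads$tok_Wa <- grads$tok_Wa + crossprod(Gs, dS)
      dG2[rowsG, ] <- dG2[rowsG, ] + dS %*% t(params$tok_Wa)
    }
  } else {
    fc <- cache$fc
    grads$fc_W2 <- crossprod(fc$Fa, dlogits)
    grads$fc_b2 <- colSums(dlogits)
    dFa <- dlogits %*% t(params$fc_W2)
    dF1 <- act_backward(dFa, fc$F1, act)
    grads$fc_W1 <- crossprod(fc$Gf, dF1)
    grads$fc_b1 <- colSums(dF1)
    dGf <- dF1 %*% t(params$fc_W1) # (n, uv*z)
    dim(dGf) <- c(n, uv, z)
    dG2 <- aperm(dGf, c(2, 1, 3)); dim(dG2) <- c(uv * n, z)
  }

  if (cfg$use_cbam) {
    cbb <- cbam_backward(dG2, params, cfg, plans, cache$cbam, cache$A4, uv, n,
                         act, grads)
    dA4 <- cbb$dA4
    grads <- cbb$grads
  } else {
    dA4 <- dG2
  }

  if (cfg$use_cnn) {
    pl <- plans$conv2d
    dy <- act_backward(dA4, cache$conv2d$ypre, act)
    if (cfg$batchnorm) {
      bb <- bn_backward(dy, cache$bn2d, params$bn2d_g)
      grads$bn2d_g <- bb$dgamma; grads$bn2d_b <- bb$dbeta
      dy <- bb$dx
    }
    cb <- conv_backward(dy, pl, params$conv2d_W, cache$conv2d$xg, n)
    grads$conv2d_W <- cb$dW; grads$conv2d_b <- cb$db
    dcur <- cb$dX
    for (l in rev(seq_along(cfg$conv3d_kernels))) {
      pl <- plans[[paste0("conv", l)]]
      dyl <- input_to_conv(dcur, pl$npos, n, pl$cout)
      dyl <- act_backward(dyl, cache[[paste0("conv", l)]]$ypre, act)
      if (cfg$batchnorm) {
        bb <- bn_backward(dyl, cache[[paste0("bn", l)]],
                          params[[paste0("bn", l, "_g")]])
        grads[[paste0("bn", l, "_g")]] <- bb$dgamma
        grads[[paste0("bn", l, "_b")]] <- bb$dbeta
        dyl <- bb$dx
      }
      cb <- conv_backward(dyl, pl, params[[paste0("conv", l, "_W")]],
                          cache[[paste0("conv", l)]]$xg, n, need_dx = l > 1)
      grads[[paste0("conv", l, "_W")]] <- cb$dW
      grads[[paste0("conv", l, "_b")]] <- cb$db
      if (l > 1) dcur <- cb$dX
    }
  } else {
    dproj <- dA4
    grads$proj_W <- crossprod(cache$proj$xp, dproj)
    grads$proj_b <- colSums(dproj)
  }
  grads
}

#' Train the spectral-spatial tokenized-transformer classifier
#'
#' Minimises softmax cross-entropy with Adam. Training is deterministic
#' given `seed` (weight initialisation, batch shuffling and dropout all draw
#' from it).
#'
#' @param patches a [patch_set] with labels covering >= 2 classes.
#' @param config an [sst_config]; its `(s, b)` must match the patch set.
#' @param epochs,batch_size,lr training hyperparameters (defaults 100 / 32 /
#'   1e-3).
#' @param lr_decay multiplicative learning-rate decay factor applied every
#'   `decay_every` epochs (default 1 = constant rate).
#' @param decay_every epochs between decay steps.
#' @param seed integer seed.
#' @param verbose print per-epoch loss and accuracy.
#' @return object of class `sst_model` with elements `params`, `config`,
#'   `bn_state`, `log` (per-epoch data frame), `classes` (label ids seen).
#' @export
train_sst <- function(patches, config, epochs = 100, batch_size = 32,
                      lr = 1e-3, lr_decay = 1, decay_every = 10, seed = 1,
                      verbose = FALSE) {
  stopifnot(inherits(patches, "patch_set"), inherits(config, "sst_config"))
  if (patches$s != config$s || patches$b != config$b) {
    stop("patch geometry does not match the model configuration")
  }
  classes <- sort(unique(patches$labels))
  if (length(classes) < 2) stop("training labels contain a single class")
  y <- match(patches$labels, classes)

  init <- sst_init(config, seed = seed)
  params <- init$params; bn_state <- init$bn_state; plans <- init$plans
  opt <- adam_init(params)
  n <- length(y)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed + 1L)
  log <- data.frame(epoch = integer(), loss = numeric(), accuracy = numeric())

  for (ep in seq_len(epochs)) {
    lr_ep <- lr * lr_decay^((ep - 1) %/% decay_every)
    ord <- sample.int(n)
    tot_loss <- 0; tot_correct <- 0
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- patches$patches[, , , idx, drop = FALSE]
      fw <- sst_forward(params, config, plans, bn_state, Xb, training = TRUE)
      bn_state <- fw$bn_state
      ce <- softmax_ce(fw$logits, y[idx])
      grads <- sst_backward(params, config, plans, fw$cache, ce$dlogits)
      st <- adam_step(params, grads, opt, lr_ep)
      params <- st$params; opt <- st$state
      tot_loss <- tot_loss + ce$loss * length(idx)
      tot_correct <- tot_correct + sum(max.col(ce$probs, ties.method = "first") == y[idx])
    }
    log <- rbind(log, data.frame(epoch = ep, loss = tot_loss / n,
                                 accuracy = tot_correct / n))
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  acc %.3f", ep, tot_loss / n,
                      tot_correct / n))
    }
  }
  structure(list(params = params, config = config, bn_state = bn_state,
                 plans = plans, log = log, classes = classes,
                 class_names = patches$class_names, seed = seed),
            class = "sst_model")
}

#' @export
print.sst_model <- function(x, ...) {
  cat(sprintf("<sst_model> %d classes, final training accuracy %.3f\n",
              length(x$classes), utils::tail(x$log$accuracy, 1)))
  invisible(x)
}

#' Predict nutrient-stress classes for patches
#'
#' @param object a trained [sst_model].
#' @param patches a [patch_set] or an (s, s, b, n) array.
#' @param type `"class"` (default) for hard labels (argmax, ties to the
#'   lowest class id) or `"prob"` for the full per-class probability matrix.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return integer labels or an n x Z probability matrix.
#' @export
predict.sst_model <- function(object, patches, type = c("class", "prob"),
                              batch_size = 32, ...) {
  type <- match.arg(type)
  X <- if (inherits(patches, "patch_set")) patches$patches else patches
  n <- dim(X)[4]
  probs <- matrix(0, n, object$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- sst_forward(object$params, object$config, object$plans,
                      object$bn_state, X[, , , idx, drop = FALSE],
                      training = FALSE)
    probs[idx, ] <- softmax_rows(fw$logits)
  }
  if (type == "prob") return(probs)
  object$classes[max.col(probs[, seq_along(object$classes), drop = FALSE],
                         ties.method = "first")]
}

# loss for a parameter vector (used by the finite-difference gradient check)
sst_loss <- function(params, cfg, plans, bn_state, X, y) {
  fw <- sst_forward(params, cfg, plans, bn_state, X, training = TRUE)
  softmax_ce(fw$logits, y)$loss
}
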