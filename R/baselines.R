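# Comparison classifiers: spectral-only models (SVM, 1D-CNN) consume
# per-pixel spectra; the spatial-spectral 3D-CNN consumes patches. All share
# the predict(type = "class"/"prob") interface of the main model.

#' SVM baseline on spectra
#'
#' RBF-kernel support vector machine with a small (C, gamma) grid search by
#' internal cross-validation on the training split only.
#'
#' @param spectra n x D matrix of training spectra.
#' @param labels integer class labels.
#' @param seed integer seed (controls the internal CV folds).
#' @param cost_grid,gamma_scale grids for the search; gamma candidates are
#'   `gamma_scale / D`.
#' @return object of class `svm_baseline`.
#' @export
baseline_svm <- function(spectra, labels, seed = 1, cost_grid = c(1, 10, 100),
                         gamma_scale = c(0.5, 1, 2)) {
  spectra <- as.matrix(spectra)
  if (length(unique(labels)) < 2) stop("training labels contain a single class")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  y <- factor(labels)
  gam <- gamma_scale / ncol(spectra)
  best <- NULL; best_acc <- -1
  n <- nrow(spectra)
  folds <- sample(rep_len(1:3, n))
  for (cc in cost_grid) for (g in gam) {
    acc <- 0
    for (f in 1:3) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) next
      fit <- e1071::svm(spectra[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = cc, gamma = g)
      acc <- acc + mean(predict(fit, spectra[!tr, , drop = FALSE]) == y[!tr])
    }
    if (acc > best_acc) { best_acc <- acc; best <- c(cost = cc, gamma = g) }
  }
  fit <- e1071::svm(spectra, y, kernel = "radial", cost = best["cost"],
                    gamma = best["gamma"])
  structure(list(fit = fit, cost = best["cost"], gamma = best["gamma"],
                 classes = as.integer(levels(y))),
            class = "svm_baseline")
}

#' @export
predict.svm_baseline <- function(object, spectra, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (type == "prob") stop("the SVM baseline reports hard labels only")
  as.integer(as.character(predict(object$fit, as.matrix(spectra))))
}

#' 1-D CNN baseline on spectra
#'
#' Two 1-D convolutions along the spectral axis (16 kernels of width 7, 32
#' of width 5, valid mode, ReLU) whose feature maps are flattened into a
#' dense layer and a linear head; trained with Adam on softmax
#' cross-entropy. The flatten (rather than a global pooling) keeps
#' wavelength position information, which is where nutrient-stress classes
#' differ. A spectral-only reference: it sees each pixel's spectrum, never
#' its neighbourhood.
#'
#' @param spectra n x D training spectra (D >= 11 for the default kernels).
#' @param labels integer class labels.
#' @param epochs,batch_size,lr,seed training hyperparameters.
#' @param hidden dense-layer width.
#' @return object of class `cnn1d_model`.
#' @export
baseline_cnn1d <- function(spectra, labels, epochs = 60, batch_size = 32,
                           lr = 1e-3, seed = 1, hidden = 64) {
  spectra <- as.matrix(spectra)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("training labels contain a single class")
  y <- match(labels, classes)
  D <- ncol(spectra); Z <- length(classes)
  plan1 <- conv_plan(c(D, 1, 1, 1), c(7, 1, 1), 16, "conv1d_1")
  plan2 <- conv_plan(c(plan1$outshape[1], 1, 1, 16), c(5, 1, 1), 32, "conv1d_2")
  nfeat <- plan2$npos * 32
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  p <- list(W1 = he_init(plan1$ksz, 16, plan1$ksz), b1 = numeric(16),
            W2 = he_init(plan2$ksz, 32, plan2$ksz), b2 = numeric(32),
            Wf = he_init(nfeat, hidden, nfeat), bf = numeric(hidden),
            Wh = xavier_init(hidden, Z), bh = numeric(Z))
  opt <- adam_init(p)
  n <- nrow(spectra)
  log <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      nb <- length(idx)
      X <- t(spectra[idx, , drop = FALSE]) # (D, nb)
      c1 <- conv_forward(X, plan1, p$W1, p$b1)
      a1 <- pmax(c1$y, 0)
      cur <- conv_to_input(a1, plan1$npos, nb, 16)
      c2 <- conv_forward(cur, plan2, p$W2, p$b2)
      a2 <- pmax(c2$y, 0)
      flat <- t(conv_to_input(a2, plan2$npos, nb, 32)) # (nb, nfeat)
      f1 <- flat %*% p$Wf
      f1 <- f1 + rep(p$bf, each = nb)
      fa <- pmax(f1, 0)
      logits <- fa %*% p$Wh
      logits <- logits + rep(p$bh, each = nb)
      ce <- softmax_ce(logits, y[idx])
      g <- list(Wh = crossprod(fa, ce$dlogits), bh = colSums(ce$dlogits))
      dfa <- ce$dlogits %*% t(p$Wh)
      df1 <- dfa * (f1 > 0)
      g$Wf <- crossprod(flat, df1); g$bf <- colSums(df1)
      dflat <- df1 %*% t(p$Wf)
      da2 <- input_to_conv(t(dflat), plan2$npos, nb, 32)
      dy2 <- da2 * (c2$y > 0)
      b2k <- conv_backward(dy2, plan2, p$W2, c2$xg, nb)
      g$W2 <- b2k$dW; g$b2 <- b2k$db
      dy1 <- input_to_conv(b2k$dX, plan1$npos, nb, 16) * (c1$y > 0)
      b1k <- conv_backward(dy1, plan1, p$W1, c1$xg, nb, need_dx = FALSE)
      g$W1 <- b1k$dW; g$b1 <- b1k$db
      st <- adam_step(p, g, opt, lr); p <- st$params; opt <- st$state
    }
    log[ep] <- ce$loss
  }
  structure(list(params = p, plans = list(plan1 = plan1, plan2 = plan2),
                 hidden = hidden, classes = classes, log = log),
            class = "cnn1d_model")
}

#' @export
predict.cnn1d_model <- function(object, spectra, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- object$params
  X <- t(as.matrix(spectra)); nb <- ncol(X)
  a1 <- pmax(conv_forward(X, object$plans$plan1, p$W1, p$b1)$y, 0)
  cur <- conv_to_input(a1, object$plans$plan1$npos, nb, 16)
  a2 <- pmax(conv_forward(cur, object$plans$plan2, p$W2, p$b2)$y, 0)
  flat <- t(conv_to_input(a2, object$plans$plan2$npos, nb, 32))
  fa <- pmax(flat %*% p$Wf + rep(p$bf, each = nb), 0)
  logits <- fa %*% p$Wh
  logits <- logits + rep(p$bh, each = nb)
  probs <- softmax_rows(logits)
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}

#' 3-D CNN baseline on patches
#'
#' Two valid-mode 3-D convolutions (8 kernels of 3x3x7, 16 of 3x3x5, ReLU)
#' on the spectral-spatial patch, flattened into a 64-unit dense layer and a
#' linear head. The spatial-spectral reference model.
#'
#' @param patches a [patch_set].
#' @param epochs,batch_size,lr,seed training hyperparameters.
#' @param hidden dense-layer width.
#' @return object of class `cnn3d_model`.
#' @export
baseline_cnn3d <- function(patches, epochs = 60, batch_size = 32, lr = 1e-3,
                           seed = 1, hidden = 64) {
  stopifnot(inherits(patches, "patch_set"))
  classes <- sort(unique(patches$labels))
  if (length(classes) < 2) stop("training labels contain a single class")
  y <- match(patches$labels, classes)
  s <- patches$s; b <- patches$b; Z <- length(classes)
  plan1 <- conv_plan(c(s, s, b, 1), c(3, 3, 7), 8, "conv3d_1")
  plan2 <- conv_plan(plan1$outshape, c(3, 3, 5), 16, "conv3d_2")
  nfeat <- prod(plan2$outshape)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  p <- list(W1 = he_init(plan1$ksz, 8, plan1$ksz), b1 = numeric(8),
            W2 = he_init(plan2$ksz, 16, plan2$ksz), b2 = numeric(16),
            Wf = he_init(nfeat, hidden, nfeat), bf = numeric(hidden),
            Wh = xavier_init(hidden, Z), bh = numeric(Z))
  opt <- adam_init(p)
  n <- length(y)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      nb <- length(idx)
      X <- patches$patches[, , , idx, drop = FALSE]
      dim(X) <- c(s * s * b, nb)
      c1 <- conv_forward(X, plan1, p$W1, p$b1)
      a1 <- pmax(c1$y, 0)
      cur <- conv_to_input(a1, plan1$npos, nb, 8)
      c2 <- conv_forward(cur, plan2, p$W2, p$b2)
      a2 <- pmax(c2$y, 0)
      flat <- t(conv_to_input(a2, plan2$npos, nb, 16)) # (nb, nfeat)
      f1 <- flat %*% p$Wf
      f1 <- f1 + rep(p$bf, each = nb)
      fa <- pmax(f1, 0)
      logits <- fa %*% p$Wh
      logits <- logits + rep(p$bh, each = nb)
      ce <- softmax_ce(logits, y[idx])
      g <- list(Wh = crossprod(fa, ce$dlogits), bh = colSums(ce$dlogits))
      dfa <- ce$dlogits %*% t(p$Wh)
      df1 <- dfa * (f1 > 0)
      g$Wf <- crossprod(flat, df1); g$bf <- colSums(df1)
      dflat <- df1 %*% t(p$Wf)
      da2 <- input_to_conv(t(dflat), plan2$npos, nb, 16)
      dy2 <- da2 * (c2$y > 0)
      b2k <- conv_backward(dy2, plan2, p$W2, c2$xg, nb)
      g$W2 <- b2k$dW; g$b2 <- b2k$db
      dy1 <- input_to_conv(b2k$dX, plan1$npos, nb, 8) * (c1$y > 0)
      b1k <- conv_backward(dy1, plan1, p$W1, c1$xg, nb, need_dx = FALSE)
      g$W1 <- b1k$dW; g$b1 <- b1k$db
      st <- adam_step(p, g, opt, lr); p <- st$params; opt <- st$state
    }
  }
  structure(list(params = p, plans = list(plan1 = plan1, plan2 = plan2),
                 s = s, b = b, hidden = hidden, classes = classes),
            class = "cnn3d_model")
}

#' @export
predict.cnn3d_model <- function(object, patches, type = c("class", "prob"),
                                batch_size = 64, ...) {
  type <- match.arg(type)
  X <- if (inherits(patches, "patch_set")) patches$patches else patches
  n <- dim(X)[4]
  p <- object$params
  probs <- matrix(0, n, length(object$classes))
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    nb <- length(idx)
    Xb <- X[, , , idx, drop = FALSE]
    dim(Xb) <- c(object$s * object$s * object$b, nb)
    a1 <- pmax(conv_forward(Xb, object$plans$plan1, p$W1, p$b1)$y, 0)
    cur <- conv_to_input(a1, object$plans$plan1$npos, nb, 8)
    a2 <- pmax(conv_forward(cur, object$plans$plan2, p$W2, p$b2)$y, 0)
    flat <- t(conv_to_input(a2, object$plans$plan2$npos, nb, 16))
    fa <- pmax(flat %*% p$Wf + rep(p$bf, each = nb), 0)
    logits <- fa %*% p$Wh
    logits <- logits + rep(p$bh, each = nb)
    probs[idx, ] <- softmax_rows(logits)
  }
  if (type == "prob") return(probs)
  object$classes[max.col(probs, ties.method = "first")]
}
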