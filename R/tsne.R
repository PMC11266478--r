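#' t-SNE embedding of spectra
#'
#' Exact (dense-gradient) t-distributed stochastic neighbour embedding for
#' unsupervised visualisation of spectral libraries. Pairwise affinities use
#' per-point Gaussian bandwidths tuned by bisection to the requested
#' perplexity; the 2-D map is optimised by gradient descent with momentum
#' and early exaggeration. Complexity is O(n^2) per iteration, appropriate
#' for the hundreds-to-thousands of representative spectra typical of a
#' treatment library.
#'
#' @param spectra samples x bands numeric matrix.
#' @param perplexity effective neighbourhood size; requires
#'   `samples > 3 * perplexity`.
#' @param seed integer seed controlling the random initial map.
#' @param max_iter gradient-descent iterations (default 500).
#' @param learning_rate step size (default `max(50, n/12)`).
#' @return object of class `tsne_embedding`: list with `coords`
#'   (samples x 2), `perplexity`, `seed`.
#' @export
tsne_embed <- function(spectra, perplexity = 30, seed = 1, max_iter = 500,
                       learning_rate = NULL) {
  x <- as.matrix(spectra)
  n <- nrow(x)
  if (n <= 3 * perplexity) stop("need samples > 3 * perplexity")
  d2 <- pairwise_sq_dists(x)
  if (max(d2) < 1e-12) stop("degenerate input: all spectra identical")
  if (is.null(learning_rate)) learning_rate <- max(50, n / 12)

  P <- cond_probs(d2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  gains <- matrix(1, n, 2); inc <- matrix(0, n, 2)
  exag <- 12; stop_exag <- 100

  for (iter in seq_len(max_iter)) {
    mult <- if (iter <= stop_exag) exag else 1
    num <- 1 / (1 + pairwise_sq_dists(y)); diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (mult * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) %*% y - W %*% y)
    momentum <- if (iter <= 20) 0.5 else 0.8
    gains <- ifelse(sign(grad) != sign(inc), gains + 0.2, gains * 0.8)
    gains <- pmax(gains, 0.01)
    inc <- momentum * inc - learning_rate * gains * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  structure(list(coords = y, perplexity = perplexity, seed = seed),
            class = "tsne_embedding")
}

pairwise_sq_dists <- function(x) {
  s <- rowSums(x^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}

# Per-row Gaussian conditional probabilities at a fixed perplexity
# (bisection on the precision beta).
cond_probs <- function(d2, perplexity, tol = 1e-5, max_tries = 60) {
  n <- nrow(d2)
  P <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; beta_min <- -Inf; beta_max <- Inf
    di <- d2[i, -i]
    for (try in seq_len(max_tries)) {
      p <- exp(-di * beta)
      sum_p <- sum(p)
      if (sum_p < 1e-300) { h <- 0; p[] <- 0 } else {
        h <- log(sum_p) + beta * sum(di * p) / sum_p
        p <- p / sum_p
      }
      if (abs(h - log_u) < tol) break
      if (h > log_u) { beta_min <- beta
        beta <- if (is.finite(beta_max)) (beta + beta_max) / 2 else beta * 2
      } else { beta_max <- beta
        beta <- if (is.finite(beta_min)) (beta + beta_min) / 2 else beta / 2
      }
    }
    P[i, -i] <- p
  }
  P
}
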