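#' Superpixel map
#'
#' A complete partition of the image plane into 4-connected segments,
#' ids 0..(K-1).
#'
#' @param segment_ids integer M x N matrix of 0-based segment ids.
#' @return object of class `superpixel_map` with elements `segment_ids` and
#'   `n_segments`.
#' @export
superpixel_map <- function(segment_ids) {
  m <- matrix(as.integer(segment_ids), nrow(segment_ids), ncol(segment_ids))
  ids <- sort(unique(as.vector(m)))
  if (!identical(ids, seq_along(ids) - 1L)) stop("segment ids must be 0..(K-1) with no gaps")
  structure(list(segment_ids = m, n_segments = length(ids)),
            class = "superpixel_map")
}

#' @export
print.superpixel_map <- function(x, ...) {
  cat(sprintf("<superpixel_map> %d x %d, %d segments\n",
              nrow(x$segment_ids), ncol(x$segment_ids), x$n_segments))
  invisible(x)
}

#' Entropy-rate superpixel segmentation
#'
#' Partitions a single-band intensity image (normally the first
#' principal-component image) into about `n_segments` compact, 4-connected
#' segments. The default method is a greedy graph construction on the
#' 4-neighbour pixel lattice maximising the entropy rate of a random walk on
#' the selected edge set plus a balancing term on segment sizes: starting
#' from singleton segments, the cross-segment edge with the largest gain in
#' `H + lambda * B` is merged until `n_segments` remain. Edge similarities
#' are Gaussian in intensity difference, so merges stop at strong intensity
#' boundaries. A k-means (SLIC-style) fallback is available via
#' `method = "kmeans"`.
#'
#' @param image numeric M x N matrix, finite values.
#' @param n_segments target number of segments K, 1 <= K <= M*N.
#' @param method `"ers"` (default) or `"kmeans"`.
#' @param lambda balancing weight, relative to the largest initial
#'   entropy-rate gain (default 2).
#' @param sigma kernel bandwidth for edge similarity; default is the sd of
#'   neighbour intensity differences.
#' @param compactness spatial weight of the k-means fallback.
#' @return a [superpixel_map].
#' @export
segment_superpixels <- function(image, n_segments, method = c("ers", "kmeans"),
                                lambda = 2, sigma = NULL, compactness = 0.2) {
  method <- match.arg(method)
  if (!is.matrix(image) || anyNA(image) || any(!is.finite(image))) {
    stop("image must be a finite numeric matrix")
  }
  h <- nrow(image); w <- ncol(image); n <- h * w
  if (n_segments < 1 || n_segments > n) stop("n_segments must lie in [1, M*N]")
  if (n_segments == n) return(superpixel_map(matrix(seq_len(n) - 1L, h, w)))
  seg <- if (method == "ers") ers_segment(image, n_segments, lambda, sigma)
         else slic_segment(image, n_segments, compactness)
  superpixel_map(seg)
}

lattice_edges <- function(h, w) {
  # 4-neighbour lattice; column-major pixel ids
  id <- matrix(seq_len(h * w), h, w)
  ea <- c(as.vector(id[-h, , drop = FALSE]), as.vector(id[, -w, drop = FALSE]))
  eb <- c(as.vector(id[-1, , drop = FALSE]), as.vector(id[, -1, drop = FALSE]))
  cbind(ea, eb)
}

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

ers_segment <- function(image, k, lambda_rel, sigma) {
  h <- nrow(image); w <- ncol(image); n <- h * w
  intens <- as.vector(image)
  ed <- lattice_edges(h, w)
  dif <- intens[ed[, 1]] - intens[ed[, 2]]
  # robust bandwidth: dominated by within-region gradients, not by the few
  # large boundary jumps that would wash weak boundaries out
  if (is.null(sigma)) sigma <- max(2 * mean(abs(dif)), 1e-9)
  ew <- exp(-dif^2 / (2 * sigma^2))
  ne <- nrow(ed)

  wdeg <- numeric(n) # full-graph node weights (stationary distribution)
  for (s in 1:2) {
    acc <- tapply(ew, ed[, s], sum)
    wdeg[as.integer(names(acc))] <- wdeg[as.integer(names(acc))] + acc
  }
  wtot <- sum(wdeg)
  mu <- wdeg / wtot
  ssum <- numeric(n)     # selected incident edge weight per node
  parent <- seq_len(n)
  csize <- rep(1L, n)
  ncomp <- n

  phi <- function(p) ifelse(p > 0, -p * log(p), 0)
  loop_term <- function(s, wd) phi(1 - s / wd)

  gain_h <- function(e) {
    a <- ed[e, 1]; b <- ed[e, 2]; v <- ew[e]
    mu[a] * (phi(v / wdeg[a]) + loop_term(ssum[a] + v, wdeg[a]) - loop_term(ssum[a], wdeg[a])) +
    mu[b] * (phi(v / wdeg[b]) + loop_term(ssum[b] + v, wdeg[b]) - loop_term(ssum[b], wdeg[b]))
  }
  gain_b <- function(p, q) {
    phi((p + q) / n) - phi(p / n) - phi(q / n) + 1
  }

  g_h0 <- vapply(seq_len(ne), gain_h, numeric(1))
  gmax <- max(g_h0)
  lambda <- lambda_rel * gmax
  # Similarity-weighted affinity term: the entropy-rate gain of an edge that
  # saturates a node's transition mass degenerates to zero, which would let
  # near-zero-similarity boundary edges outrank strong interior edges late in
  # the merge; weighting by the raw edge similarity keeps boundary adherence.
  # On a constant image all similarities are equal and the term is inert.
  kappa <- gmax
  gains <- g_h0 + lambda * gain_b(1, 1) + kappa * ew

  while (ncomp > k) {
    e <- which.max(gains)
    if (!is.finite(gains[e])) break
    ra <- uf_find(parent, ed[e, 1]); rb <- uf_find(parent, ed[e, 2])
    if (ra == rb) { gains[e] <- -Inf; next }
    g_new <- gain_h(e) + lambda * gain_b(csize[ra], csize[rb]) + kappa * ew[e]
    if (g_new < gains[e] - 1e-12) { gains[e] <- g_new; next } # lazy re-sort
    # accept merge
    a <- ed[e, 1]; b <- ed[e, 2]
    ssum[a] <- ssum[a] + ew[e]; ssum[b] <- ssum[b] + ew[e]
    if (csize[ra] < csize[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
    parent[rb] <- ra
    csize[ra] <- csize[ra] + csize[rb]
    ncomp <- ncomp - 1L
    gains[e] <- -Inf
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  matrix(match(comp, unique(comp)) - 1L, h, w)
}

slic_segment <- function(image, k, compactness) {
  h <- nrow(image); w <- ncol(image); n <- h * w
  s_grid <- sqrt(n / k)
  rr <- rep(seq_len(h), times = w); cc <- rep(seq_len(w), each = h)
  feat <- cbind(as.vector(image), rr * compactness / s_grid,
                cc * compactness / s_grid)
  # deterministic grid initialisation
  gr <- max(1L, round(sqrt(k * h / w))); gc <- ceiling(k / gr)
  ctr_r <- round(seq(1, h, length.out = gr + 2))[2:(gr + 1)]
  ctr_c <- round(seq(1, w, length.out = gc + 2))[2:(gc + 1)]
  centers0 <- as.matrix(expand.grid(ctr_r, ctr_c))[seq_len(min(k, gr * gc)), , drop = FALSE]
  init <- feat[(centers0[, 2] - 1L) * h + centers0[, 1], , drop = FALSE]
  km <- stats::kmeans(feat, centers = init, iter.max = 30)
  seg <- matrix(km$cluster, h, w)
  relabel_connected(seg, min_size = max(4L, floor(n / k / 4)))
}

# split clusters into 4-connected components and absorb tiny fragments into
# their most frequent neighbouring segment
relabel_connected <- function(seg, min_size) {
  h <- nrow(seg); w <- ncol(seg)
  comp <- matrix(0L, h, w); cur <- 0L
  for (start in which(comp == 0L)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start; comp[start] <- cur
    while (length(queue)) {
      p <- queue[length(queue)]; queue <- queue[-length(queue)]
      r <- ((p - 1L) %% h) + 1L; cl <- ((p - 1L) %/% h) + 1L
      for (q in c(if (r > 1) p - 1L, if (r < h) p + 1L,
                  if (cl > 1) p - h, if (cl < w) p + h)) {
        if (comp[q] == 0L && seg[q] == seg[p]) { comp[q] <- cur; queue <- c(queue, q) }
      }
    }
  }
  sizes <- tabulate(comp, cur)
  repeat {
    small <- which(sizes > 0 & sizes < min_size)
    if (!length(small)) break
    ed <- lattice_edges(h, w)
    ca <- comp[ed[, 1]]; cb <- comp[ed[, 2]]
    changed <- FALSE
    for (s in small) {
      nb <- c(cb[ca == s], ca[cb == s]); nb <- nb[nb != s]
      if (!length(nb)) next
      tgt <- as.integer(names(which.max(table(nb))))
      comp[comp == s] <- tgt
      sizes[tgt] <- sizes[tgt] + sizes[s]; sizes[s] <- 0L
      changed <- TRUE
    }
    if (!changed) break
  }
  matrix(match(comp, sort(unique(as.vector(comp)))) - 1L, h, w)
}
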