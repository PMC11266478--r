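#' PCA of a set of spectra
#'
#' Mean-centred, covariance-based principal component analysis (no band
#' standardisation: all bands share reflectance units). Loadings are
#' unit-norm with a deterministic sign convention — each component's entry
#' of largest magnitude is positive — so results are comparable across runs
#' and implementations.
#'
#' @param spectra samples x bands numeric matrix.
#' @param k number of components to retain; must satisfy
#'   `k <= min(samples - 1, bands)`.
#' @return object of class `spectral_pca`: list with `loadings` (bands x k),
#'   `explained_variance_ratio` (length k, nonincreasing, sums to <= 1),
#'   `scores` (samples x k), and `center` (band means).
#' @examples
#' s <- matrix(rnorm(200), 20, 10)
#' p <- spectral_pca(s, 3)
#' p$explained_variance_ratio
#' @export
spectral_pca <- function(spectra, k) {
  spectra <- as.matrix(spectra)
  n <- nrow(spectra); d <- ncol(spectra)
  if (n <= k) stop("need more samples than components")
  if (k > min(n - 1, d)) stop("k exceeds min(samples - 1, bands)")
  pc <- stats::prcomp(spectra, center = TRUE, scale. = FALSE, rank. = k)
  total_var <- sum(apply(spectra, 2, stats::var))
  ratio <- pc$sdev[seq_len(k)]^2 / total_var
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = unname(loadings),
                 explained_variance_ratio = unname(ratio),
                 scores = unname(scores),
                 center = unname(pc$center)),
            class = "spectral_pca")
}

#' @export
print.spectral_pca <- function(x, ...) {
  cat(sprintf("<spectral_pca> %d components; explained variance: %s\n",
              ncol(x$loadings),
              paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio),
                    collapse = ", ")))
  invisible(x)
}

#' First principal-component image
#'
#' Projects every pixel spectrum onto the first principal component of the
#' pixelwise spectra and rescales the projection to [0, 1]; this is the
#' single-band intensity image that drives superpixel segmentation.
#'
#' @param cube an [hsi_cube] with at least 2 bands.
#' @return M x N numeric matrix in [0, 1], with the PC1 loading vector
#'   attached as attribute `"loading"`.
#' @export
first_pc_image <- function(cube) {
  stopifnot(inherits(cube, "hsi_cube"))
  d <- dim(cube$values)
  if (d[3] < 2) stop("need at least 2 bands for a principal component")
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  if (all(abs(sweep(flat, 2, flat[1, ])) < 1e-12)) {
    stop("constant cube: first principal component undefined")
  }
  p <- spectral_pca(flat, 1)
  img <- matrix(p$scores[, 1], d[1], d[2])
  rng <- range(img)
  img <- if (diff(rng) > 0) (img - rng[1]) / diff(rng) else img * 0
  attr(img, "loading") <- p$loadings[, 1]
  img
}
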