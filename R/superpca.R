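#' Superpixelwise PCA reduction
#'
#' Reduces a D-band cube to `b` bands by running an independent,
#' mean-centred PCA inside every superpixel of `segmap` and projecting each
#' segment's pixels onto its own top-`b` components, leaving the spatial
#' dimensions intact. Regions are spectrally near-homogeneous, so a local
#' basis captures local variation with far fewer bands than a global one.
#' Segments with fewer pixels than `b + 1` cannot support a local basis and
#' fall back to the global-image loadings.
#'
#' With a single-segment map this degenerates to ordinary global PCA.
#'
#' @param cube an [hsi_cube] with D bands.
#' @param segmap a [superpixel_map] matching the cube's spatial dims.
#' @param b target band count, 1 <= b <= D.
#' @return object of class `reduced_cube`: list with `values` (M x N x b
#'   array of component scores), `b`, and `provenance` (per-segment loadings
#'   and the fallback flags).
#' @export
superpca_reduce <- function(cube, segmap, b) {
  stopifnot(inherits(cube, "hsi_cube"), inherits(segmap, "superpixel_map"))
  d <- dim(cube$values)
  if (b < 1 || b > d[3]) stop("b must lie in [1, D]")
  if (!all(dim(segmap$segment_ids) == d[1:2])) {
    stop("segment map does not match the cube's spatial dims")
  }
  flat <- matrix(cube$values, d[1] * d[2], d[3])
  seg <- as.vector(segmap$segment_ids)
  out <- matrix(0, d[1] * d[2], b)
  loadings <- vector("list", segmap$n_segments)
  fallback <- logical(segmap$n_segments)

  global_pca <- NULL
  for (s in seq_len(segmap$n_segments) - 1L) {
    idx <- which(seg == s)
    px <- flat[idx, , drop = FALSE]
    if (length(idx) >= b + 1) {
      p <- spectral_pca(px, b)
      out[idx, ] <- p$scores
      loadings[[s + 1]] <- p$loadings
    } else {
      if (is.null(global_pca)) global_pca <- spectral_pca(flat, b)
      ctr <- sweep(px, 2, colMeans(px))
      out[idx, ] <- ctr %*% global_pca$loadings
      loadings[[s + 1]] <- global_pca$loadings
      fallback[s + 1] <- TRUE
    }
  }
  structure(list(values = array(out, c(d[1], d[2], b)), b = b,
                 provenance = list(loadings = loadings, fallback = fallback,
                                   n_segments = segmap$n_segments)),
            class = "reduced_cube")
}

#' @export
print.reduced_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<reduced_cube> %d x %d pixels, %d bands (%d segments)\n",
              d[1], d[2], x$b, x$provenance$n_segments))
  invisible(x)
}

#' Patch set
#'
#' The network's training/evaluation unit: one S x S x B spectral-spatial
#' patch per labelled pixel, labelled by its centre pixel.
#'
#' @param patches S x S x B x n array.
#' @param centers n x 2 integer matrix of (row, col) centre positions.
#' @param labels integer class ids, length n.
#' @param class_names character vector of class names.
#' @return object of class `patch_set`.
#' @export
patch_set <- function(patches, centers, labels, class_names = NULL) {
  stopifnot(length(dim(patches)) == 4, dim(patches)[4] == length(labels),
            nrow(centers) == length(labels))
  structure(list(patches = patches, centers = centers,
                 labels = as.integer(labels), class_names = class_names,
                 s = dim(patches)[1], b = dim(patches)[3]),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d x %d x %d, %d classes\n",
              length(x$labels), x$s, x$s, x$b,
              length(unique(x$labels))))
  invisible(x)
}

#' @export
`[.patch_set` <- function(x, i) {
  patch_set(x$patches[, , , i, drop = FALSE], x$centers[i, , drop = FALSE],
            x$labels[i], x$class_names)
}

#' @export
length.patch_set <- function(x) length(x$labels)

#' Extract spectral-spatial patches around labelled pixels
#'
#' Cuts one S x S x B window per labelled (nonzero) pixel from the reduced
#' cube, zero-padding borders by (S-1)/2 so edge pixels are retrievable
#' (reflect padding available via `pad`). The patch label is the centre
#' pixel's label.
#'
#' @param reduced a [reduced_cube] (or [hsi_cube]).
#' @param labels a [label_map].
#' @param s odd window size >= 3.
#' @param pad `"zero"` (default) or `"reflect"`.
#' @return a [patch_set].
#' @export
extract_patches <- function(reduced, labels, s = 13, pad = c("zero", "reflect")) {
  pad <- match.arg(pad)
  if (s %% 2 == 0 || s < 3) stop("window size s must be odd and >= 3")
  stopifnot(inherits(labels, "label_map"))
  vals <- if (inherits(reduced, "hsi_cube") || inherits(reduced, "reduced_cube"))
    reduced$values else reduced
  d <- dim(vals)
  if (!all(dim(labels$labels) == d[1:2])) stop("label map does not match cube dims")
  hw <- (s - 1L) / 2L
  # padded array
  ph <- d[1] + 2 * hw; pw <- d[2] + 2 * hw
  padded <- array(0, c(ph, pw, d[3]))
  padded[hw + seq_len(d[1]), hw + seq_len(d[2]), ] <- vals
  if (pad == "reflect") {
    ridx <- c(rev(seq_len(hw) + 1L), seq_len(d[1]), d[1] - seq_len(hw))
    cidx <- c(rev(seq_len(hw) + 1L), seq_len(d[2]), d[2] - seq_len(hw))
    padded <- vals[ridx, cidx, , drop = FALSE]
  }
  centers <- which(labels$labels > 0L, arr.ind = TRUE)
  n <- nrow(centers)
  if (n == 0) stop("label map has no labelled pixels")
  patches <- array(0, c(s, s, d[3], n))
  for (i in seq_len(n)) {
    r <- centers[i, 1]; cc <- centers[i, 2]
    patches[, , , i] <- padded[r:(r + s - 1L), cc:(cc + s - 1L), ]
  }
  patch_set(patches, centers, labels$labels[centers],
            class_names = labels$class_names)
}

#' Subsample a label map to at most `per_class` pixels per class
#'
#' Convenience for building balanced patch sets of manageable size; pixels
#' beyond the quota are relabelled 0 (dropped), chosen at random under the
#' seed.
#'
#' @param labels a [label_map].
#' @param per_class maximum pixels retained per class.
#' @param seed integer.
#' @return a [label_map].
#' @export
subsample_labels <- function(labels, per_class, seed = 1) {
  stopifnot(inherits(labels, "label_map"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  m <- labels$labels
  for (k in seq_along(labels$class_names)) {
    idx <- which(m == k)
    if (length(idx) > per_class) {
      drop <- sample(idx, length(idx) - per_class)
      m[drop] <- 0L
    }
  }
  label_map(m, labels$class_names)
}
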