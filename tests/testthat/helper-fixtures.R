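# Shared fixtures and small independent oracles for the test suite.

make_axis <- function(n = 50, lo = 400, hi = 1000) {
  spectral_axis(seq(lo, hi, length.out = n))
}

random_cube <- function(h = 6, w = 5, d = 8, seed = 1, kind = "reflectance") {
  set.seed(seed)
  hsi_cube(array(runif(h * w * d, 0.05, 0.9), c(h, w, d)),
           seq(400, 1000, length.out = d), kind = kind)
}

# mean silhouette width from 2-D coordinates and integer labels
silhouette_mean <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  n <- nrow(coords)
  s <- numeric(n)
  for (i in seq_len(n)) {
    same <- labels == labels[i]; same[i] <- FALSE
    a <- mean(d[i, same])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(d[i, labels == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# undersegmentation error: fraction of pixels not in their segment's
# majority ground-truth region
underseg_error <- function(seg, truth) {
  tot <- 0
  for (s in unique(as.vector(seg))) {
    px <- truth[seg == s]
    tot <- tot + sum(px != as.integer(names(which.max(table(px)))))
  }
  tot / length(truth)
}

# boundary recall with 1-pixel tolerance
boundary_recall <- function(seg, truth) {
  h <- nrow(truth); w <- ncol(truth)
  dil <- function(m) {
    p <- m
    p[-1, ] <- p[-1, ] | m[-nrow(m), ]; p[-nrow(m), ] <- p[-nrow(m), ] | m[-1, ]
    p[, -1] <- p[, -1] | m[, -ncol(m)]; p[, -ncol(m)] <- p[, -ncol(m)] | m[, -1]
    p
  }
  tb <- truth[-h, ] != truth[-1, ];  sb <- dil(seg[-h, ] != seg[-1, ])
  tc <- truth[, -w] != truth[, -1];  sc <- dil(seg[, -w] != seg[, -1])
  (sum(tb & sb) + sum(tc & sc)) / (sum(tb) + sum(tc))
}

# all segments 4-connected?
segments_connected <- function(seg) {
  h <- nrow(seg); w <- ncol(seg)
  for (s in unique(as.vector(seg))) {
    px <- which(seg == s)
    comp <- integer(0); queue <- px[1]; seen <- px[1]
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- ((p - 1) %% h) + 1; cl <- ((p - 1) %/% h) + 1
      for (q in c(if (r > 1) p - 1, if (r < h) p + 1,
                  if (cl > 1) p - h, if (cl < w) p + h)) {
        if (seg[q] == s && !(q %in% seen)) { seen <- c(seen, q); queue <- c(queue, q) }
      }
    }
    if (length(seen) != length(px)) return(FALSE)
  }
  TRUE
}

# tiny smooth network configuration for gradient checks
tiny_config <- function(s = 9, b = 9, n_classes = 3, activation = "tanh", ...) {
  sst_config(s = s, b = b, n_classes = n_classes,
             conv3d_channels = c(2, 2, 4),
             conv3d_kernels = list(c(3, 3, 3), c(1, 1, 3), c(3, 3, 3)),
             conv2d_channels = 8, cbam_reduction = 4, cbam_spatial_kernel = 3,
             n_tokens = 2, n_heads = 2, mlp_dim = 16, activation = activation,
             batchnorm = TRUE, ...)
}

# Pool subsampled patch sets from a list of generated scenes; `superpca`
# FALSE substitutes a global-image PCA (single segment) at the same band
# count.
build_patchset <- function(scenes, s, b, per_class, seed, superpca = TRUE,
                           K = 20) {
  pss <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    if (superpca) {
      sp <- segment_superpixels(first_pc_image(sc$cube), K)
    } else {
      sp <- superpixel_map(matrix(0L, nrow(sc$labels$labels),
                                  ncol(sc$labels$labels)))
    }
    red <- superpca_reduce(sc$cube, sp, b)
    lab <- subsample_labels(sc$labels, per_class, seed = seed + i)
    pss[[i]] <- extract_patches(red, lab, s = s)
  }
  patches <- array(0, c(s, s, b, sum(sapply(pss, length))))
  off <- 0; labs <- integer(0); cents <- NULL
  for (ps in pss) {
    n <- length(ps)
    patches[, , , off + seq_len(n)] <- ps$patches
    labs <- c(labs, ps$labels); cents <- rbind(cents, ps$centers)
    off <- off + n
  }
  patch_set(patches, cents, labs, pss[[1]]$class_names)
}

# pooled, subsampled patch set over a plot-trial scene collection;
# `superpca` FALSE substitutes a per-scene global PCA at the same band count
build_trial_patchset <- function(scenes, s, b, per_scene, seed,
                                 superpca = TRUE, K = 6) {
  pss <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    sp <- if (superpca) {
      segment_superpixels(first_pc_image(sc$cube), K)
    } else {
      superpixel_map(matrix(0L, nrow(sc$labels$labels), ncol(sc$labels$labels)))
    }
    red <- superpca_reduce(sc$cube, sp, b)
    lab <- subsample_labels(sc$labels, per_scene, seed = seed + i)
    pss[[i]] <- extract_patches(red, lab, s = s)
  }
  patches <- array(0, c(s, s, b, sum(sapply(pss, length))))
  off <- 0; labs <- integer(0); cents <- NULL
  for (ps in pss) {
    n <- length(ps)
    patches[, , , off + seq_len(n)] <- ps$patches
    labs <- c(labs, ps$labels); cents <- rbind(cents, ps$centers)
    off <- off + n
  }
  patch_set(patches, cents, labs, pss[[1]]$class_names)
}

# matching raw per-pixel spectra (for the spectral-only baselines)
trial_spectra <- function(scenes, per_scene, seed) {
  sp <- NULL; y <- integer(0)
  for (i in seq_along(scenes)) {
    lab <- subsample_labels(scenes[[i]]$labels, per_scene, seed = seed + i)
    keep <- as.vector(lab$labels > 0)
    sp <- rbind(sp, pixel_spectra(scenes[[i]]$cube)[keep, ])
    y <- c(y, lab$labels[lab$labels > 0])
  }
  list(x = sp, y = y)
}

# cache expensive shared fixtures across test files
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# finite-difference gradient comparison over a random subset of entries
grad_check <- function(cfg, seed = 3, n_batch = 4, per_param = 3, eps = 1e-6) {
  init <- hsistress:::sst_init(cfg, seed = seed)
  set.seed(seed)
  X <- array(stats::rnorm(cfg$s * cfg$s * cfg$b * n_batch),
             c(cfg$s, cfg$s, cfg$b, n_batch))
  y <- rep_len(seq_len(cfg$n_classes), n_batch)
  fw <- hsistress:::sst_forward(init$params, cfg, init$plans, init$bn_state, X,
                                training = TRUE)
  ce <- hsistress:::softmax_ce(fw$logits, y)
  grads <- hsistress:::sst_backward(init$params, cfg, init$plans, fw$cache,
                                    ce$dlogits)
  worst <- 0
  for (nm in names(init$params)) {
    p <- init$params[[nm]]
    for (i in sample(length(p), min(per_param, length(p)))) {
      pp <- init$params; pp[[nm]][i] <- pp[[nm]][i] + eps
      lp <- hsistress:::sst_loss(pp, cfg, init$plans, init$bn_state, X, y)
      pm <- init$params; pm[[nm]][i] <- pm[[nm]][i] - eps
      lm <- hsistress:::sst_loss(pm, cfg, init$plans, init$bn_state, X, y)
      g_fd <- (lp - lm) / (2 * eps)
      g_an <- grads[[nm]][i]
      den <- max(abs(g_fd), abs(g_an))
      if (den < 1e-6) next # invariant direction (e.g. conv bias under BN)
      worst <- max(worst, abs(g_fd - g_an) / den)
    }
  }
  worst
}
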