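test_that("vegetation indices match their defining ratios", {
  w <- c(500, 531, 570, 670, 680, 750, 800)
  # NDVI
  expect_equal(ndvi(c(0, 0, 0, 0.1, 0, 0, 0.5), wavelengths = w), 2 / 3,
               tolerance = 1e-12)
  expect_equal(ndvi(c(0, 0, 0, 0.3, 0, 0, 0.3), wavelengths = w), 0)
  expect_equal(ndvi(c(0, 0, 0, 0, 0, 0, 0.4), wavelengths = w), 1)
  # PRI
  expect_equal(pri(c(0, 0.12, 0.08, 0, 0, 0, 0), wavelengths = w), 0.2)
  expect_equal(pri(rep(0.3, 7), wavelengths = w), 0)
  # PSRI
  expect_equal(psri(c(0.05, 0, 0, 0, 0.15, 0.5, 0), wavelengths = w), 0.2)
  expect_equal(psri(c(0.1, 0, 0, 0, 0.1, 0.5, 0), wavelengths = w), 0)
})

test_that("indices are scale-invariant and flag undefined pixels as NA", {
  set.seed(8)
  w <- seq(400, 1000, length.out = 30)
  s <- runif(30, 0.05, 0.8)
  for (f in list(ndvi, pri, psri)) {
    expect_equal(f(s, wavelengths = w), f(3.1 * s, wavelengths = w))
  }
  expect_true(is.na(ndvi(rep(0, 30), wavelengths = w)))
  s750 <- rep(0.4, 30)
  s750[nearest_band(spectral_axis(w), 750)] <- 0
  expect_true(is.na(psri(s750, wavelengths = w))) # rho750 = 0
})

test_that("cube indices return per-pixel maps bounded like the spectrum form", {
  sc <- fixture("scene_default", function() generate_scene(scene_config(seed = 7)))
  nd <- ndvi(sc$cube)
  expect_identical(dim(nd), dim(sc$cube$values)[1:2])
  expect_true(all(nd[!is.na(nd)] >= -1 & nd[!is.na(nd)] <= 1))
  p <- pri(sc$cube)
  expect_true(all(p[!is.na(p)] >= -1 & p[!is.na(p)] <= 1))
})

test_that("a stress class with brighter red and darker NIR scores lower NDVI", {
  trs <- default_treatments(1, seed = 1)
  ax <- make_axis(204); w <- as.numeric(ax)
  ref <- which(vapply(trs, function(t) grepl("^F", t$name), logical(1)))
  nd <- vapply(trs, function(tr) ndvi(make_endmember(tr$endmember, ax),
                                      wavelengths = w), numeric(1))
  expect_lt(nd[1], nd[ref]) # extreme N deficit vs reference
})

test_that("mean/CV profile uses the sample sd in percent", {
  expect_equal(mean_cv_profile(rbind(c(0.2, 0.3), c(0.4, 0.3)))$mean, c(0.3, 0.3))
  cv <- mean_cv_profile(rbind(c(0.2, 0.3), c(0.4, 0.3)))$cv_pct
  expect_equal(cv[1], 100 * sd(c(0.2, 0.4)) / 0.3) # 47.14%
  expect_equal(cv[1], 47.14045, tolerance = 1e-4)
  expect_equal(cv[2], 0)
  m <- matrix(runif(50, 0.1, 1), 10, 5)
  expect_equal(mean_cv_profile(m)$cv_pct, mean_cv_profile(4.2 * m)$cv_pct)
  expect_warning(mean_cv_profile(rbind(c(0, 1), c(0, 1))), "zero-mean")
})

test_that("spectral PCA agrees with a covariance eigendecomposition oracle", {
  set.seed(12)
  x <- matrix(rnorm(500), 50, 10)
  p <- spectral_pca(x, 4)
  ev <- eigen(cov(x), symmetric = TRUE)
  expect_equal(p$explained_variance_ratio,
               ev$values[1:4] / sum(ev$values), tolerance = 1e-10)
  for (j in 1:4) {
    vo <- ev$vectors[, j]
    if (vo[which.max(abs(vo))] < 0) vo <- -vo # same sign convention
    expect_equal(p$loadings[, j], vo, tolerance = 1e-8)
  }
  # scores: centred projections
  expect_equal(p$scores, sweep(x, 2, colMeans(x)) %*% p$loadings,
               tolerance = 1e-10)
})

test_that("PCA satisfies its structural invariants", {
  set.seed(13)
  x <- matrix(rnorm(300), 30, 10)
  p <- spectral_pca(x, 5)
  expect_true(all(diff(p$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(p$explained_variance_ratio), 1 + 1e-12)
  expect_equal(colMeans(p$scores), rep(0, 5), tolerance = 1e-12)
  cv <- cov(p$scores)
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-10)
  expect_equal(unname(apply(p$loadings, 2, function(v) sqrt(sum(v^2)))),
               rep(1, 5))
  # rank-1 data -> first ratio 1
  base <- runif(10)
  r1 <- outer(seq_len(20), base) + matrix(rep(runif(10), each = 20), 20)
  expect_equal(spectral_pca(r1, 2)$explained_variance_ratio[1], 1)
  expect_error(spectral_pca(x, 11), "exceeds")
})

test_that("t-SNE separates separable classes and is seed-deterministic", {
  set.seed(5)
  x <- rbind(matrix(rnorm(300, 0), 30, 10), matrix(rnorm(300, 6), 30, 10))
  lab <- rep(1:2, each = 30)
  e1 <- tsne_embed(x, perplexity = 10, seed = 2, max_iter = 300)
  expect_gt(silhouette_mean(e1$coords, lab), 0.5)
  e2 <- tsne_embed(x, perplexity = 10, seed = 2, max_iter = 300)
  expect_identical(e1$coords, e2$coords)
  expect_true(all(is.finite(e1$coords)))
  expect_error(tsne_embed(matrix(1, 40, 5), perplexity = 5), "degenerate")
  expect_error(tsne_embed(x, perplexity = 30), "perplexity")
})

test_that("low-separability treatment spectra embed as overlapping clusters", {
  sc <- generate_scene(scene_config(separability = 0.3, seed = 21))
  lab <- subsample_labels(sc$labels, 10, seed = 3)
  keep <- as.vector(lab$labels > 0)
  x <- pixel_spectra(sc$cube)[keep, ]
  y <- lab$labels[lab$labels > 0]
  emb <- tsne_embed(x, perplexity = 15, seed = 4, max_iter = 300)
  expect_lt(silhouette_mean(emb$coords, y), 0.25)
})
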