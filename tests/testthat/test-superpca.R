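test_that("superpixel segmentation honours its partition contract", {
  img <- matrix(runif(400), 20, 20)
  sp <- segment_superpixels(img, 6)
  expect_identical(sort(unique(as.vector(sp$segment_ids))), 0:(sp$n_segments - 1L))
  expect_true(segments_connected(sp$segment_ids))
  expect_identical(segment_superpixels(img, 1)$n_segments, 1L)
  expect_error(segment_superpixels(matrix(c(1, NA), 2, 2), 2), "finite")
})

test_that("a constant image splits into roughly equal connected segments", {
  sp <- segment_superpixels(matrix(0.5, 20, 20), 4)
  expect_identical(sp$n_segments, 4L)
  sizes <- tabulate(as.vector(sp$segment_ids) + 1L, 4)
  expect_true(all(sizes >= 400 / 16)) # none degenerate
  expect_true(segments_connected(sp$segment_ids))
})

test_that("segmentation recovers a 14-plot layout with hard borders", {
  sc <- fixture("plot_scene", function() {
    tr <- default_treatments(0, seed = 1)
    for (i in seq_along(tr)) {
      tr[[i]]$endmember$nir_plateau <- 0.15 + 0.05 * i
      tr[[i]]$within_class_sd <- 0.005
    }
    generate_scene(scene_config(background_fraction = 0, treatments = tr,
                                sensor_noise_sd = 0.002, seed = 5))
  })
  pc1 <- first_pc_image(sc$cube)
  sp <- segment_superpixels(pc1, 14)
  expect_lt(underseg_error(sp$segment_ids, sc$labels$labels), 0.05)
  expect_gte(boundary_recall(sp$segment_ids, sc$labels$labels), 0.9)
  # k-means fallback keeps the partition contract and decent adherence
  spk <- segment_superpixels(pc1, 14, method = "kmeans")
  expect_true(segments_connected(spk$segment_ids))
  expect_lt(abs(spk$n_segments - 14), 8)
  expect_lt(underseg_error(spk$segment_ids, sc$labels$labels), 0.5)
})

test_that("first PC image matches the eigendecomposition oracle", {
  cube <- random_cube(8, 8, 5, seed = 3)
  img <- first_pc_image(cube)
  flat <- pixel_spectra(cube)
  ev <- eigen(cov(flat), symmetric = TRUE)$vectors[, 1]
  proj <- sweep(flat, 2, colMeans(flat)) %*% ev
  proj <- (proj - min(proj)) / diff(range(proj))
  # sign convention may flip the oracle's direction
  d1 <- max(abs(as.vector(img) - proj)); d2 <- max(abs(as.vector(img) - (1 - proj)))
  expect_lt(min(d1, d2), 1e-8)
  # rank-1 cube: PC1 image proportional to the construction coefficients
  coefs <- matrix(seq(0, 1, length.out = 24), 4, 6)
  base <- runif(5, 0.2, 0.8)
  vals <- array(0, c(4, 6, 5))
  for (b in 1:5) vals[, , b] <- 0.05 + coefs * base[b]
  r1 <- first_pc_image(hsi_cube(vals, seq(400, 1000, length.out = 5)))
  expect_equal(r1[, ], (coefs - min(coefs)) / diff(range(coefs)), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(first_pc_image(hsi_cube(array(0.3, c(3, 3, 4)),
                                       c(400, 500, 600, 700))), "constant")
})

test_that("PC1 separates a two-class scene", {
  tr <- default_treatments(0, seed = 1)[1:2]
  tr[[1]]$endmember$nir_plateau <- 0.3; tr[[2]]$endmember$nir_plateau <- 0.6
  tr[[2]]$class_id <- 2L
  sc <- generate_scene(scene_config(height = 24, width = 24, n_bands = 40,
                                    treatments = tr, background_fraction = 0,
                                    seed = 8))
  img <- first_pc_image(sc$cube)
  y <- as.vector(sc$labels$labels)
  x <- as.vector(img)
  between <- (mean(x[y == 1]) - mean(x[y == 2]))^2
  within <- var(x[y == 1]) + var(x[y == 2])
  expect_gt(between, within)
})

test_that("single-segment SuperPCA degenerates to global PCA", {
  cube <- random_cube(7, 6, 10, seed = 5)
  seg1 <- superpixel_map(matrix(0L, 7, 6))
  red <- superpca_reduce(cube, seg1, 4)
  flat <- pixel_spectra(cube)
  glob <- spectral_pca(flat, 4)$scores
  out <- matrix(red$values, 42, 4)
  for (j in 1:4) {
    expect_lt(min(max(abs(out[, j] - glob[, j])),
                  max(abs(out[, j] + glob[, j]))), 1e-8)
  }
  # full-rank single segment: centred reconstruction is exact
  redD <- superpca_reduce(cube, seg1, 10)
  L <- redD$provenance$loadings[[1]]
  rec <- matrix(redD$values, 42, 10) %*% t(L)
  expect_equal(rec, sweep(flat, 2, colMeans(flat)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("per-segment reduction equals independent PCA on each segment", {
  cube <- random_cube(6, 6, 8, seed = 9)
  seg <- matrix(0L, 6, 6); seg[, 4:6] <- 1L
  sp <- superpixel_map(seg)
  red <- superpca_reduce(cube, sp, 3)
  flat <- pixel_spectra(cube)
  for (s in 0:1) {
    idx <- which(as.vector(seg) == s)
    px <- flat[idx, ]
    ev <- eigen(cov(px), symmetric = TRUE)$vectors[, 1:3]
    got <- matrix(red$values, 36, 3)[idx, ]
    want <- sweep(px, 2, colMeans(px)) %*% ev
    for (j in 1:3) {
      expect_lt(min(max(abs(got[, j] - want[, j])),
                    max(abs(got[, j] + want[, j]))), 1e-8)
    }
  }
  expect_error(superpca_reduce(cube, sp, 9), "\\[1, D\\]")
})

test_that("undersized segments fall back to global loadings", {
  cube <- random_cube(4, 4, 8, seed = 10)
  seg <- matrix(0L, 4, 4); seg[1, 1] <- 1L # one-pixel segment
  red <- superpca_reduce(cube, superpixel_map(seg), 3)
  expect_true(red$provenance$fallback[2])
  expect_false(red$provenance$fallback[1])
})

test_that("patch extraction conserves labels and pads borders with zeros", {
  vals <- array(runif(4 * 4 * 3), c(4, 4, 3))
  cube <- hsi_cube(vals, c(500, 600, 700))
  lab <- label_map(matrix(rep(1:2, 8), 4, 4), c("a", "b"))
  ps <- extract_patches(cube, lab, s = 3)
  expect_identical(length(ps), 16L)
  expect_identical(dim(ps$patches)[1:3], c(3L, 3L, 3L))
  # label conservation as a multiset
  expect_identical(sort(ps$labels), sort(as.vector(lab$labels)))
  # centre value identity
  for (i in seq_len(16)) {
    expect_equal(ps$patches[2, 2, , i], vals[ps$centers[i, 1], ps$centers[i, 2], ])
  }
  # corner patch: 5 zero-padded cells for s = 3
  corner <- which(ps$centers[, 1] == 1 & ps$centers[, 2] == 1)
  slice <- ps$patches[, , 1, corner]
  expect_identical(sum(slice == 0), 5L)
  expect_equal(slice[2:3, 2:3], vals[1:2, 1:2, 1])
  # interior patch equals the raw sub-array
  interior <- which(ps$centers[, 1] == 2 & ps$centers[, 2] == 3)
  expect_equal(ps$patches[, , , interior], vals[1:3, 2:4, ])
  expect_error(extract_patches(cube, lab, s = 4), "odd")
})

test_that("only labelled pixels produce patches", {
  cube <- random_cube(6, 6, 4, seed = 11)
  m <- matrix(0L, 6, 6); m[2:3, 2:5] <- 1L
  lab <- label_map(m, "a")
  ps <- extract_patches(cube, lab, s = 5)
  expect_identical(length(ps), 8L)
  expect_true(all(ps$labels == 1L))
})
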