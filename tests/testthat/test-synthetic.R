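test_that("the default endmember has the canonical vegetation features", {
  ax <- make_axis(204)
  w <- as.numeric(ax)
  em <- make_endmember(endmember_params(), ax)
  expect_true(all(em >= 0 & em <= 1))
  # NIR shoulder global maximum
  expect_true(w[which.max(em)] >= 740 && w[which.max(em)] <= 930)
  # green peak: local max inside 530-570
  gwin <- which(w >= 510 & w <= 600)
  peak <- gwin[which.max(em[gwin])]
  expect_true(w[peak] >= 530 && w[peak] <= 570)
  # red valley: local min inside 660-700
  rwin <- which(w >= 640 & w <= 720)
  valley <- rwin[which.min(em[rwin])]
  expect_true(w[valley] >= 660 && w[valley] <= 700)
  expect_gt(ndvi(em, wavelengths = w), 0.6)
})

test_that("amplitude-free endmember is flat and narrow axes are rejected", {
  ax <- make_axis(100)
  p0 <- endmember_params(green_peak_amp = 0, red_valley_depth = 0,
                         nir_plateau = 1e-9, water_dip_depth = 0,
                         base_vis = 0.3)
  expect_equal(make_endmember(p0, ax), rep(0.3, 100), tolerance = 1e-6)
  expect_error(make_endmember(endmember_params(), spectral_axis(seq(500, 900, 10))),
               "400-1000")
})

test_that("treatment spread scales with separability and vanishes at zero", {
  t0 <- default_treatments(0, seed = 5)
  ax <- make_axis(120)
  ems0 <- vapply(t0, function(tr) make_endmember(tr$endmember, ax), numeric(120))
  expect_equal(max(apply(ems0, 1, function(r) diff(range(r)))), 0)

  t1a <- default_treatments(1, seed = 5)
  t1b <- default_treatments(1, seed = 5)
  expect_identical(t1a, t1b) # deterministic under seed
  mean_dist <- function(trs) {
    ems <- vapply(trs, function(tr) make_endmember(tr$endmember, ax), numeric(120))
    mean(dist(t(ems)))
  }
  expect_gt(mean_dist(t1a), 0)
  # monotone in separability over a grid
  d <- vapply(c(0.25, 0.5, 1, 1.5, 2),
              function(s) mean_dist(default_treatments(s, seed = 5)), numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("nitrogen-deficit classes are brighter in green/red and darker in NIR", {
  trs <- default_treatments(1, seed = 1)
  ax <- make_axis(204); w <- as.numeric(ax)
  ems <- vapply(trs, function(tr) make_endmember(tr$endmember, ax), numeric(204))
  green <- w >= 530 & w <= 570; red <- w >= 650 & w <= 690
  nir <- w >= 780 & w <= 900
  ref <- which(vapply(trs, function(t) grepl("^F", t$name), logical(1)))
  for (cl in 1:2) { # A (N0P0K2), B (N0P2K2)
    expect_gt(mean(ems[green, cl]), mean(ems[green, ref]))
    expect_gt(mean(ems[red, cl]), mean(ems[red, ref]))
    expect_lt(mean(ems[nir, cl]), mean(ems[nir, ref]))
  }
})

test_that("every generated class spectrum keeps the template ordering", {
  trs <- default_treatments(1.5, seed = 3)
  ax <- make_axis(204); w <- as.numeric(ax)
  i550 <- nearest_band(ax, 550); i680 <- nearest_band(ax, 680)
  i800 <- nearest_band(ax, 800)
  for (tr in trs) {
    em <- make_endmember(tr$endmember, ax)
    expect_gt(em[i550], em[i680])
    expect_gt(em[i800], em[i680])
  }
})

test_that("scene generation is exact in the noiseless limit and seeded", {
  trs <- default_treatments(1, seed = 2)
  for (i in seq_along(trs)) trs[[i]]$within_class_sd <- 0
  cfg <- scene_config(height = 32, width = 32, n_bands = 60, treatments = trs,
                      sensor_noise_sd = 0, seed = 9)
  sc <- generate_scene(cfg)
  ax <- sc$cube$axis
  for (k in c(1, 7, 14)) {
    em <- make_endmember(trs[[k]]$endmember, ax)
    px <- pixel_spectra(sc$cube)[as.vector(sc$labels$labels == k), , drop = FALSE]
    expect_equal(max(abs(sweep(px, 2, em))), 0)
  }
  sc2 <- generate_scene(cfg)
  expect_identical(sc$cube$values, sc2$cube$values) # bit-identical regeneration
  # shape agreement and mask/label coupling
  expect_identical(dim(sc$cube$values)[1:2], dim(sc$labels$labels))
  expect_identical(sc$mask, sc$labels$labels > 0)
})

test_that("per-class scene means track the endmembers within 2%", {
  sc <- fixture("scene_default", function() generate_scene(scene_config(seed = 7)))
  trs <- default_treatments(1, seed = 7)
  ax <- sc$cube$axis
  flat <- pixel_spectra(sc$cube)
  for (k in c(2, 8, 13)) {
    # expected pixel mean: endmember times the lognormal factor's mean
    em <- make_endmember(trs[[k]]$endmember, ax) *
      exp(trs[[k]]$within_class_sd^2 / 2)
    mu <- colMeans(flat[as.vector(sc$labels$labels == k), , drop = FALSE])
    strong <- em > 0.1 & em < 0.95
    expect_lt(max(abs(mu - em)[strong] / em[strong]), 0.02)
  }
})

test_that("class pixel counts follow the configured layout exactly", {
  cfg <- scene_config(height = 40, width = 40, n_bands = 30, seed = 3,
                      background_fraction = 0.1)
  sc <- generate_scene(cfg)
  counts <- tabulate(sc$labels$labels[sc$labels$labels > 0], 14)
  expect_true(all(counts > 0))
  expect_identical(sum(counts) + sum(sc$labels$labels == 0), 1600L)
  lay2 <- generate_scene(cfg)$labels$labels
  expect_identical(sc$labels$labels, lay2)
})

test_that("multi-scene datasets are independent draws with a year-2 drift", {
  cfg <- scene_config(height = 32, width = 32, n_bands = 40, seed = 31)
  ds <- generate_dataset(cfg, n_scenes = 6, year_shift = 0)
  expect_length(ds, 6)
  expect_length(unique(vapply(ds, function(s) s$cube$values[1, 1, 1], numeric(1))), 6)
  expect_identical(vapply(ds, `[[`, integer(1), "year"), rep(1:2, each = 3L))

  ds2 <- generate_dataset(cfg, n_scenes = 10, year_shift = 0.05)
  vm <- function(s) mean(pixel_spectra(s$cube, s$mask))
  m1 <- mean(vapply(ds2[1:5], vm, numeric(1)))
  m2 <- mean(vapply(ds2[6:10], vm, numeric(1)))
  expect_equal(m2 / m1, 1.05, tolerance = 0.015)
  ds0 <- generate_dataset(cfg, n_scenes = 10, year_shift = 0)
  m1 <- mean(vapply(ds0[1:5], vm, numeric(1)))
  m2 <- mean(vapply(ds0[6:10], vm, numeric(1)))
  expect_equal(m2 / m1, 1, tolerance = 0.015)
})
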