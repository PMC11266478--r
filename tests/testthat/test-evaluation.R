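test_that("confusion matrix counts true-by-predicted pairs", {
  expect_identical(unclass(confusion(c(1, 1, 2), c(1, 2, 2), 2)),
                   matrix(c(1L, 0L, 1L, 1L), 2))
  cm <- confusion(c(1, 2, 3), c(1, 2, 3), 3)
  expect_identical(diag(unclass(cm)), rep(1L, 3))
  set.seed(1)
  yt <- sample(4, 200, replace = TRUE); yp <- sample(4, 200, replace = TRUE)
  cmr <- confusion(yt, yp, 4)
  expect_identical(unname(rowSums(cmr)), as.numeric(tabulate(yt, 4)))
  expect_identical(sum(cmr), 200L)
  expect_error(confusion(c(1, 5), c(1, 1), 4), "range")
})

test_that("OA, AA and kappa match hand-computed fixtures", {
  cm <- matrix(c(45, 10, 5, 40), 2) # rows true, cols predicted
  expect_equal(overall_accuracy(cm), 0.85)
  expect_equal(kappa(cm), 0.70)
  cm2 <- matrix(c(8, 5, 2, 5), 2)
  expect_equal(average_accuracy(cm2), 0.65)
  d <- diag(c(3, 9, 1))
  expect_equal(overall_accuracy(d), 1)
  expect_equal(average_accuracy(d), 1)
  expect_equal(kappa(d), 1)
  u <- matrix(1, 5, 5)
  expect_equal(overall_accuracy(u), 1 / 5)
  # equal support and equal recall -> AA == OA
  cm3 <- matrix(c(7, 3, 3, 7), 2)
  expect_equal(average_accuracy(cm3), overall_accuracy(cm3))
  expect_error(average_accuracy(matrix(c(0, 1, 0, 1), 2)), "class 1")
  expect_warning(kappa(matrix(c(5, 0, 0, 0), 2)), "degenerate")
})

test_that("kappa equals the expanded count-ratio form on random matrices", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    cm <- matrix(rpois(n * n, 8), n)
    total <- sum(cm)
    expanded <- (total * sum(diag(cm)) - sum(rowSums(cm) * colSums(cm))) /
      (total^2 - sum(rowSums(cm) * colSums(cm)))
    expect_equal(kappa(cm), expanded, tolerance = 1e-12)
  }
})

test_that("kappa is near zero for chance-level prediction", {
  set.seed(3)
  ks <- replicate(30, {
    yt <- sample(5, 400, replace = TRUE)
    yp <- sample(5, 400, replace = TRUE)
    kappa(confusion(yt, yp, 5))
  })
  expect_lt(abs(mean(ks)), 0.02)
  expect_lt(max(abs(ks)), 0.15)
})

test_that("metrics are invariant under joint class relabelling", {
  set.seed(4)
  yt <- sample(4, 120, replace = TRUE); yp <- sample(4, 120, replace = TRUE)
  perm <- sample(4)
  cm1 <- confusion(yt, yp, 4); cm2 <- confusion(perm[yt], perm[yp], 4)
  expect_equal(overall_accuracy(cm1), overall_accuracy(cm2))
  expect_equal(average_accuracy(cm1), average_accuracy(cm2))
  expect_equal(kappa(cm1), kappa(cm2))
})

test_that("stratified splits hit the requested fractions per class", {
  y <- rep(1:3, each = 100)
  sp <- split_indices(y, 0.70, seed = 5)
  expect_true(all(abs(tabulate(y[sp$train], 3) - 70) <= 1))
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  y2 <- rep(1:2, each = 1000)
  sp2 <- split_indices(y2, 0.05, seed = 5)
  expect_identical(unname(tabulate(y2[sp2$train], 2)), c(50L, 50L))
  expect_identical(split_indices(y, 0.7, seed = 9)$train,
                   split_indices(y, 0.7, seed = 9)$train)
  expect_error(split_indices(c(1, 2, 2), 0.5), "fewer than 2")
})

test_that("cross-validation folds are disjoint, exhaustive and stratified", {
  y <- rep(1:4, each = 25)
  x <- matrix(rnorm(1000), 100, 10) + y
  majority_factory <- function(xt, yt) {
    structure(list(lab = as.integer(names(which.max(table(yt))))),
              class = "majority_model")
  }
  assign("predict.majority_model",
         function(object, newdata, ...) rep(object$lab, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.majority_model", envir = globalenv()))
  cv <- cross_validate(x, k = 10, model_factory = majority_factory, seed = 6,
                       labels = y)
  expect_identical(unname(tabulate(cv$fold_of, 10)), rep(10L, 10))
  # constant prediction scores its class's frequency in each fold
  for (f in 1:10) {
    maj <- as.integer(names(which.max(table(y[cv$fold_of != f]))))
    expect_equal(cv$folds$OA[f], mean(y[cv$fold_of == f] == maj))
  }
  cv2 <- cross_validate(x, k = 10, model_factory = majority_factory, seed = 6,
                        labels = y)
  expect_identical(cv$folds, cv2$folds)
  expect_error(cross_validate(x, k = 30, majority_factory, labels = y), "fewer")
})

test_that("the ablation case table encodes the seven component combinations", {
  tab <- ablation_cases()
  expect_identical(nrow(tab), 7L)
  expect_identical(tab$use_superpca, c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_identical(tab$use_cbam, c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(tab$use_cnn, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_identical(tab$use_tokenizer_te, c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(tab[7, -1] == TRUE))
  expect_error(run_ablation(toy <- NULL, cases = data.frame(name = "x")),
               "patch_set|malformed")
})

test_that("classification maps agree with patchwise evaluation", {
  tr <- default_treatments(0, seed = 1)[1:3]
  shift <- c(0.25, 0.45, 0.7)
  for (i in 1:3) {
    tr[[i]]$class_id <- i
    tr[[i]]$endmember$nir_plateau <- shift[i]
    tr[[i]]$within_class_sd <- 0
  }
  cfg <- scene_config(height = 20, width = 20, n_bands = 40, treatments = tr,
                      background_fraction = 0.2, sensor_noise_sd = 0, seed = 17)
  sc <- generate_scene(cfg)
  # two large segments so each local PCA basis spans several classes
  seg <- segment_superpixels(first_pc_image(sc$cube), 2)
  red <- superpca_reduce(sc$cube, seg, 9)
  ps <- extract_patches(red, sc$labels, s = 9)
  m <- train_sst(ps, tiny_config(activation = "relu", n_classes = 3),
                 epochs = 30, batch_size = 32, lr = 2e-3, lr_decay = 0.5,
                 decay_every = 12, seed = 8)
  cmap <- classification_map(m, red, sc$labels)
  # background untouched
  expect_true(all(cmap$labels[sc$labels$labels == 0] == 0))
  # map-derived and patch-derived confusion matrices coincide
  pred_patch <- predict(m, ps)
  cm_patch <- confusion(ps$labels, pred_patch, 3)
  keep <- sc$labels$labels > 0
  cm_map <- confusion(sc$labels$labels[keep], cmap$labels[keep], 3)
  expect_identical(unclass(cm_map), unclass(cm_patch))
  # a saturated model on a noiseless scene reproduces the label map
  expect_gte(mean(pred_patch == ps$labels), 0.99)
  expect_true(all(cmap$labels[keep] == sc$labels$labels[keep]))
})
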