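#' Stratified train/test split
#'
#' Randomly splits sample indices (default: stratified per class so the
#' train fraction holds within each class to +/- 1 sample). Deterministic
#' per seed. The pixelwise/patchwise sampling unit follows the per-pixel
#' classification framing; splitting whole scenes instead avoids spatial
#' leakage between overlapping patches and is recommended when scenes are
#' plentiful (split on scene ids and pool the patches yourself).
#'
#' @param labels integer class labels (or a [patch_set], whose labels are
#'   used).
#' @param train_fraction fraction assigned to training (e.g. 0.70 or 0.05).
#' @param stratified stratify per class (default TRUE).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_indices <- function(labels, train_fraction = 0.70, stratified = TRUE,
                          seed = 1) {
  if (inherits(labels, "patch_set")) labels <- labels$labels
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie in (0, 1)")
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  n <- length(labels)
  if (stratified) {
    train <- integer(0)
    for (k in sort(unique(labels))) {
      idx <- which(labels == k)
      if (length(idx) < 2) {
        stop(sprintf("class %d has fewer than 2 samples; cannot stratify", k))
      }
      n_tr <- max(1L, min(length(idx) - 1L, round(train_fraction * length(idx))))
      train <- c(train, sample(idx, n_tr))
    }
  } else {
    train <- sample.int(n, max(1L, round(train_fraction * n)))
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_len(n), train))
}

#' Split a patch set into train and test patch sets
#'
#' @param patches a [patch_set].
#' @param train_fraction,stratified,seed see [split_indices()].
#' @return list with patch sets `train` and `test`.
#' @export
split_patches <- function(patches, train_fraction = 0.70, stratified = TRUE,
                          seed = 1) {
  stopifnot(inherits(patches, "patch_set"))
  idx <- split_indices(patches$labels, train_fraction, stratified, seed)
  list(train = patches[idx$train], test = patches[idx$test])
}

#' Stratified k-fold cross-validation
#'
#' Partitions samples into k stratified folds (disjoint, exhaustive);
#' trains a model on each training complement via `model_factory` and
#' reports per-fold and aggregated metrics.
#'
#' @param patches a [patch_set] (or a spectra matrix when `labels` given).
#' @param k number of folds (default 10); every class must have >= k
#'   samples.
#' @param model_factory function(train_data, train_labels) returning an
#'   object with a `predict(object, newdata)` method yielding class labels.
#'   For a [patch_set] input the factory receives a [patch_set].
#' @param seed integer seed.
#' @param labels class labels when `patches` is a plain matrix.
#' @return list with `folds` (data frame of per-fold AA/OA/Kappa x 100) and
#'   `summary` (mean and sd per metric).
#' @export
cross_validate <- function(patches, k = 10, model_factory, seed = 1,
                           labels = NULL) {
  is_ps <- inherits(patches, "patch_set")
  y <- if (is_ps) patches$labels else labels
  if (is.null(y)) stop("labels required for matrix input")
  if (k < 2) stop("k must be >= 2")
  counts <- table(y)
  if (any(counts < k)) {
    stop(sprintf("class %s has fewer than k = %d samples",
                 names(counts)[which(counts < k)[1]], k))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  fold_of <- integer(length(y))
  cnt <- 0L # continue the fold cycle across classes so totals stay balanced
  for (cl in sort(unique(y))) {
    idx <- sample(which(y == cl))
    fold_of[idx] <- ((cnt + seq_along(idx) - 1L) %% k) + 1L
    cnt <- cnt + length(idx)
  }
  nz <- max(y)
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    if (is_ps) {
      model <- model_factory(patches[tr])
      pred <- predict(model, patches[te])
    } else {
      model <- model_factory(patches[tr, , drop = FALSE], y[tr])
      pred <- predict(model, patches[te, , drop = FALSE])
    }
    rows[[f]] <- metric_row(y[te], pred, nz)
  }
  folds <- as.data.frame(do.call(rbind, rows))
  folds$fold <- seq_len(k)
  list(folds = folds,
       summary = data.frame(metric = c("AA", "OA", "Kappa100"),
                            mean = colMeans(folds[, 1:3]),
                            sd = apply(folds[, 1:3], 2, stats::sd)),
       fold_of = fold_of)
}
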